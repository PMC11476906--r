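# Shared fixtures: tiny catalogs, random alignment tables, and a
# brute-force oracle for the fractional allocation rule.

tiny_catalog <- function() {
  as_gene_catalog(data.frame(
    gene_id = c("g1", "g2", "g3", "m1"),
    length_bp = c(1500, 1000, 600, 1200),
    ko_id = c("K00001", "K00001", "K00002", "KM01"),
    gene_symbol = c("nirS", "nirS", "nosZ", "m1"),
    pathway = c("denitrification", "denitrification", "denitrification",
                "unannotated"),
    is_marker = c(FALSE, FALSE, FALSE, TRUE)
  ))
}

# random alignment table: n_inserts inserts over genes, each insert mapping
# to 1..max_targets distinct genes, all rows passing the filters
random_alignment_table <- function(n_inserts, genes = paste0("g", 1:6),
                                   max_targets = 3) {
  rows <- lapply(seq_len(n_inserts), function(i) {
    k <- sample.int(min(max_targets, length(genes)), 1)
    data.frame(insert_id = paste0("i", i),
               gene_id = sample(genes, k),
               pct_id = runif(k, 95, 100),
               aligned_bases = sample(45:150, k, replace = TRUE))
  })
  do.call(rbind, rows)
}

# fast variant: vectorized, every insert has 1 or 2 targets
random_alignment_table_fast <- function(n_inserts, genes = paste0("g", 1:8),
                                        p_ambiguous = 0.3) {
  g1 <- sample(genes, n_inserts, replace = TRUE)
  amb <- runif(n_inserts) < p_ambiguous
  id <- paste0("i", seq_len(n_inserts))
  tab <- data.frame(insert_id = id, gene_id = g1,
                    pct_id = 99, aligned_bases = 100)
  if (any(amb)) {
    g2 <- vapply(g1[amb], function(g) sample(setdiff(genes, g), 1), "")
    tab <- rbind(tab, data.frame(insert_id = id[amb], gene_id = g2,
                                 pct_id = 99, aligned_bases = 100))
  }
  tab
}

# independent brute-force implementation of the allocation rule: explicit
# per-insert loop, no shared code with count_inserts()
brute_force_counts <- function(rows, zero_unique = "equal") {
  rows <- unique(rows[, c("insert_id", "gene_id")])
  targets <- split(rows$gene_id, rows$insert_id)
  uniq <- table(unlist(targets[lengths(targets) == 1L]))
  counts <- list()
  add <- function(g, x) counts[[g]] <<- (counts[[g]] %||% 0) + x
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (tg in targets) {
    if (length(tg) == 1L) {
      add(tg, 1)
    } else {
      w <- vapply(tg, function(g) {
        if (g %in% names(uniq)) as.numeric(uniq[[g]]) else 0
      }, numeric(1))
      if (sum(w) > 0) {
        for (j in seq_along(tg)) add(tg[j], w[j] / sum(w))
      } else if (zero_unique == "equal") {
        for (j in seq_along(tg)) add(tg[j], 1 / length(tg))
      }
    }
  }
  out <- setNames(as.numeric(unlist(counts)), names(counts))
  out[sort(names(out))]
}
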