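# From alignment tables to per-cell profiles.
#
# The counting unit is the "insert": a merged read pair or orphan read. An
# insert mapping to exactly one gene is unique; one mapping to several genes
# is ambiguous and is fractionally allocated in proportion to the unique
# insert counts of its target genes.

#' Filter insert-to-gene alignments
#'
#' Retains only alignments with percent identity >= `min_identity` and at
#' least `min_aligned` aligned bases (both inclusive).
#'
#' @param rows data frame with columns `insert_id`, `gene_id`, `pct_id`,
#'   `aligned_bases`.
#' @param min_identity minimum percent identity (0-100), default 95.
#' @param min_aligned minimum aligned bases, default 45.
#' @return the surviving rows, same columns.
#' @export
filter_alignments <- function(rows, min_identity = 95, min_aligned = 45) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) return(rows)
  need <- c("insert_id", "gene_id", "pct_id", "aligned_bases")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0L)
    stop("alignment table missing column(s): ", paste(miss, collapse = ", "))
  if (any(rows$pct_id < 0 | rows$pct_id > 100))
    stop("pct_id must lie in [0, 100]")
  keep <- rows$pct_id >= min_identity & rows$aligned_bases >= min_aligned
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fractional insert counts per gene
#'
#' Every unique insert contributes 1 to its single target gene. Every
#' ambiguous insert distributes 1 across its target genes in proportion to
#' those genes' unique insert counts; if none of its targets has a unique
#' count the insert is split equally (`zero_unique = "equal"`, default) or
#' dropped (`zero_unique = "discard"`). Proportions are computed once from
#' the unique counts (single pass, no iterative reallocation). Repeated
#' (insert, gene) rows are deduplicated with a warning.
#'
#' @param rows filtered alignment rows (see [filter_alignments()]); only
#'   `insert_id` and `gene_id` are used.
#' @param zero_unique policy for ambiguous inserts whose targets all lack
#'   unique counts: `"equal"` or `"discard"`.
#' @return named numeric vector of fractional counts per gene. Unless
#'   inserts were discarded, the values sum to the number of distinct
#'   inserts.
#' @export
count_inserts <- function(rows, zero_unique = c("equal", "discard")) {
  zero_unique <- match.arg(zero_unique)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) return(setNames(numeric(0), character(0)))
  dt <- data.table::data.table(insert_id = as.character(rows$insert_id),
                               gene_id = as.character(rows$gene_id))
  n0 <- nrow(dt)
  dt <- unique(dt)
  if (nrow(dt) < n0)
    warning("deduplicated ", n0 - nrow(dt), " repeated (insert, gene) pair(s)")
  ntarget <- NULL; insert_id <- NULL; gene_id <- NULL; w <- NULL # NSE notes
  dt[, ntarget := .N, by = insert_id]
  uniq <- dt[ntarget == 1L]
  ucount <- uniq[, .N, by = gene_id]
  counts <- setNames(as.numeric(ucount$N), ucount$gene_id)
  amb <- dt[ntarget > 1L]
  if (nrow(amb) > 0L) {
    amb[, w := counts[gene_id]]
    amb[is.na(w), w := 0]
    tot <- NULL; frac <- NULL
    amb[, tot := sum(w), by = insert_id]
    if (zero_unique == "equal") {
      amb[, frac := if (tot[1L] > 0) w / tot[1L] else rep(1 / .N, .N),
          by = insert_id]
    } else {
      amb[, frac := if (tot[1L] > 0) w / tot[1L] else rep(0, .N),
          by = insert_id]
    }
    add <- amb[, .(add = sum(frac)), by = gene_id]
    all_genes <- union(names(counts), add$gene_id)
    out <- setNames(numeric(length(all_genes)), all_genes)
    out[names(counts)] <- counts
    out[add$gene_id] <- out[add$gene_id] + add$add
    counts <- out
  }
  counts[sort(names(counts))]
}

#' Gene-length normalization of insert counts
#'
#' Divides every gene's (fractional) insert count by the gene length in
#' bases, giving abundances in counts per base.
#'
#' @param counts named numeric vector of fractional counts (from
#'   [count_inserts()]).
#' @param catalog a `gene_catalog`; every counted gene must be present.
#' @return named numeric vector of length-normalized abundances.
#' @export
length_normalize <- function(counts, catalog) {
  if (length(counts) == 0L) return(counts)
  idx <- match(names(counts), catalog$gene_id)
  if (anyNA(idx))
    stop("gene(s) absent from catalog: ",
         paste(names(counts)[is.na(idx)], collapse = ", "))
  counts / catalog$length_bp[idx]
}

#' Aggregate gene abundances into KEGG-orthology abundances
#'
#' Sums length-normalized gene abundances over shared KOs. Genes without a
#' KO annotation are excluded from the output; their summed abundance is
#' attached as attribute `"unannotated_mass"`.
#'
#' @param abundances named numeric vector of gene abundances.
#' @param catalog a `gene_catalog` supplying `ko_id` per gene.
#' @return named numeric vector keyed by KO, with attribute
#'   `unannotated_mass`.
#' @export
aggregate_ko <- function(abundances, catalog) {
  if (length(abundances) == 0L) {
    out <- setNames(numeric(0), character(0))
    attr(out, "unannotated_mass") <- 0
    return(out)
  }
  idx <- match(names(abundances), catalog$gene_id)
  if (anyNA(idx))
    stop("gene(s) absent from catalog: ",
         paste(names(abundances)[is.na(idx)], collapse = ", "))
  ko <- catalog$ko_id[idx]
  unannot <- ko == "unannotated" | is.na(ko)
  mass <- sum(abundances[unannot])
  ann <- abundances[!unannot]
  ko <- ko[!unannot]
  if (length(ann) == 0L) {
    out <- setNames(numeric(0), character(0))
  } else {
    agg <- tapply(ann, ko, sum)
    out <- setNames(as.numeric(agg), names(agg))
    out <- out[sort(names(out))]
  }
  attr(out, "unannotated_mass") <- unname(mass)
  out
}

#' Per-cell normalization by single-copy marker genes
#'
#' Divides abundances by the median abundance of the universal single-copy
#' marker genes. Because each marker occurs once per genome, the median
#' marker abundance estimates the sequencing units contributed per cell, so
#' the normalized values are interpretable as gene (or transcript) copies
#' per cell and are invariant to sequencing depth.
#'
#' @param abundances named numeric vector (gene- or KO-keyed).
#' @param marker_abundances numeric vector of the marker genes' abundances.
#' @param expected_markers number of markers required (default 10).
#' @param allow_partial if TRUE, fewer markers than expected is a warning
#'   instead of an error.
#' @return named numeric vector of per-cell values, with attribute
#'   `marker_median` holding the normalization constant.
#' @export
per_cell_normalize <- function(abundances, marker_abundances,
                               expected_markers = 10, allow_partial = FALSE) {
  if (length(marker_abundances) < expected_markers) {
    msg <- sprintf("expected %d marker abundances, got %d",
                   expected_markers, length(marker_abundances))
    if (allow_partial) warning(msg) else stop(msg)
  }
  m <- median(marker_abundances)
  if (!is.finite(m) || m <= 0) stop("marker median zero")
  out <- abundances / m
  attr(out, "marker_median") <- m
  out
}

#' One-sample quantification pipeline: alignments to per-cell KO profile
#'
#' Chains [filter_alignments()], [count_inserts()], [length_normalize()],
#' [aggregate_ko()] and [per_cell_normalize()] (per-cell normalization is
#' applied after KO aggregation; marker genes are single genes with their
#' own KO so the ratio is unaffected by the order).
#'
#' @param rows alignment rows for one sample and omic layer.
#' @param catalog a `gene_catalog` with `is_marker` flags.
#' @param min_identity,min_aligned alignment filter thresholds.
#' @param zero_unique see [count_inserts()].
#' @param allow_partial see [per_cell_normalize()].
#' @return named numeric vector of per-cell values keyed by KO (markers
#'   included), with attributes `marker_median` and `unannotated_mass`.
#' @export
per_cell_pipeline <- function(rows, catalog, min_identity = 95,
                              min_aligned = 45, zero_unique = "equal",
                              allow_partial = FALSE) {
  kept <- filter_alignments(rows, min_identity, min_aligned)
  counts <- count_inserts(kept, zero_unique = zero_unique)
  ab <- length_normalize(counts, catalog)
  kos <- aggregate_ko(ab, catalog)
  marker_kos <- unique(catalog$ko_id[catalog$is_marker])
  mk <- setNames(numeric(length(marker_kos)), marker_kos)
  present <- intersect(marker_kos, names(kos))
  mk[present] <- kos[present]
  out <- per_cell_normalize(kos, mk, expected_markers = length(marker_kos),
                            allow_partial = allow_partial)
  attr(out, "unannotated_mass") <- attr(kos, "unannotated_mass")
  out
}

#' Read / write alignment tables and profile matrices (TSV)
#'
#' Alignment tables carry columns `sample_id`, `insert_id`, `gene_id`,
#' `pct_id`, `aligned_bases`. Profile matrices are written with features as
#' rows and samples as columns, at 12 significant digits so that writes
#' round-trip losslessly at that precision.
#'
#' @param path file path.
#' @return `read_alignment_table`: a data frame; `read_profile_matrix`: a
#'   numeric matrix with feature row names.
#' @export
read_alignment_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE)
}

#' @rdname read_alignment_table
#' @param table alignment data frame to write.
#' @export
write_alignment_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_alignment_table
#' @param mat numeric matrix (features x samples).
#' @export
write_profile_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat),
                   signif(as.data.frame(mat), 12),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_alignment_table
#' @export
read_profile_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
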