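test_that("alignment filter keeps >=95% identity and >=45 aligned bases, inclusive", {
  rows <- data.frame(insert_id = c("a", "b", "c", "d"),
                     gene_id = "g1",
                     pct_id = c(95.0, 94.9, 99.0, 97.0),
                     aligned_bases = c(45, 100, 44, 80))
  kept <- filter_alignments(rows)
  expect_setequal(kept$insert_id, c("a", "d"))
  expect_equal(filter_alignments(rows[0, ]), rows[0, ])
})

test_that("fractional allocation follows the unique-proportional rule", {
  # uniques g1:3, g2:1; one ambiguous insert on {g1,g2} -> 3.75 / 1.25
  rows <- data.frame(
    insert_id = c("u1", "u2", "u3", "u4", "x", "x"),
    gene_id = c("g1", "g1", "g1", "g2", "g1", "g2"),
    pct_id = 99, aligned_bases = 100)
  expect_equal(count_inserts(rows), c(g1 = 3.75, g2 = 1.25))
  expect_equal(sum(count_inserts(rows)), 5)

  # single ambiguous insert, no uniques anywhere -> equal split
  amb <- data.frame(insert_id = "x", gene_id = c("g1", "g2"),
                    pct_id = 99, aligned_bases = 100)
  expect_equal(count_inserts(amb), c(g1 = 0.5, g2 = 0.5))
  expect_equal(unname(count_inserts(amb, zero_unique = "discard")), c(0, 0))

  # only unique inserts -> raw counts
  u <- data.frame(insert_id = c("a", "b", "c"), gene_id = c("g1", "g1", "g2"),
                  pct_id = 99, aligned_bases = 100)
  expect_equal(count_inserts(u), c(g1 = 2, g2 = 1))

  # duplicated (insert, gene) rows deduplicate with a warning
  expect_warning(res <- count_inserts(rbind(u, u[1, ])), "deduplicated")
  expect_equal(res, c(g1 = 2, g2 = 1))
})

test_that("count_inserts matches a brute-force oracle on exhaustive small tables", {
  set.seed(7)
  n_cases <- 0
  for (rep in 1:220) {
    tab <- random_alignment_table(sample(1:20, 1),
                                  genes = paste0("g", 1:sample(2:6, 1)))
    got <- count_inserts(tab)
    want <- brute_force_counts(tab)
    expect_equal(got, want, tolerance = 1e-12)
    n_cases <- n_cases + 1
  }
  expect_gte(n_cases, 200)
})

test_that("allocation conserves counts and is scale-free", {
  set.seed(11)
  for (rep in 1:25) {
    tab <- random_alignment_table_fast(sample(50:500, 1))
    counts <- count_inserts(tab)
    expect_equal(sum(counts), length(unique(tab$insert_id)),
                 tolerance = 1e-9)
  }
  # scale-free split: replicating every unique insert c times leaves the
  # ambiguous insert's proportions unchanged
  base <- data.frame(insert_id = c("u1", "u2", "u3", "u4"),
                     gene_id = c("g1", "g1", "g1", "g2"),
                     pct_id = 99, aligned_bases = 100)
  amb <- data.frame(insert_id = "x", gene_id = c("g1", "g2"),
                    pct_id = 99, aligned_bases = 100)
  for (c_ in c(2, 5)) {
    scaled <- base[rep(seq_len(nrow(base)), c_), ]
    scaled$insert_id <- paste0(scaled$insert_id, "_", rep(seq_len(c_), each = 4))
    split1 <- count_inserts(rbind(base, amb)) - c(g1 = 3, g2 = 1)
    splitc <- count_inserts(rbind(scaled, amb)) - c_ * c(g1 = 3, g2 = 1)
    expect_equal(split1, splitc, tolerance = 1e-12)
  }
})

test_that("length normalization divides by gene length and is homogeneous", {
  cat <- tiny_catalog()
  counts <- c(g1 = 3.75, g2 = 0, g3 = 6)
  ab <- length_normalize(counts, cat)
  expect_equal(ab, c(g1 = 3.75 / 1500, g2 = 0, g3 = 0.01))
  cat2 <- cat; cat2$length_bp <- cat2$length_bp * 2L
  expect_equal(length_normalize(counts, cat2), ab / 2)
  expect_error(length_normalize(c(zz = 1), cat), "absent from catalog.*zz")
})

test_that("KO aggregation sums shared KOs and tracks unannotated mass", {
  cat <- as_gene_catalog(data.frame(
    gene_id = c("g1", "g2", "g3"),
    length_bp = c(1000, 1000, 1000),
    ko_id = c("K00370", "K00370", NA)))
  ab <- c(g1 = 0.0025, g2 = 0.0005, g3 = 0.4)
  ko <- aggregate_ko(ab, cat)
  expect_equal(as.numeric(ko["K00370"]), 0.003)
  expect_false("g3" %in% names(ko))
  expect_equal(attr(ko, "unannotated_mass"), 0.4)
  empty <- aggregate_ko(setNames(numeric(0), character(0)), cat)
  expect_length(empty, 0)
})

test_that("per-cell normalization divides by the marker median and is depth-invariant", {
  markers <- rep(0.25, 10)
  pc <- per_cell_normalize(c(K1 = 0.003), markers)
  expect_equal(unname(pc["K1"]), 0.012)
  expect_equal(attr(pc, "marker_median"), 0.25)
  # even marker count: midpoint-of-order-statistics median
  mk <- c(1:10) / 10
  expect_equal(attr(per_cell_normalize(c(K1 = 1), mk), "marker_median"),
               (0.5 + 0.6) / 2)
  # scaling all abundances (incl. markers) by 10 leaves values unchanged
  ab <- c(K1 = 0.003, K2 = 0.01)
  expect_equal(per_cell_normalize(ab * 10, markers * 10),
               per_cell_normalize(ab, markers), ignore_attr = TRUE)
  expect_error(per_cell_normalize(ab, rep(0, 10)), "marker median zero")
  expect_error(per_cell_normalize(ab, rep(1, 7)), "expected 10")
  expect_warning(per_cell_normalize(ab, rep(1, 7), allow_partial = TRUE),
                 "expected 10")
})

test_that("profile matrices round-trip through TSV at 12 significant digits", {
  set.seed(3)
  mat <- matrix(rlnorm(20), 5, 4,
                dimnames = list(paste0("K", 1:5), paste0("s", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(mat, path)
  back <- read_profile_matrix(path)
  expect_equal(back, mat, tolerance = 1e-11)
})
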