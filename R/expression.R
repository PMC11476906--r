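# Expression scores (transcripts per gene copy), log2 views, pathway
# summaries and the genomic-potential classification.

#' Expression score: transcripts per gene copy
#'
#' The expression of a feature is the ratio of its metatranscriptomic
#' per-cell abundance to its metagenomic per-cell abundance. Features with
#' zero gene copies but detected transcripts are reported separately as
#' "orphan transcription" (no ratio is emitted); features absent from both
#' layers are omitted.
#'
#' @param metaG,metaT named numeric vectors of per-cell values over the same
#'   key universe (missing keys are treated as 0).
#' @return list with `expression` (named numeric vector of ratios) and
#'   `orphan` (character vector of keys transcribed without detected gene
#'   copies).
#' @export
expression_score <- function(metaG, metaT) {
  keys <- union(names(metaG), names(metaT))
  g <- setNames(numeric(length(keys)), keys)
  t_ <- g
  g[names(metaG)] <- metaG
  t_[names(metaT)] <- metaT
  orphan <- keys[g == 0 & t_ > 0]
  ok <- keys[g > 0]
  list(expression = t_[ok] / g[ok], orphan = orphan)
}

#' Log2 transform with an explicit zero policy
#'
#' @param x non-negative numeric vector (or matrix).
#' @param zero how to handle zeros: `"half_min"` (default) replaces them by
#'   half the smallest positive value in `x` before taking logs;
#'   `"pseudocount"` adds `pseudocount` to every value; `"na"` maps zeros
#'   to `NA`.
#' @param pseudocount pseudocount used by the `"pseudocount"` policy.
#' @return log2-transformed values, same shape as `x`, with attributes
#'   `zero_policy` and (for `"half_min"`) `zero_fill` recording the policy.
#' @export
log2_transform <- function(x, zero = c("half_min", "pseudocount", "na"),
                           pseudocount = 1e-6) {
  zero <- match.arg(zero)
  if (any(x < 0, na.rm = TRUE)) stop("log2_transform requires non-negative input")
  fill <- NA_real_
  y <- x
  if (zero == "half_min") {
    pos <- x[is.finite(x) & x > 0]
    if (any(x == 0, na.rm = TRUE)) {
      if (length(pos) == 0L)
        stop("all values are zero; cannot apply half-min zero policy")
      fill <- min(pos) / 2
      y[y == 0] <- fill
    }
    out <- log2(y)
  } else if (zero == "pseudocount") {
    out <- log2(y + pseudocount)
  } else {
    y[y == 0] <- NA_real_
    out <- log2(y)
  }
  attr(out, "zero_policy") <- zero
  attr(out, "zero_fill") <- fill
  out
}

# Map KO-keyed profile rows to process labels via the catalog's symbols.
ko_process_table <- function(catalog, map = default_pathway_map()) {
  df <- unique(data.frame(ko_id = catalog$ko_id,
                          symbol = catalog$gene_symbol,
                          is_marker = catalog$is_marker,
                          stringsAsFactors = FALSE))
  df$process <- pathway_of(df$symbol, map)
  df$process[df$is_marker] <- "marker"
  df
}

#' Per-process summary of per-cell profiles
#'
#' Averages per-cell values over the genes of each N-transformation process,
#' per sample. For abundance-like inputs the mean is taken over all catalog
#' genes of the process (zeros included); for expression-like inputs the
#' mean is taken over detected (non-missing, positive-gene-copy) entries
#' only, and the number of dropped entries is reported. Dual NO3<->NO2
#' genes are summarized once, under the dedicated dual process, and are
#' never double-counted into nitrate reduction or nitrification.
#'
#' @param mat numeric matrix, KO rows x sample columns, of per-cell values
#'   (NA allowed for expression inputs where the ratio is undefined).
#' @param catalog a `gene_catalog` linking KOs to gene symbols.
#' @param map a `pathway_map`.
#' @param values one of `"abundance"` (mean over all process genes) or
#'   `"expression"` (mean over detected genes only).
#' @return data.frame with columns `process`, `sample_id`, `mean`, `sum`,
#'   `n_genes`, `n_detected`, `detected`.
#' @export
pathway_summary <- function(mat, catalog, map = default_pathway_map(),
                            values = c("abundance", "expression")) {
  values <- match.arg(values)
  kp <- ko_process_table(catalog, map)
  proc <- kp$process[match(rownames(mat), kp$ko_id)]
  rows <- lapply(PROCESS_LABELS, function(p) {
    kos_all <- unique(kp$ko_id[kp$process == p])
    sub <- mat[rownames(mat) %in% kos_all, , drop = FALSE]
    # abundance view: zero rows for catalog KOs never observed
    missing_kos <- setdiff(kos_all, rownames(sub))
    if (values == "abundance" && length(missing_kos) > 0L) {
      pad <- matrix(0, nrow = length(missing_kos), ncol = ncol(mat),
                    dimnames = list(missing_kos, colnames(mat)))
      sub <- rbind(sub, pad)
    }
    vapply(seq_len(ncol(mat)), function(j) {
      v <- sub[, j]
      if (values == "expression") v <- v[!is.na(v)]
      n_det <- sum(v > 0, na.rm = TRUE)
      m <- if (length(v) == 0L) 0 else mean(v)
      c(mean = m, sum = sum(v), n_genes = length(kos_all),
        n_detected = n_det)
    }, numeric(4))
  })
  out <- do.call(rbind, lapply(seq_along(PROCESS_LABELS), function(i) {
    data.frame(process = PROCESS_LABELS[i],
               sample_id = colnames(mat),
               t(rows[[i]]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$detected <- out$n_detected > 0
  out
}

#' Classify lakes by N-transformation genomic potential
#'
#' A lake is classified `"high"` iff its mean per-cell N-transformation gene
#' abundance strictly exceeds `threshold` (default 0.006 genes/cell), else
#' `"low"`.
#'
#' @param lake_means named numeric vector of per-lake mean N-transformation
#'   genes/cell (mean over process-level means; see [lake_potential()]).
#' @param threshold classification threshold, default 0.006.
#' @return named character vector with values `"high"` / `"low"`.
#' @export
classify_potential <- function(lake_means, threshold = 0.006) {
  setNames(ifelse(lake_means > threshold, "high", "low"), names(lake_means))
}

#' Lake-level N-transformation potential from a pathway summary
#'
#' Averages the process-level mean genes/cell of each lake's samples: first
#' over samples within the lake, then over the six N processes.
#'
#' @param summary a [pathway_summary()] result on metagenomic per-cell
#'   profiles.
#' @param sample_lake named character vector mapping `sample_id` to lake.
#' @return named numeric vector of mean N-transformation genes/cell per lake.
#' @export
lake_potential <- function(summary, sample_lake) {
  summary$lake <- sample_lake[summary$sample_id]
  if (anyNA(summary$lake)) stop("sample(s) without lake assignment")
  agg <- tapply(summary$mean, list(summary$process, summary$lake), mean)
  colMeans(agg, na.rm = TRUE)
}

#' Completeness of anammox pathway expression in a sample
#'
#' TRUE iff every gene of the configured anammox set has detected
#' transcripts in the sample. Overriding the default four-gene set
#' (hzsA, hzsB, hzsC, hdh) triggers a warning so non-standard calls are
#' visible.
#'
#' @param transcripts named numeric vector of per-cell transcript values
#'   keyed by gene symbol (or KO mapped to symbols upstream).
#' @param genes anammox gene set, default `c("hzsA","hzsB","hzsC","hdh")`.
#' @return logical scalar.
#' @export
anammox_complete <- function(transcripts,
                             genes = c("hzsA", "hzsB", "hzsC", "hdh")) {
  default <- c("hzsA", "hzsB", "hzsC", "hdh")
  if (!setequal(genes, default))
    warning("non-default anammox gene set: ", paste(genes, collapse = ", "))
  all(genes %in% names(transcripts)) &&
    all(transcripts[genes] > 0, na.rm = FALSE) && !anyNA(transcripts[genes])
}
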