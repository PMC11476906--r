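#' @importFrom stats median ave cmdscale coef cor cor.test cutree dist hclust
#'   lm prcomp residuals rlnorm rnorm runif sd setNames var
#' @importFrom utils combn modifyList read.delim write.table
#' @import data.table
NULL

# Process labels of the inorganic N cycle tracked throughout the package.
# "NO3<->NO2" is the dedicated dual process for genes that cannot be told
# apart functionally: nitrate reductase (narGH) vs nitrite oxidoreductase
# (nxrAB) subunits share KOs.
PROCESS_LABELS <- c("nitrification", "NO3<->NO2", "nitrate_reduction",
                    "denitrification", "DNRA", "anammox")

#' Built-in map from N-cycle gene symbols to transformation processes
#'
#' Returns the default assignment of marker-gene symbols of the inorganic
#' nitrogen cycle to six process labels: nitrification (amoABC, hao), the
#' dual NO3<->NO2 interconversion (narG;nxrA and narH;nxrB, which cannot be
#' assigned unambiguously to nitrate reduction or nitrite oxidation),
#' dissimilatory nitrate reduction (napAB, narI), denitrification
#' (nirS/K, norBC, nosZ), DNRA (nrfAH) and anammox (hzsABC, hdh).
#'
#' @param overrides optional named list `list(process = c("sym", ...))`
#'   replacing the gene set of one or more processes.
#' @return a `data.frame` with columns `symbol`, `process`, `dual`
#'   (logical; TRUE for symbols carrying both candidate processes) and
#'   `candidates` (";"-separated candidate processes for dual symbols),
#'   of class `pathway_map`.
#' @seealso [pathway_of()], [read_pathway_map()]
#' @export
default_pathway_map <- function(overrides = NULL) {
  sets <- list(
    nitrification     = c("amoA", "amoB", "amoC", "hao"),
    "NO3<->NO2"       = c("narG;nxrA", "narH;nxrB"),
    nitrate_reduction = c("napA", "napB", "narI"),
    denitrification   = c("nirS", "nirK", "norB", "norC", "nosZ"),
    DNRA              = c("nrfA", "nrfH"),
    anammox           = c("hzsA", "hzsB", "hzsC", "hdh")
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    bad <- setdiff(names(overrides), names(sets))
    if (length(bad) > 0L)
      stop("unknown process label(s) in overrides: ", paste(bad, collapse = ", "))
    sets[names(overrides)] <- overrides
  }
  map <- data.frame(
    symbol  = unlist(sets, use.names = FALSE),
    process = rep(names(sets), lengths(sets)),
    stringsAsFactors = FALSE
  )
  map$dual <- map$process == "NO3<->NO2"
  map$candidates <- ifelse(map$dual, "nitrate_reduction;nitrification", map$process)
  dup <- map$symbol[duplicated(map$symbol)]
  if (length(dup) > 0L)
    stop("gene symbol assigned to more than one process: ",
         paste(unique(dup), collapse = ", "))
  class(map) <- c("pathway_map", "data.frame")
  map
}

#' Look up the process of a gene symbol
#'
#' @param symbol character vector of gene symbols.
#' @param map a pathway map, by default [default_pathway_map()].
#' @return character vector of process labels; symbols absent from the map
#'   return `"unannotated"`. Dual symbols return `"NO3<->NO2"`.
#' @export
pathway_of <- function(symbol, map = default_pathway_map()) {
  out <- map$process[match(symbol, map$symbol)]
  out[is.na(out)] <- "unannotated"
  out
}

#' Read a pathway-map override file (JSON)
#'
#' The file holds an object `{"process": ["symbol", ...], ...}`; listed
#' processes replace the defaults, unlisted processes keep them.
#'
#' @param path path to a JSON file.
#' @return a `pathway_map` (see [default_pathway_map()]).
#' @export
read_pathway_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  default_pathway_map(overrides = as.list(obj))
}

#' Read a gene catalog from TSV
#'
#' The catalog is a UTF-8 tab-separated table with a header and columns
#' `gene_id` and `length_bp`, plus optional `ko_id`, `gene_symbol`,
#' `pathway` and `is_marker`. Lines starting with `#` are ignored; fields
#' are never quoted. Missing annotation fields become `"unannotated"`.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` of class `gene_catalog` with columns `gene_id`,
#'   `length_bp`, `ko_id`, `gene_symbol`, `pathway`, `is_marker`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  need <- c("gene_id", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("catalog is missing required column(s): ", paste(miss, collapse = ", "))
  as_gene_catalog(df)
}

#' Assemble a gene catalog from a data frame
#'
#' @param df data frame with at least `gene_id` and `length_bp`.
#' @return a validated `gene_catalog`.
#' @export
as_gene_catalog <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene_id <- as.character(df$gene_id)
  if (nrow(df) > 0L) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    if (length(dup) > 0L)
      stop("duplicated gene_id in catalog: ", paste(dup, collapse = ", "))
    if (any(!is.finite(df$length_bp)) || any(df$length_bp < 1))
      stop("non-positive gene length in catalog (gene_id: ",
           paste(df$gene_id[!is.finite(df$length_bp) | df$length_bp < 1],
                 collapse = ", "), ")")
  }
  df$length_bp <- as.integer(df$length_bp)
  for (col in c("ko_id", "gene_symbol", "pathway")) {
    if (is.null(df[[col]])) df[[col]] <- rep("unannotated", nrow(df))
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]]) | df[[col]] == ""] <- "unannotated"
  }
  if (is.null(df$is_marker)) df$is_marker <- rep(FALSE, nrow(df))
  df$is_marker <- as.logical(df$is_marker)
  if (anyNA(df$is_marker)) stop("is_marker must be logical (TRUE/FALSE or 0/1)")
  if (any(df$is_marker & !(df$pathway %in% c("unannotated", "marker"))))
    stop("a single-copy marker gene cannot carry an N-pathway label")
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Write a gene catalog to TSV
#'
#' @param catalog a `gene_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Number of single-copy marker genes in a catalog
#' @param catalog a `gene_catalog`.
#' @return integer count of marker genes.
#' @export
n_markers <- function(catalog) sum(catalog$is_marker)

#' Filter KEGG annotation hits and pick one KO per gene
#'
#' Keeps a hit iff its subject coverage is at least `min_coverage` and its
#' bit score is at least `min_bit_frac` of the maximum expected bit score
#' (both thresholds inclusive), then retains for every gene the surviving
#' hit with the highest bit score; ties are broken lexicographically by KO
#' id so the result is deterministic.
#'
#' @param hits data frame with columns `gene_id`, `ko_id`,
#'   `subject_coverage` (fraction in \[0, 1\]), `bit_score` and
#'   `max_expected_bit_score`.
#' @param min_coverage minimum subject coverage, default 0.70.
#' @param min_bit_frac minimum fraction of the maximum expected bit score,
#'   default 0.5.
#' @return data frame `gene_id`, `ko_id`, `bit_score` with one row per
#'   gene that has an accepted annotation.
#' @export
filter_annotations <- function(hits, min_coverage = 0.70, min_bit_frac = 0.5) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  need <- c("gene_id", "ko_id", "subject_coverage", "bit_score",
            "max_expected_bit_score")
  miss <- setdiff(need, names(hits))
  if (length(miss) > 0L)
    stop("annotation hits missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(hits) == 0L)
    return(hits[, c("gene_id", "ko_id", "bit_score")])
  if (any(hits$max_expected_bit_score <= 0))
    stop("max_expected_bit_score must be positive")
  if (any(hits$subject_coverage < 0 | hits$subject_coverage > 1))
    stop("subject_coverage must lie in [0, 1]")
  keep <- hits$subject_coverage >= min_coverage &
    hits$bit_score >= min_bit_frac * hits$max_expected_bit_score
  kept <- hits[keep, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(kept[, c("gene_id", "ko_id", "bit_score")])
  # best bit score per gene, KO lexicographic tie-break
  kept <- kept[order(kept$gene_id, -kept$bit_score, kept$ko_id), , drop = FALSE]
  kept <- kept[!duplicated(kept$gene_id), c("gene_id", "ko_id", "bit_score")]
  rownames(kept) <- NULL
  kept
}
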