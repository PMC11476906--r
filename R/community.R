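# Beta-diversity, ordination, environmental fitting, group tests,
# hierarchical clustering and the thresholded Pearson co-expression network.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i,j) = sum|x_i - x_j| / sum(x_i + x_j)` on non-negative sample
#' profiles. A pair of all-zero samples is undefined under this formula and
#' is set to 0 by convention, with a warning.
#'
#' @param mat numeric matrix, samples x features, non-negative.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("Bray-Curtis requires non-negative input")
  # vegdist warns separately about empty rows and the resulting NAs; the
  # package raises its own single warning for the all-zero convention below
  d <- suppressWarnings(vegan::vegdist(mat, method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): Bray-Curtis set to 0 by convention")
    d[is.na(d)] <- 0
  }
  d
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Minimizes Kruskal stress-1 by isotonic-regression-based iterative
#' majorization (the `vegan::monoMDS` engine, global model), taking the best
#' of `restarts` starts: the first start is the metric (classical scaling)
#' configuration, the remaining ones are random. Because increasing
#' `restarts` only appends starts to the same seeded stream, the attained
#' stress is non-increasing in `restarts`. The returned configuration is
#' centred and rotated to its principal axes.
#'
#' @param d a `dist` object (n >= k + 2).
#' @param k target dimensionality, default 2.
#' @param restarts number of starts, default 20.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param maxit maximum iterations per start.
#' @return list of class `nmds_ordination`: `points` (n x k), `stress`
#'   (in \[0, 1\]), `converged`, `k`, `restarts`, `seed`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed, maxit = 500) {
  if (missing(seed)) stop("nmds requires an explicit seed")
  n <- attr(d, "Size")
  if (is.null(n)) stop("d must be a 'dist' object")
  if (n <= k) stop("need more samples than dimensions (n > k)")
  set.seed(seed)
  best <- NULL
  init0 <- cmdscale(d, k = k)
  if (ncol(init0) < k)
    init0 <- cbind(init0, matrix(0, n, k - ncol(init0)))
  for (i in seq_len(restarts)) {
    init <- if (i == 1L) init0 else matrix(rnorm(n * k), n, k)
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                          maxit = maxit)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  pr <- prcomp(pts, center = FALSE, scale. = FALSE)
  pts <- pr$x[, seq_len(k), drop = FALSE]
  dimnames(pts) <- list(attr(d, "Labels"), paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress,
                 converged = isTRUE(best$converged > 0) || best$stress < 1e-6,
                 k = k, restarts = restarts, seed = seed),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples, k = %d, stress = %.4f (%d starts, seed %s)\n",
              nrow(x$points), x$k, x$stress, x$restarts, format(x$seed)))
  invisible(x)
}

#' Principal component analysis of environmental variables
#'
#' Centred (and by default unit-scaled) PCA. Constant variables cannot be
#' scaled and are dropped with a warning when `scale = TRUE`.
#'
#' @param mat numeric matrix, samples x variables.
#' @param scale scale variables to unit variance, default TRUE.
#' @return list of class `pca_ordination`: `points` (scores), `rotation`,
#'   `variance_fraction` per axis.
#' @export
pca_ordinate <- function(mat, scale = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("PCA needs at least 2 samples")
  if (scale) {
    sds <- apply(mat, 2, sd)
    if (any(sds == 0)) {
      warning("dropping constant variable(s): ",
              paste(colnames(mat)[sds == 0], collapse = ", "))
      mat <- mat[, sds > 0, drop = FALSE]
      if (ncol(mat) == 0L) stop("no non-constant variables left")
    }
  }
  pr <- prcomp(mat, center = TRUE, scale. = scale)
  structure(list(points = pr$x, rotation = pr$rotation,
                 variance_fraction = pr$sdev^2 / sum(pr$sdev^2)),
            class = "pca_ordination")
}

#' Fit environmental vectors onto an ordination
#'
#' For every environmental variable, regresses the (centred) variable on
#' the ordination coordinates; reports the squared multiple correlation
#' (r2), unit-length direction cosines on the ordination axes, and a
#' permutation p-value (fraction of permutations with r2 at least the
#' observed, with the +1 correction). The regression statistic matches
#' `vegan::envfit` (cross-checked in the test suite); the permutation test
#' is vectorized in-package so large calibration studies stay fast.
#'
#' @param ord an `nmds_ordination`, `pca_ordination`, or a coordinate
#'   matrix.
#' @param env data frame of environmental variables, rows aligned with the
#'   ordination samples.
#' @param permutations number of permutations (>= 99), default 999.
#' @param seed RNG seed.
#' @param alpha optional significance filter: keep only variables with
#'   p < alpha in `$significant`.
#' @return list of class `envfit_result`: `directions` (unit vectors),
#'   `r2`, `p`, `permutations`, `significant`.
#' @export
env_fit <- function(ord, env, permutations = 999, seed = 1, alpha = NULL) {
  pts <- if (is.matrix(ord)) ord else ord$points
  if (permutations < 99) stop("use at least 99 permutations")
  env <- as.data.frame(env)
  if (nrow(env) != nrow(pts)) stop("env rows must align with ordination samples")
  n <- nrow(pts)
  keep <- vapply(env, function(v) sd(v) > 0, logical(1))
  dropped <- names(env)[!keep]
  x <- scale(pts, center = TRUE, scale = FALSE)
  qx <- qr.Q(qr(x))
  set.seed(seed)
  perms <- replicate(permutations, sample.int(n))
  fit_one <- function(y) {
    yc <- y - mean(y)
    ssy <- sum(yc^2)
    b <- qr.coef(qr(x), yc)
    r2 <- sum(qr.fitted(qr(x), yc)^2) / ssy
    dir <- b / sqrt(sum(b^2))
    yp <- matrix(yc[perms], nrow = n)
    r2p <- colSums((crossprod(qx, yp))^2) / ssy
    list(r2 = r2, p = (sum(r2p >= r2) + 1) / (permutations + 1), dir = dir)
  }
  vars <- names(env)
  r2 <- setNames(rep(NA_real_, length(vars)), vars)
  p <- r2
  arr <- matrix(NA_real_, length(vars), ncol(pts),
                dimnames = list(vars, colnames(pts)))
  for (v in vars[keep]) {
    f <- fit_one(env[[v]])
    r2[v] <- f$r2; p[v] <- f$p; arr[v, ] <- f$dir
  }
  sig <- if (is.null(alpha)) vars else vars[!is.na(p) & p < alpha]
  structure(list(directions = arr, r2 = r2, p = p,
                 permutations = permutations, significant = sig,
                 dropped = dropped, seed = seed),
            class = "envfit_result")
}

#' BIOENV: best environmental-variable subset for a community distance
#'
#' Exhaustive search over subsets of environmental variables (sizes 1 to
#' `max_subset`). For each subset, the environmental distance is Euclidean
#' on z-scored variables, and the score is the Spearman rank correlation
#' rho between the vectorized upper triangles of the community and
#' environmental distance matrices. Returns the best subset and the full
#' ranking.
#'
#' @param d community `dist`.
#' @param env data frame of environmental variables (rows = samples).
#' @param max_subset largest subset size, default all variables.
#' @param max_evals guard on the exhaustive budget, default 10000 subsets.
#' @return list of class `bioenv_result`: `best` (variable names), `rho`,
#'   `ranking` (data.frame subset/size/rho, sorted by rho).
#' @export
bioenv_select <- function(d, env, max_subset = ncol(env), max_evals = 10000) {
  env <- as.data.frame(env)
  p <- ncol(env)
  if (p < 1L) stop("empty environmental variable set")
  if (nrow(env) != attr(d, "Size")) stop("env rows must match distance size")
  max_subset <- min(max_subset, p)
  n_eval <- sum(choose(p, seq_len(max_subset)))
  if (n_eval > max_evals)
    stop("exhaustive search over ", n_eval, " subsets exceeds budget; ",
         "reduce max_subset")
  z <- scale(as.matrix(env))
  dv <- as.vector(d)
  rows <- list()
  for (size in seq_len(max_subset)) {
    for (idx in utils::combn(p, size, simplify = FALSE)) {
      de <- dist(z[, idx, drop = FALSE])
      rho <- suppressWarnings(cor(dv, as.vector(de), method = "spearman"))
      rows[[length(rows) + 1L]] <-
        data.frame(subset = paste(names(env)[idx], collapse = "+"),
                   size = size, rho = rho, stringsAsFactors = FALSE)
    }
  }
  rk <- do.call(rbind, rows)
  rk <- rk[order(-rk$rho), , drop = FALSE]
  rownames(rk) <- NULL
  structure(list(best = strsplit(rk$subset[1L], "+", fixed = TRUE)[[1L]],
                 rho = rk$rho[1L], ranking = rk),
            class = "bioenv_result")
}

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' One-factor distance-based partition of sums of squares: total SS from
#' all pairwise squared distances, within-group SS from within-group pairs
#' (the Gower-centred formulation), pseudo-F = (SSb/(a-1)) / (SSw/(n-a)),
#' and a p-value from free permutation of group labels with the +1
#' correction. Vectorized over permutations; cross-checked against
#' `vegan::adonis2` in the test suite.
#'
#' @param d a `dist`.
#' @param groups factor (or vector) of group labels, length n.
#' @param permutations number of label permutations, default 999.
#' @param seed RNG seed.
#' @return list of class `permanova_result`: `F`, `R2`, `p`, `df`,
#'   `permutations`.
#' @export
permanova <- function(d, groups, permutations = 999, seed = 1) {
  n <- attr(d, "Size")
  groups <- factor(groups)
  if (length(groups) != n) stop("groups must have one label per sample")
  a <- nlevels(groups)
  if (a < 2L) stop("need at least 2 groups")
  if (all(table(groups) == 1L))
    warning("all groups are singletons: residual df is 0, p degenerate")
  d2 <- as.matrix(d)^2
  sst <- sum(d2) / (2 * n)
  gsets <- split(seq_len(n), groups)   # fixed group slots; permute samples
  gsizes <- lengths(gsets)
  ssw_of <- function(m) {
    s <- 0
    for (j in seq_along(gsets)) {
      i <- gsets[[j]]
      if (gsizes[[j]] > 1L) s <- s + sum(m[i, i]) / (2 * gsizes[[j]])
    }
    s
  }
  ssw <- ssw_of(d2)
  ssb <- sst - ssw
  df1 <- a - 1L; df2 <- n - a
  fobs <- if (df2 > 0 && ssw > 0) (ssb / df1) / (ssw / df2) else Inf
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(permutations)) {
    idx <- sample.int(n)
    sswp <- ssw_of(d2[idx, idx])
    fp <- if (df2 > 0 && sswp > 0) ((sst - sswp) / df1) / (sswp / df2) else Inf
    if (fp >= fobs) ge <- ge + 1L
  }
  structure(list(F = fobs, R2 = ssb / sst, p = (ge + 1) / (permutations + 1),
                 df = c(df1, df2), permutations = permutations, seed = seed),
            class = "permanova_result")
}

#' Hierarchical clustering of profiles
#'
#' Agglomerative clustering (average linkage by default) on Euclidean
#' distances of log2-transformed profiles. Items are ordered by id before
#' clustering so ties resolve deterministically.
#'
#' @param mat numeric matrix, items (e.g. samples) x features.
#' @param linkage linkage method, default "average".
#' @param log2_input transform profiles with [log2_transform()] first,
#'   default TRUE.
#' @return an `hclust` object.
#' @export
hclust_profiles <- function(mat, linkage = "average", log2_input = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 items to cluster")
  if (anyNA(mat)) {
    bad <- rownames(mat)[apply(mat, 1, anyNA)]
    stop("NaN/NA in profiles of: ", paste(bad, collapse = ", "))
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (log2_input) mat[] <- log2_transform(mat)
  hclust(dist(mat), method = linkage)
}

#' Thresholded Pearson co-expression network
#'
#' Computes pairwise Pearson correlations between feature profiles on
#' pairwise-complete observations and keeps every undirected edge with
#' |r| >= `threshold` (sign retained). Features with fewer than `min_n`
#' complete observations are excluded with a warning; isolated features
#' stay in the node list.
#'
#' @param mat numeric matrix, features x samples (log2-transformed
#'   upstream; see [log2_transform()]).
#' @param threshold absolute-correlation cutoff, default 0.8.
#' @param min_n minimum complete observations per feature, default 3.
#' @return list of class `coexpression_network`: `edges` (data.frame
#'   `feature_a`, `feature_b`, `r`, `n`), `nodes`, `threshold`.
#' @export
coexpression_network <- function(mat, threshold = 0.8, min_n = 3) {
  mat <- as.matrix(mat)
  if (ncol(mat) < min_n) stop("need at least ", min_n, " samples")
  nobs <- rowSums(is.finite(mat))
  if (any(nobs < min_n)) {
    warning("excluding feature(s) with < ", min_n, " complete observations: ",
            paste(rownames(mat)[nobs < min_n], collapse = ", "))
    mat <- mat[nobs >= min_n, , drop = FALSE]
  }
  nodes <- rownames(mat)
  if (length(nodes) < 2L)
    return(structure(list(edges = data.frame(feature_a = character(0),
                                             feature_b = character(0),
                                             r = numeric(0), n = integer(0)),
                          nodes = nodes, threshold = threshold),
                     class = "coexpression_network"))
  r <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  nmat <- tcrossprod(!is.na(mat) * 1)  # complete pairs per feature pair
  ut <- which(upper.tri(r), arr.ind = TRUE)
  keep <- !is.na(r[ut]) & abs(r[ut]) >= threshold & nmat[ut] >= min_n
  sel <- ut[keep, , drop = FALSE]
  edges <- data.frame(feature_a = nodes[sel[, 1]],
                      feature_b = nodes[sel[, 2]],
                      r = r[sel], n = as.integer(nmat[sel]),
                      stringsAsFactors = FALSE)
  # canonical ordered pair and deterministic row order
  swap <- edges$feature_a > edges$feature_b
  tmp <- edges$feature_a[swap]
  edges$feature_a[swap] <- edges$feature_b[swap]
  edges$feature_b[swap] <- tmp
  edges <- edges[order(edges$feature_a, edges$feature_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = nodes, threshold = threshold),
            class = "coexpression_network")
}
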