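test_that("Bray-Curtis obeys bounds, symmetry and conventions", {
  m <- rbind(a = c(2, 0, 1), b = c(2, 0, 1), c = c(0, 2, 0))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)        # disjoint supports
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(as.matrix(bray_curtis(rbind(x = c(2, 0), y = c(0, 2))))[1, 2], 1)
  set.seed(2)
  r <- matrix(rlnorm(60), 6)
  expect_true(all(bray_curtis(r) >= 0 & bray_curtis(r) <= 1))
  expect_warning(dz <- bray_curtis(rbind(a = c(0, 0), b = c(0, 0))),
                 "all-zero")
  expect_equal(as.vector(dz), 0)
  expect_error(bray_curtis(matrix(c(-1, 1), 1)), "non-negative")
})

test_that("NMDS recovers embeddable configurations and is deterministic", {
  set.seed(14)
  pts <- matrix(rnorm(8), 4, 2)
  d <- dist(pts)
  o <- nmds(d, k = 2, restarts = 5, seed = 7)
  expect_lt(o$stress, 1e-3)
  o2 <- nmds(d, k = 2, restarts = 5, seed = 7)
  expect_identical(o$points, o2$points)
  expect_error(nmds(dist(matrix(rnorm(4), 2)), k = 2, seed = 1), "n > k")
})

test_that("NMDS stress is non-increasing in restarts", {
  set.seed(3)
  dr <- as.dist(matrix(runif(64), 8, 8) + t(matrix(runif(64), 8, 8)))
  s1 <- nmds(dr, restarts = 1, seed = 5)$stress
  s20 <- nmds(dr, restarts = 20, seed = 5)$stress
  expect_lte(s20, s1 + 1e-12)
})

test_that("PCA reports variance fractions and drops constant variables", {
  x <- rnorm(20)
  m <- cbind(v1 = x, v2 = 2 * x + 3)
  p <- pca_ordinate(m)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  set.seed(8)
  iso <- matrix(rnorm(4000), 2000, 2)
  pv <- pca_ordinate(iso)$variance_fraction
  expect_equal(unname(pv), c(0.5, 0.5), tolerance = 0.05)
  expect_warning(pc <- pca_ordinate(cbind(a = x, b = rep(1, 20))), "constant")
  expect_error(pca_ordinate(matrix(1, 1, 3)), "at least 2 samples")
})

test_that("env_fit matches vegan::envfit and nails a perfect axis fit", {
  set.seed(31)
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  env <- data.frame(a = rnorm(12), b = rnorm(12))
  mine <- env_fit(pts, env, permutations = 999, seed = 4)
  set.seed(4)
  ref <- vegan::envfit(pts, env, permutations = 999)
  expect_equal(unname(mine$r2), unname(ref$vectors$r), tolerance = 1e-10)
  expect_equal(abs(unname(mine$directions)), abs(unname(ref$vectors$arrows)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # unit-length direction vectors
  expect_equal(unname(rowSums(mine$directions^2)), c(1, 1), tolerance = 1e-12)
  # variable equal to axis 1: r2 = 1 and minimal permutation p
  perfect <- env_fit(pts, data.frame(ax1 = pts[, 1]),
                     permutations = 999, seed = 4)
  expect_equal(unname(perfect$r2), 1, tolerance = 1e-12)
  expect_equal(unname(perfect$p), 1 / 1000)
  expect_error(env_fit(pts, env, permutations = 0), "at least 99")
  # zero-variance variable -> NA with reason
  z <- env_fit(pts, data.frame(a = env$a, k = rep(2, 12)),
               permutations = 999, seed = 4)
  expect_true(is.na(z$r2["k"]))
  expect_equal(z$dropped, "k")
})

test_that("bioenv finds the generating gradient variable", {
  set.seed(12)
  n <- 14
  gradient <- sort(runif(n))
  comm <- sapply(1:25, function(j) {
    opt <- runif(1)
    exp(-((gradient - opt) / 0.25)^2) * rlnorm(n, 0, 0.05)
  })
  d <- bray_curtis(comm)
  env <- data.frame(good = exp(gradient),     # monotone transform
                    junk1 = rnorm(n), junk2 = rnorm(n))
  be <- bioenv_select(d, env, max_subset = 2)
  expect_equal(be$best, "good")
  expect_gt(be$rho, 0.9)
  # pure-noise env: best rho stays small
  env_noise <- data.frame(n1 = rnorm(12), n2 = rnorm(12), n3 = rnorm(12))
  set.seed(77)
  dn <- dist(matrix(rnorm(36), 12))
  expect_lte(bioenv_select(dn, env_noise)$rho, 0.5)
  expect_error(bioenv_select(d, env[, 0]), "empty")
})

test_that("bioenv agrees with vegan::bioenv on the winning subset", {
  set.seed(9)
  comm <- matrix(rlnorm(10 * 8), 10, 8)
  env <- data.frame(e1 = rowSums(comm[, 1:3]) + rnorm(10, 0, 0.1),
                    e2 = rnorm(10), e3 = rnorm(10))
  d <- bray_curtis(comm)
  mine <- bioenv_select(d, env)
  ref <- vegan::bioenv(d, env)
  ref_best <- names(env)[ref$models[[which.max(vapply(ref$models,
                                                      `[[`, 1, "est"))]]$best]
  expect_setequal(mine$best, ref_best)
  expect_equal(mine$rho, max(vapply(ref$models, `[[`, 1, "est")),
               tolerance = 1e-10)
})

test_that("permanova matches adonis2 and separates constructed clusters", {
  set.seed(6)
  m <- rbind(matrix(rnorm(30, 0), 6), matrix(rnorm(30, 4), 6))
  d <- dist(m)
  g <- rep(c("A", "B"), each = 6)
  pm <- permanova(d, g, permutations = 999, seed = 3)
  ad <- vegan::adonis2(d ~ g, data = data.frame(g = g), permutations = 999)
  expect_equal(pm$F, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
  # two tight clusters: p near its floor. The exact floor is not 1/(nperm+1)
  # because label permutations that preserve the 6/6 partition (probability
  # 2*(6!)^2/12! ~ 0.2%) reproduce the observed F.
  expect_lte(pm$p, 0.01)
  expect_error(permanova(d, rep("A", 12)), "at least 2 groups")
  expect_warning(permanova(dist(matrix(rnorm(6), 3)), c("a", "b", "c"),
                           permutations = 9), "singleton")
})

test_that("hierarchical clustering is deterministic with monotone merge heights", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(9, 9, 9),
             s4 = c(8.5, 9, 9))
  hc <- hclust_profiles(m, log2_input = FALSE)
  # identical profiles merge first
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("s1", "s2"))
  expect_true(all(diff(hc$height) >= -1e-12))
  # cut at k = 2 recovers the two constructed groups
  k2 <- cutree(hc, k = 2)
  expect_equal(unname(k2["s1"]), unname(k2["s2"]))
  expect_equal(unname(k2["s3"]), unname(k2["s4"]))
  expect_false(k2[["s1"]] == k2[["s3"]])
  mm <- m; mm[1, 1] <- NA
  expect_error(hclust_profiles(mm, log2_input = FALSE), "s1")
})

test_that("clustering separates the two synthetic lake tiers", {
  st <- simulate_study(list(n_inserts = 2e4), seed = 5)
  q <- quantify_study(st)
  nmat <- q$metaG[!grepl("^KMG", rownames(q$metaG)), ]
  lake_mean <- sapply(split(colnames(nmat), q$sample_lake[colnames(nmat)]),
                      function(s) rowMeans(nmat[, s, drop = FALSE]))
  hc <- hclust_profiles(t(lake_mean))
  k2 <- cutree(hc, 2)
  tier <- setNames(st$metadata$potential_tier, st$metadata$lake)
  expect_equal(length(unique(k2[names(tier)[tier == "high"]])), 1)
  expect_equal(length(unique(k2[names(tier)[tier == "low"]])), 1)
})

test_that("co-expression network applies the |r| >= 0.8 rule with contracts", {
  x <- seq_len(10)
  m <- rbind(f1 = x, f2 = x + rnorm(10, 0, 1e-9),   # r = 1
             f3 = -x,                                # r = -1 with f1
             f4 = c(5, 1, 4, 2, 6, 3, 5, 2, 6, 1))   # weak
  net <- coexpression_network(m, threshold = 0.8)
  e <- net$edges
  key <- paste(e$feature_a, e$feature_b)
  expect_true("f1 f2" %in% key)
  expect_true("f1 f3" %in% key)          # anti-correlation kept, sign retained
  expect_lt(e$r[key == "f1 f3"], 0)
  expect_false(any(grepl("f4", key)))
  expect_true(all(abs(e$r) >= 0.8))
  expect_true(all(e$feature_a != e$feature_b))        # no self-loops
  expect_true(all(e$feature_a < e$feature_b))         # canonical pairs
  # isolated nodes stay in the node list
  expect_true("f4" %in% net$nodes)
  # sample-order invariance
  perm <- sample(10)
  net2 <- coexpression_network(m[, perm], threshold = 0.8)
  expect_equal(net2$edges[, c("feature_a", "feature_b")],
               e[, c("feature_a", "feature_b")])
  # Pearson invariance to increasing affine transforms of one feature
  m3 <- m; m3["f1", ] <- 3 * m3["f1", ] + 11
  net3 <- coexpression_network(m3, threshold = 0.8)
  expect_equal(net3$edges[, c("feature_a", "feature_b")],
               e[, c("feature_a", "feature_b")])
  # short features excluded with a warning
  m4 <- rbind(m, f5 = c(1, 2, NA, NA, NA, NA, NA, NA, NA, NA))
  expect_warning(net4 <- coexpression_network(m4), "f5")
  expect_false("f5" %in% net4$nodes)
})
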