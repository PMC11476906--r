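test_that("porewater grid matches the 15-depth sampling scheme", {
  g <- porewater_grid()
  expect_length(g, 15)
  expect_equal(min(g), -1.0)                        # bottom water, 1 cm above
  expect_equal(g[g > 0 & g <= 2], seq(0.25, 2, 0.25))
  expect_equal(diff(g[g >= 2.5]), rep(0.5, 5))
  expect_equal(max(g), 5.0)
})

test_that("default archetypes carry the stated per-process means and roster", {
  arch <- default_archetypes()
  expect_length(arch, 3)
  expect_equal(arch$pristine_alpine$genes_per_cell$high[["nitrification"]],
               0.017)
  expect_equal(arch$agriculture$genes_per_cell$low[["anammox"]], 0.00005)
  expect_equal(arch$pristine_alpine$genes_per_cell$high[["denitrification"]],
               0.004)
  expect_equal(arch$agriculture$genes_per_cell$low[["nitrate_reduction"]],
               0.002)
  expect_true(all(lengths(lapply(arch, `[[`, "lakes")) == 4))
  # O2 penetration anchors: 1.2 mm (eutrophic) vs 4.7 mm (pristine)
  expect_equal(arch$agriculture$o2_penetration_mm, 1.2)
  expect_equal(arch$pristine_alpine$o2_penetration_mm, 4.7)
  # transcript anchors
  expect_equal(arch$agriculture$transcripts_per_cell[["nitrification"]], 1.2)
  expect_equal(arch$agriculture$transcripts_per_cell[["NO3<->NO2"]], 0.1)
  expect_equal(arch$agriculture$transcripts_per_cell[["denitrification"]],
               0.04)
})

test_that("lake truth is reproducible, mean-accurate, and fixes markers at 1", {
  cat <- default_catalog()
  gpc_high <- default_archetypes()$pristine_alpine$genes_per_cell$high
  t1 <- simulate_lake_truth(gpc_high, catalog = cat, seed = 33)
  t2 <- simulate_lake_truth(gpc_high, catalog = cat, seed = 33)
  expect_identical(t1, t2)
  expect_true(all(t1$copies_per_cell[t1$process == "marker"] == 1))
  expect_true(all(t1$transcripts_per_cell[t1$process == "marker"] == 1))
  # CV = 0: every gene exactly at the process mean / paralog count
  t0 <- simulate_lake_truth(gpc_high, catalog = cat,
                            cv = 0, seed = 1)
  nit <- t0[t0$process == "nitrification", ]
  expect_equal(unique(nit$copies_per_cell), 0.017 / 2)
  # law of large numbers: many replicate draws recover the mean within 2%
  many <- do.call(rbind, lapply(1:60, function(s)
    simulate_lake_truth(gpc_high, catalog = cat,
                        cv = 0.3, seed = 1000 + s)))
  nit_mean <- mean(2 * many$copies_per_cell[many$process == "nitrification"])
  expect_equal(nit_mean, 0.017, tolerance = 0.02)
})

test_that("alignment tables honor construction contracts", {
  cat <- default_catalog()
  gpc_high <- default_archetypes()$pristine_alpine$genes_per_cell$high
  truth <- simulate_lake_truth(gpc_high, catalog = cat, seed = 2)
  t1 <- truth[truth$depth == "05mm", ]
  tab <- simulate_alignment_table(t1, cat, "metaG", n_inserts = 5000,
                                  f_ambiguous = 0.2, f_below = 0.05, seed = 4)
  expect_equal(length(unique(tab$insert_id)), 5000)
  # spiked sub-threshold fraction exercises the filter
  kept <- filter_alignments(tab)
  expect_equal(length(unique(kept$insert_id)), 4750)
  # f_ambiguous = 0: single targets only
  tab0 <- simulate_alignment_table(t1, cat, "metaG", n_inserts = 2000,
                                   f_ambiguous = 0, f_below = 0, seed = 4)
  expect_equal(max(table(tab0$insert_id)), 1)
  # ambiguous rows always pair same-KO paralogs
  multi <- names(which(table(tab$insert_id) == 2))
  pairs <- tab[tab$insert_id %in% multi, ]
  ko_of <- setNames(cat$ko_id, cat$gene_id)
  ko_pairs <- tapply(ko_of[pairs$gene_id], pairs$insert_id,
                     function(k) length(unique(k)))
  expect_true(all(ko_pairs == 1))
  expect_error(simulate_alignment_table(t1, cat[0, ], "metaG", seed = 1),
               "empty catalog")
})

test_that("porewater generator reproduces the stated profile shapes", {
  arch <- default_archetypes()
  agri <- simulate_porewater(arch$agriculture, noise_sd = 0, seed = 1)
  # NH4 exceeds 300 uM at 5 cm in the agriculture archetype (noise-free)
  nh4 <- agri$porewater[agri$porewater$solute == "NH4", ]
  expect_gt(nh4$conc_uM[nh4$depth_cm == 5], 300)
  # pristine archetype: NO3 still present below 1 cm
  pris <- simulate_porewater(arch$pristine_alpine, noise_sd = 0, seed = 1)
  no3 <- pris$porewater[pris$porewater$solute == "NO3", ]
  expect_true(all(no3$conc_uM[no3$depth_cm > 1 & no3$depth_cm <= 2] > 1))
  # noise-free output is seed-independent
  pris2 <- simulate_porewater(arch$pristine_alpine, noise_sd = 0, seed = 999)
  expect_identical(pris, pris2)
  # microprofile on a 0.1 mm grid, penetration at the archetype depth
  expect_equal(diff(agri$microprofile$depth_mm)[1], 0.1)
  pen <- o2_penetration(agri$microprofile)
  expect_equal(pen$depth_mm, 1.2, tolerance = 0.05)
})

test_that("simulate_study builds the full 12-lake design deterministically", {
  st <- simulate_study(list(n_inserts = 300), seed = 17)
  expect_equal(nrow(st$metadata), 12)
  expect_equal(unname(table(st$metadata$group)), rep(4L, 3), ignore_attr = TRUE)
  # 12 lakes x 2 depths x 2 omic layers = 24 meta-omic sample pairs
  n_tables <- sum(vapply(st$alignments, function(l)
    sum(lengths(l)), integer(1)))
  expect_equal(n_tables, 48)
  expect_length(st$porewater, 12)
  expect_length(st$microprofiles, 12)
  st2 <- simulate_study(list(n_inserts = 300), seed = 17)
  expect_identical(st$truth, st2$truth)
  expect_identical(st$alignments, st2$alignments)
  expect_identical(st$porewater, st2$porewater)
  expect_error(simulate_study(list(bogus = 1), seed = 1), "unknown config")
})

test_that("recovered fluxes fall within the printed benthic flux ranges", {
  for (seed in c(1, 2)) {
    st <- simulate_study(list(n_inserts = 10), seed = seed)
    fl <- flux_table(st$porewater, st$microprofiles)
    expect_true(all(fl$J_O2 >= 2.58 & fl$J_O2 <= 10.7),
                label = paste("O2 flux in range, seed", seed))
    expect_true(all(fl$J_NO3 >= 0.21 & fl$J_NO3 <= 3.14),
                label = paste("NO3 flux in range, seed", seed))
    expect_true(all(fl$J_NH4 >= -4.19 & fl$J_NH4 <= -0.15),
                label = paste("NH4 flux in range, seed", seed))
  }
})
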