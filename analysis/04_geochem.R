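#!/usr/bin/env Rscript
# Stage 4: porewater geochemistry. Diffusive benthic fluxes of O2, NO3 and
# NH4 (Fick's first law, Boudreau tortuosity), O2 penetration depths, molar
# C/N ratios of bulk OM, and a correlation screen of lake-level variables.
#
# Usage: Rscript analysis/04_geochem.R [seed]

suppressPackageStartupMessages(library(benthicN))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

st <- simulate_study(list(n_inserts = 10), seed = seed)  # geochem only
dir.create("results/04_geochem", showWarnings = FALSE, recursive = TRUE)

fl <- flux_table(st$porewater, st$microprofiles,
                 groups = setNames(st$metadata$group, st$metadata$lake))
write.table(fl, "results/04_geochem/flux_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cn <- vapply(st$bulk_om, function(om)
  mean(cn_molar_ratio(om$TOC_percent, om$TN_percent)), numeric(1))
env <- data.frame(
  lake = st$metadata$lake,
  max_depth_m = st$metadata$max_depth_m,
  o2_bottom_uM = st$metadata$o2_bottom_uM,
  TOC = vapply(st$bulk_om[st$metadata$lake], function(x) mean(x$TOC_percent), 1),
  TN = vapply(st$bulk_om[st$metadata$lake], function(x) mean(x$TN_percent), 1),
  CN_molar = cn[st$metadata$lake],
  J_O2 = fl$J_O2, J_NH4 = fl$J_NH4, J_NO3 = fl$J_NO3,
  o2_penetration_mm = fl$o2_penetration_mm)
write.table(env, "results/04_geochem/lake_env.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cs <- correlation_screen(env[, -1])
write.table(cs, "results/04_geochem/correlation_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "Fluxes (mmol m-2 d-1): O2 %.2f..%.2f in, NO3 %.2f..%.2f in, NH4 %.2f..%.2f out; O2 penetration %.1f-%.1f mm; grand mean molar C/N %.1f.",
  min(fl$J_O2), max(fl$J_O2), min(fl$J_NO3), max(fl$J_NO3),
  min(fl$J_NH4), max(fl$J_NH4), min(fl$o2_penetration_mm),
  max(fl$o2_penetration_mm), mean(cn)))
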