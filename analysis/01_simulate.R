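#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 12-lake study (ground truth, meta-omic
# alignment tables, porewater/microprofiles, bulk OM, metadata) and save the
# raw-data tables that the later stages consume.
#
# Usage: Rscript analysis/01_simulate.R [seed] [n_inserts]

suppressPackageStartupMessages(library(benthicN))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
n_inserts <- if (length(args) >= 2) as.numeric(args[2]) else 1e5

dir.create("results/01_study", showWarnings = FALSE, recursive = TRUE)
st <- simulate_study(list(n_inserts = n_inserts), seed = seed)

write_catalog(st$catalog, "results/01_study/catalog.tsv")
write.table(st$metadata, "results/01_study/lake_metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# ground truth and alignment tables, one TSV per data stream
truth <- do.call(rbind, Map(function(tr, lk) cbind(lake = lk, tr),
                            st$truth, names(st$truth)))
write.table(truth, "results/01_study/truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (lk in names(st$alignments)) {
  for (dep in names(st$alignments[[lk]])) {
    for (layer in names(st$alignments[[lk]][[dep]])) {
      f <- sprintf("results/01_study/aln_%s_%s_%s.tsv", lk, dep, layer)
      write_alignment_table(st$alignments[[lk]][[dep]][[layer]], f)
    }
  }
}
pw <- do.call(rbind, Map(function(x, lk) cbind(lake = lk, x),
                         st$porewater, names(st$porewater)))
write.table(pw, "results/01_study/porewater.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
mp <- do.call(rbind, Map(function(x, lk) cbind(lake = lk, x),
                         st$microprofiles, names(st$microprofiles)))
write.table(mp, "results/01_study/microprofiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
om <- do.call(rbind, Map(function(x, lk) cbind(lake = lk, x),
                         st$bulk_om, names(st$bulk_om)))
write.table(om, "results/01_study/bulk_om.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "Simulated %d lakes x 2 depths at %g inserts/sample (seed %d): %d alignment tables, %d porewater profiles.",
  nrow(st$metadata), n_inserts, seed,
  sum(vapply(st$alignments, function(l) sum(lengths(l)), 1L)),
  length(st$porewater) * 3L))
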