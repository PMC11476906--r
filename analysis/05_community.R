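#!/usr/bin/env Rscript
# Stage 5: community statistics. Bray-Curtis beta-diversity of the
# per-cell gene, transcript and expression views; NMDS ordinations with
# fitted environmental vectors (permutation-tested); PERMANOVA of lake
# grouping; hierarchical clustering; thresholded Pearson co-expression
# network. Runs the packaged end-to-end pipeline and reports the headline
# statistics.
#
# Usage: Rscript analysis/05_community.R [seed] [n_inserts]

suppressPackageStartupMessages(library(benthicN))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
n_inserts <- if (length(args) >= 2) as.numeric(args[2]) else 1e5

res <- run_pipeline(
  config = list(syndata = list(n_inserts = n_inserts, seed = seed),
                ordination = list(nmds_seed = seed + 1L,
                                  envfit_seed = seed + 2L,
                                  permanova_seed = seed + 3L)),
  outdir = "results/05_community")

for (v in names(res$community)) {
  cm <- res$community[[v]]
  sig <- cm$envfit$significant
  message(sprintf(
    "%s view: NMDS stress %.3f; PERMANOVA (lake) F = %.1f, R2 = %.2f, p = %.3f; envfit variables with p < 0.01: %s",
    v, cm$nmds$stress, cm$permanova$F, cm$permanova$R2, cm$permanova$p,
    if (length(sig)) paste(sig, collapse = ", ") else "none"))
}
message(sprintf("Co-expression network: %d nodes, %d edges at |r| >= %.2f.",
                length(res$network$nodes), nrow(res$network$edges),
                res$network$threshold))
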