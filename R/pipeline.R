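# Orchestration: study-wide quantification, configuration validation, and
# the end-to-end pipeline run that writes every result table.

#' Quantify a whole study: per-cell matrices and expression
#'
#' Runs the per-sample quantification pipeline ([per_cell_pipeline()]) on
#' every (lake, depth, layer) alignment table of a study and assembles
#' KO x sample per-cell matrices for the metagenomic and metatranscriptomic
#' layers, plus expression matrices (transcripts per gene copy, NA where
#' the gene copy is zero).
#'
#' @param study a `benthic_study` (or a compatible list with `alignments`
#'   and `catalog`).
#' @param min_identity,min_aligned alignment filter thresholds.
#' @param zero_unique ambiguous-insert policy, see [count_inserts()].
#' @return list: `metaG`, `metaT` (KO x sample per-cell matrices),
#'   `expression` (ratio matrix, NA where undefined), `orphan` (list of
#'   orphan-transcription KOs per sample), `marker_median` (per sample and
#'   layer), `sample_lake` (named vector).
#' @export
quantify_study <- function(study, min_identity = 95, min_aligned = 45,
                           zero_unique = "equal") {
  catalog <- study$catalog
  samples <- list()
  for (lk in names(study$alignments)) {
    for (dep in names(study$alignments[[lk]])) {
      samples[[paste(lk, dep, sep = "_")]] <- study$alignments[[lk]][[dep]]
    }
  }
  kos <- sort(unique(catalog$ko_id[catalog$ko_id != "unannotated"]))
  build <- function(layer) {
    mat <- matrix(0, nrow = length(kos), ncol = length(samples),
                  dimnames = list(kos, names(samples)))
    mm <- setNames(numeric(length(samples)), names(samples))
    for (s in names(samples)) {
      pc <- per_cell_pipeline(samples[[s]][[layer]], catalog,
                              min_identity = min_identity,
                              min_aligned = min_aligned,
                              zero_unique = zero_unique)
      mat[names(pc), s] <- pc
      mm[s] <- attr(pc, "marker_median")
    }
    list(mat = mat, marker_median = mm)
  }
  g <- build("metaG")
  t_ <- build("metaT")
  expr <- matrix(NA_real_, nrow = length(kos), ncol = length(samples),
                 dimnames = list(kos, names(samples)))
  orphan <- list()
  for (s in names(samples)) {
    es <- expression_score(g$mat[, s], t_$mat[, s])
    expr[names(es$expression), s] <- es$expression
    orphan[[s]] <- es$orphan
  }
  sample_lake <- setNames(sub("_[^_]+$", "", names(samples)), names(samples))
  list(metaG = g$mat, metaT = t_$mat, expression = expr, orphan = orphan,
       marker_median = list(metaG = g$marker_median, metaT = t_$marker_median),
       sample_lake = sample_lake)
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults: alignment
#' and annotation filter thresholds, marker count, flux constants, porosity,
#' ordination and permutation settings, network threshold, and the
#' synthetic-study generator settings.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    filters = list(min_identity = 95, min_aligned = 45,
                   min_coverage = 0.70, min_bit_frac = 0.5),
    markers = list(expected = 10),
    flux = list(phi = 0.9, d0 = as.list(d0_defaults()),
                gradient_window = 3, o2_detection_limit = 1),
    ordination = list(k = 2, restarts = 20, nmds_seed = 101,
                      permutations = 999, envfit_seed = 102,
                      envfit_alpha = 0.01, permanova_seed = 103),
    network = list(threshold = 0.8, min_n = 3),
    classify = list(threshold = 0.006),
    syndata = list(n_inserts = 1e5, f_ambiguous = 0.2, f_below = 0.05,
                   cv = 0.3, noise_sd = 1, lake_jitter_sd = 0.05, seed = 1)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Fills unset keys with defaults, then checks ranges (porosity strictly in
#' (0,1), positive thresholds and diffusivities, seeds present for every
#' stochastic stage). Unknown keys are an error in strict mode, a warning
#' otherwise.
#'
#' @param config possibly partial configuration list.
#' @param strict unknown keys are an error (TRUE, default) or warning.
#' @return the completed, validated configuration.
#' @export
validate_config <- function(config = list(), strict = TRUE) {
  defs <- default_config()
  check_unknown <- function(x, ref, path) {
    bad <- setdiff(names(x), names(ref))
    if (length(bad) > 0L) {
      msg <- paste0("unknown config key(s) under ", path, ": ",
                    paste(bad, collapse = ", "))
      if (strict) stop(msg) else warning(msg)
      x <- x[setdiff(names(x), bad)]
    }
    x
  }
  config <- check_unknown(config, defs, "top level")
  for (sec in names(config)) {
    if (is.list(defs[[sec]]))
      config[[sec]] <- check_unknown(config[[sec]], defs[[sec]], sec)
  }
  cfg <- utils::modifyList(defs, config)
  with(cfg, {
    stopifnot(filters$min_identity > 0, filters$min_aligned > 0,
              filters$min_coverage > 0, filters$min_bit_frac > 0)
    if (flux$phi <= 0 || flux$phi >= 1)
      stop("porosity phi must lie strictly between 0 and 1")
    if (any(unlist(flux$d0) <= 0)) stop("diffusion coefficients must be positive")
    stopifnot(network$threshold > 0, classify$threshold > 0)
  })
  for (s in c("nmds_seed", "envfit_seed", "permanova_seed")) {
    if (is.null(cfg$ordination[[s]]))
      stop("missing seed for stochastic stage: ", s)
  }
  if (is.null(cfg$syndata$seed)) stop("missing seed for syndata")
  cfg
}

#' Run the full analysis pipeline on a (synthetic or supplied) study
#'
#' Executes generation (unless a study is supplied), quantification,
#' expression, geochemistry and community statistics, and writes the result
#' tables to `outdir`: per-cell gene and transcript matrices and pathway
#' summaries, the lake potential classification, the benthic flux table,
#' NMDS coordinates with fitted environmental vectors for the gene,
#' transcript and expression views, the co-expression network edge list,
#' and a JSON manifest recording every threshold and seed.
#'
#' @param config configuration (see [validate_config()]).
#' @param outdir output directory, created if needed.
#' @param study optional pre-built `benthic_study`; by default one is
#'   simulated from `config$syndata`.
#' @return (invisibly) list with all in-memory results.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("benthicN_run_"),
                         study = NULL) {
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(study)) {
    sd_cfg <- cfg$syndata
    study <- stage("syndata",
                   simulate_study(sd_cfg[setdiff(names(sd_cfg), "seed")],
                                  seed = sd_cfg$seed))
  }
  q <- stage("quant", quantify_study(study,
                                     min_identity = cfg$filters$min_identity,
                                     min_aligned = cfg$filters$min_aligned))
  catalog <- study$catalog

  # pathway summaries and classification
  sum_g <- stage("expression",
                 pathway_summary(q$metaG, catalog, values = "abundance"))
  sum_t <- pathway_summary(q$metaT, catalog, values = "abundance")
  sum_e <- pathway_summary(q$expression, catalog, values = "expression")
  pot <- lake_potential(sum_g, q$sample_lake)
  classes <- classify_potential(pot, threshold = cfg$classify$threshold)

  # anammox completeness per sample, on transcript detection by symbol
  kp <- ko_process_table(catalog)
  anx <- vapply(colnames(q$metaT), function(s) {
    v <- q$metaT[, s]
    sym <- kp$symbol[match(names(v), kp$ko_id)]
    by_sym <- tapply(v, sym, sum)
    anammox_complete(by_sym)
  }, logical(1))

  # geochemistry
  fl <- stage("geochem",
              flux_table(study$porewater, study$microprofiles,
                         groups = setNames(study$metadata$group,
                                           study$metadata$lake),
                         phi = cfg$flux$phi,
                         d0 = unlist(cfg$flux$d0),
                         k = cfg$flux$gradient_window,
                         detection_limit = cfg$flux$o2_detection_limit))
  cn <- vapply(study$bulk_om, function(om)
    mean(cn_molar_ratio(om$TOC_percent, om$TN_percent)), numeric(1))

  # lake-level environmental table, repeated per sample
  meta <- study$metadata
  env_lake <- data.frame(
    row.names = meta$lake,
    max_depth_m = meta$max_depth_m,
    o2_bottom_uM = meta$o2_bottom_uM,
    TOC = vapply(study$bulk_om[meta$lake], function(x) mean(x$TOC_percent), 1),
    TN = vapply(study$bulk_om[meta$lake], function(x) mean(x$TN_percent), 1),
    d13C = vapply(study$bulk_om[meta$lake], function(x) mean(x$d13C_permil), 1),
    d15N = vapply(study$bulk_om[meta$lake], function(x) mean(x$d15N_permil), 1),
    CN_molar = cn[meta$lake],
    J_O2 = fl$J_O2[match(meta$lake, fl$lake)],
    o2_penetration_mm = fl$o2_penetration_mm[match(meta$lake, fl$lake)]
  )
  samples <- colnames(q$metaG)
  env_smp <- env_lake[q$sample_lake[samples], , drop = FALSE]
  rownames(env_smp) <- samples

  # ordinations: genes/cell, transcripts/cell, and raw expression ratios
  ord_cfg <- cfg$ordination
  views <- list(genes = t(q$metaG), transcripts = t(q$metaT),
                expression = {
                  e <- t(q$expression); e[is.na(e)] <- 0; e
                })
  community <- stage("community", lapply(seq_along(views), function(i) {
    d <- bray_curtis(views[[i]])
    o <- nmds(d, k = ord_cfg$k, restarts = ord_cfg$restarts,
              seed = ord_cfg$nmds_seed + i - 1L)
    ef <- env_fit(o, env_smp, permutations = ord_cfg$permutations,
                  seed = ord_cfg$envfit_seed + i - 1L,
                  alpha = ord_cfg$envfit_alpha)
    pm <- permanova(d, q$sample_lake[samples] , permutations =
                      ord_cfg$permutations, seed = ord_cfg$permanova_seed + i - 1L)
    list(dist = d, nmds = o, envfit = ef, permanova = pm)
  }))
  names(community) <- names(views)

  # co-expression network on log2 expression ratios (detected entries only)
  expr_log <- q$expression
  pos <- expr_log[!is.na(expr_log) & expr_log > 0]
  fill <- if (length(pos) > 0) min(pos) / 2 else NA_real_
  expr_log[!is.na(expr_log) & expr_log == 0] <- fill
  expr_log <- log2(expr_log)
  net <- stage("network", coexpression_network(expr_log,
                                               threshold = cfg$network$threshold,
                                               min_n = cfg$network$min_n))

  # write outputs
  w <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  write_profile_matrix(q$metaG, file.path(outdir, "per_cell_genes.tsv"))
  write_profile_matrix(q$metaT, file.path(outdir, "per_cell_transcripts.tsv"))
  write_profile_matrix(q$expression, file.path(outdir, "expression_ratio.tsv"))
  w(sum_g, "pathway_summary_genes.tsv")
  w(sum_t, "pathway_summary_transcripts.tsv")
  w(sum_e, "pathway_summary_expression.tsv")
  w(fl, "flux_table.tsv")
  w(net$edges, "coexpression_edges.tsv")
  for (v in names(community)) {
    pts <- community[[v]]$nmds$points
    w(data.frame(sample_id = rownames(pts), pts), paste0("nmds_", v, ".tsv"))
    ef <- community[[v]]$envfit
    w(data.frame(variable = names(ef$r2), r2 = ef$r2, p = ef$p,
                 ef$directions),
      paste0("envfit_", v, ".tsv"))
  }
  lake_report <- list(
    potential = as.list(pot),
    classification = as.list(classes),
    anammox_complete = as.list(anx),
    orphan_counts = lapply(q$orphan, length),
    cn_molar = as.list(cn)
  )
  jsonlite::write_json(lake_report, file.path(outdir, "lake_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    config = cfg[setdiff(names(cfg), "syndata")],
    syndata = cfg$syndata,
    study_seed = study$seed,
    files = sort(unique(c(list.files(outdir), "manifest.json"))),
    n_samples = length(samples),
    stress = lapply(community, function(x) x$nmds$stress)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = cfg, study = study, quant = q,
                 summaries = list(genes = sum_g, transcripts = sum_t,
                                  expression = sum_e),
                 potential = pot, classification = classes,
                 anammox_complete = anx, flux = fl, env = env_lake,
                 community = community, network = net, outdir = outdir))
}
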