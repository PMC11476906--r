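# Synthetic 12-lake study generator. Emulates the statistical structure of
# a Swiss-lake sediment survey: three lake archetypes with stated per-cell
# N-pathway abundances, porewater/microprofile shapes, bulk organic matter,
# and meta-omic alignment tables generated from known ground truth. All
# generators are pure functions of (parameters, seed).

# Per-process mean genes/cell of the high- and low-potential lake tiers.
# Printed values: nitrification 0.017/0.004, denitrification 0.004/0.002,
# nitrate reduction 0.005/0.002, anammox 0.004/0.00005. The dual NO3<->NO2
# and DNRA means are free parameters chosen a priori (see vignette).
GENES_PER_CELL_HIGH <- c(nitrification = 0.017, "NO3<->NO2" = 0.012,
                         nitrate_reduction = 0.005, denitrification = 0.004,
                         DNRA = 0.002, anammox = 0.004)
GENES_PER_CELL_LOW <- c(nitrification = 0.004, "NO3<->NO2" = 0.004,
                        nitrate_reduction = 0.002, denitrification = 0.002,
                        DNRA = 0.001, anammox = 0.00005)
# Study-wide mean transcripts/cell; printed: nitrification 1.2, dual 0.1,
# denitrification 0.04. The rest are free parameters (see vignette).
TRANSCRIPTS_PER_CELL <- c(nitrification = 1.2, "NO3<->NO2" = 0.1,
                          nitrate_reduction = 0.01, denitrification = 0.04,
                          DNRA = 0.002, anammox = 0.004)

#' Roster and metadata of the 12-lake study design
#'
#' Surface area, water residence time, mean and maximum depth, trophic
#' state and lake group for the twelve lakes the generator emulates
#' (four lakes per group).
#'
#' @return data.frame with columns `lake`, `group`, `surface_km2`,
#'   `residence_yr`, `mean_depth_m`, `max_depth_m`, `trophic`,
#'   `potential_tier`.
#' @export
lake_metadata <- function() {
  df <- data.frame(
    lake = c("BRI", "LUC", "SAR", "WAL",
             "BAL", "HAL", "SEM", "ZUG",
             "CON", "GEN", "MAG", "NEU"),
    group = rep(c("pristine_alpine", "agriculture", "large_deep"), each = 4),
    surface_km2 = c(29.8, 111, 7.15, 24.1, 5.22, 9.95, 14.1, 38.3,
                    482, 582, 212, 213),
    residence_yr = c(2.69, 3.5, 0.76, 1.45, 4.22, 3.85, 17.5, 15.1,
                     4.35, 11.4, 4.1, 8.25),
    mean_depth_m = c(168, 107, 34, 104, 33, 29, 46, 84, 99, 153, 177, 64),
    max_depth_m = c(260, 214, 52, 145, 66, 45, 86, 197, 254, 310, 372, 153),
    trophic = c("Oligo", "Oligo", "Oligo", "Oligo",
                "Eu", "Meso", "Meso", "Eu",
                "Oligo", "Meso", "Oligo-meso", "Oligo-meso"),
    stringsAsFactors = FALSE
  )
  # high N-transformation potential: pristine-alpine lakes plus CON and NEU
  df$potential_tier <- ifelse(df$group == "pristine_alpine" |
                                df$lake %in% c("CON", "NEU"), "high", "low")
  df
}

#' Default lake-archetype parameters
#'
#' Three parameter sets (agriculture-influenced, pristine-alpine,
#' large-deep) with per-process mean genes/cell and transcripts/cell and
#' porewater/bulk-OM shape parameters. The large-deep archetype carries
#' per-lake gene-abundance tiers (CON and NEU behave like the
#' high-potential lakes, GEN and MAG like the low-potential ones) while
#' sharing one intermediate porewater shape.
#'
#' @return named list of three archetypes; each holds `group`, `lakes`,
#'   `gene_tier` (named per-lake "high"/"low"), `genes_per_cell` per tier,
#'   `transcripts_per_cell`, and porewater / bulk OM parameters.
#' @export
default_archetypes <- function() {
  meta <- lake_metadata()
  mk <- function(group, o2_pen_mm, o2_bottom, no3_swi, no3_scale_cm,
                 nh4_asym, nh4_scale_cm, so4_swi, so4_scale_cm,
                 toc, tn, d13c, d15n) {
    lakes <- meta$lake[meta$group == group]
    tier <- setNames(meta$potential_tier[meta$group == group], lakes)
    list(group = group, lakes = lakes, gene_tier = tier,
         genes_per_cell = list(high = GENES_PER_CELL_HIGH,
                               low = GENES_PER_CELL_LOW),
         transcripts_per_cell = TRANSCRIPTS_PER_CELL,
         o2_penetration_mm = o2_pen_mm, o2_bottom_uM = o2_bottom,
         no3_swi_uM = no3_swi, no3_scale_cm = no3_scale_cm,
         nh4_asymptote_uM = nh4_asym, nh4_scale_cm = nh4_scale_cm,
         so4_swi_uM = so4_swi, so4_scale_cm = so4_scale_cm,
         toc_percent = toc, tn_percent = tn, d13C = d13c, d15N = d15n)
  }
  list(
    agriculture = mk("agriculture", o2_pen_mm = 1.2, o2_bottom = 100,
                     no3_swi = 120, no3_scale_cm = 0.25,
                     nh4_asym = 400, nh4_scale_cm = 1.5,
                     so4_swi = 150, so4_scale_cm = 0.5,
                     toc = 6.0, tn = 1.0, d13c = -33, d15n = 6),
    pristine_alpine = mk("pristine_alpine", o2_pen_mm = 4.7, o2_bottom = 250,
                         no3_swi = 80, no3_scale_cm = 1.0,
                         nh4_asym = 100, nh4_scale_cm = 2.0,
                         so4_swi = 150, so4_scale_cm = 10,
                         toc = 1.2, tn = 0.15, d13c = -28, d15n = 2),
    large_deep = mk("large_deep", o2_pen_mm = 3.0, o2_bottom = 180,
                    no3_swi = 70, no3_scale_cm = 0.6,
                    nh4_asym = 150, nh4_scale_cm = 2.0,
                    so4_swi = 150, so4_scale_cm = 5,
                    toc = 3.5, tn = 0.5, d13c = -31, d15n = 4.5)
  )
}

#' Porewater sampling depths of the study design
#'
#' The 15 sampling depths: one bottom-water sample 1 cm above the
#' sediment-water interface (-1.0 cm), 0.25 cm intervals from 0 to 2 cm,
#' and 0.5 cm intervals from 2.5 to 5 cm.
#'
#' @return numeric vector of 15 depths in cm (positive downward).
#' @export
porewater_grid <- function() {
  c(-1.0, seq(0.25, 2.0, by = 0.25), seq(2.5, 5.0, by = 0.5))
}

#' Default synthetic gene catalog
#'
#' Twenty N-cycle gene symbols (two same-KO paralogs each, so ambiguous
#' mappings have a target pair) plus ten universal single-copy marker genes
#' with one gene and one KO each.
#'
#' @return a `gene_catalog` (50 genes).
#' @export
default_catalog <- function() {
  map <- default_pathway_map()
  kos <- c("amoA" = "K10944", "amoB" = "K10945", "amoC" = "K10946",
           "hao" = "K10535", "narG;nxrA" = "K00370", "narH;nxrB" = "K00371",
           "napA" = "K02567", "napB" = "K02568", "narI" = "K00374",
           "nirS" = "K15864", "nirK" = "K00368", "norB" = "K04561",
           "norC" = "K02305", "nosZ" = "K00376", "nrfA" = "K03385",
           "nrfH" = "K15876", "hzsA" = "K20932", "hzsB" = "K20933",
           "hzsC" = "K20934", "hdh" = "K20935")
  base_len <- c(830, 1260, 810, 1710, 3740, 1540, 2490, 450, 680,
                1630, 1130, 1370, 440, 1920, 1440, 470, 2400, 1320,
                700, 1600)
  stopifnot(length(base_len) == length(kos))
  sym <- names(kos)
  n_genes <- data.frame(
    gene_id = c(paste0(rep(sym, each = 2), "_", rep(1:2, length(sym)))),
    length_bp = as.integer(rep(base_len, each = 2) + rep(c(0L, 90L), length(sym))),
    ko_id = rep(unname(kos), each = 2),
    gene_symbol = rep(sym, each = 2),
    pathway = rep(pathway_of(sym, map), each = 2),
    is_marker = FALSE,
    stringsAsFactors = FALSE
  )
  markers <- data.frame(
    gene_id = sprintf("MG%02d", 1:10),
    length_bp = as.integer(c(1200, 950, 1410, 1820, 1020, 1330, 760,
                             1480, 1110, 1600)),
    ko_id = sprintf("KMG%02d", 1:10),
    gene_symbol = sprintf("MG%02d", 1:10),
    pathway = "unannotated",
    is_marker = TRUE,
    stringsAsFactors = FALSE
  )
  as_gene_catalog(rbind(n_genes, markers))
}

#' Simulate ground-truth per-cell copy numbers for one lake
#'
#' Per-gene copy numbers are drawn log-normally around the tier's
#' per-process mean (divided equally among a symbol's paralogs) with
#' coefficient of variation `cv`; transcripts are copies times the
#' process-level expression rate (study-wide mean transcripts/cell divided
#' by the tier's mean genes/cell). Marker genes are fixed at exactly 1
#' copy and 1 transcript per cell.
#'
#' @param genes_per_cell named per-process mean genes/cell (a tier set).
#' @param transcripts_per_cell named per-process mean transcripts/cell.
#' @param catalog a `gene_catalog` (default [default_catalog()]).
#' @param cv lognormal coefficient of variation across genes and depths,
#'   default 0.3.
#' @param depths sediment layer labels, default `c("05mm", "10mm")`.
#' @param seed RNG seed.
#' @return data.frame `depth`, `gene_id`, `ko_id`, `gene_symbol`,
#'   `process`, `copies_per_cell`, `transcripts_per_cell`.
#' @export
simulate_lake_truth <- function(genes_per_cell, transcripts_per_cell =
                                  TRANSCRIPTS_PER_CELL,
                                catalog = default_catalog(), cv = 0.3,
                                depths = c("05mm", "10mm"), seed) {
  if (missing(seed)) stop("simulate_lake_truth requires a seed")
  set.seed(seed)
  map <- default_pathway_map()
  proc <- pathway_of(catalog$gene_symbol, map)
  proc[catalog$is_marker] <- "marker"
  n_paralog <- ave(seq_len(nrow(catalog)), catalog$gene_symbol,
                   FUN = length)
  sdlog <- sqrt(log(1 + cv^2))
  out <- lapply(depths, function(dep) {
    mu <- ifelse(catalog$is_marker, 1,
                 genes_per_cell[proc] / n_paralog)
    copies <- if (sdlog == 0) mu else
      rlnorm(nrow(catalog), meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    copies[catalog$is_marker] <- 1
    rate <- ifelse(catalog$is_marker, 1,
                   transcripts_per_cell[proc] / genes_per_cell[proc])
    data.frame(depth = dep, gene_id = catalog$gene_id,
               ko_id = catalog$ko_id, gene_symbol = catalog$gene_symbol,
               process = proc, copies_per_cell = copies,
               transcripts_per_cell = copies * rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a meta-omic alignment table from ground truth
#'
#' Inserts are assigned to genes with probability proportional to copy
#' number x gene length (metagenome) or transcript rate x gene length
#' (metatranscriptome). A fraction `f_ambiguous` of inserts whose target
#' has a same-KO paralog is listed against the paralog pair. Identity and
#' aligned-bases fields of passing inserts are drawn above the filter
#' thresholds (identity uniform 95-100, aligned 45-150 bp); a fraction
#' `f_below` of inserts is spiked below the identity threshold
#' (uniform 90-94.9) to exercise the filters.
#'
#' @param truth one depth layer of a [simulate_lake_truth()] table.
#' @param catalog the matching `gene_catalog`.
#' @param layer `"metaG"` (copies) or `"metaT"` (transcripts).
#' @param n_inserts total inserts in the table (including spiked failures).
#' @param f_ambiguous fraction of (eligible) inserts reported against a
#'   same-KO paralog pair, default 0.2.
#' @param f_below fraction of inserts spiked below the identity filter,
#'   default 0.05.
#' @param seed RNG seed.
#' @return data.frame `insert_id`, `gene_id`, `pct_id`, `aligned_bases`.
#' @export
simulate_alignment_table <- function(truth, catalog,
                                     layer = c("metaG", "metaT"),
                                     n_inserts = 1e5, f_ambiguous = 0.2,
                                     f_below = 0.05, seed) {
  layer <- match.arg(layer)
  if (missing(seed)) stop("simulate_alignment_table requires a seed")
  if (nrow(catalog) == 0L) stop("empty catalog")
  stopifnot(n_inserts >= 1, f_ambiguous >= 0, f_ambiguous < 1)
  set.seed(seed)
  idx <- match(truth$gene_id, catalog$gene_id)
  stopifnot(!anyNA(idx))
  len <- catalog$length_bp[idx]
  w <- if (layer == "metaG") truth$copies_per_cell * len else
    truth$transcripts_per_cell * len
  gi <- sample.int(nrow(truth), n_inserts, replace = TRUE, prob = w)
  gene <- truth$gene_id[gi]
  ko <- truth$ko_id[gi]
  insert <- paste0("i", seq_len(n_inserts))
  n_below <- round(f_below * n_inserts)
  below <- seq_len(n_inserts) <= n_below   # first block fails the filter
  pct <- ifelse(below, runif(n_inserts, 90, 94.9), runif(n_inserts, 95, 100))
  alen <- sample(45:150, n_inserts, replace = TRUE)
  tab <- data.frame(insert_id = insert, gene_id = gene, pct_id = pct,
                    aligned_bases = alen, stringsAsFactors = FALSE)
  # paralog of each gene: same KO, other gene id (or NA for singletons)
  sym_genes <- split(catalog$gene_id, catalog$ko_id)
  paralog_of <- unlist(lapply(sym_genes, function(g) {
    if (length(g) == 2L) setNames(rev(g), g) else setNames(rep(NA_character_,
                                                               length(g)), g)
  }), use.names = TRUE)
  names(paralog_of) <- unlist(lapply(sym_genes, identity), use.names = FALSE)
  pl <- paralog_of[gene]
  amb <- runif(n_inserts) < f_ambiguous & !is.na(pl)
  if (any(amb)) {
    extra <- tab[amb, , drop = FALSE]
    extra$gene_id <- unname(pl[amb])
    tab <- rbind(tab, extra)
  }
  rownames(tab) <- NULL
  tab
}

#' Simulate porewater profiles and an O2 microprofile for one lake
#'
#' O2 decays linearly from the bottom-water concentration at the SWI to the
#' archetype's penetration depth on a 0.1 mm grid; NO3 and SO4 decay
#' exponentially from their SWI concentrations with archetype length
#' scales; NH4 saturates toward the archetype asymptote as
#' `A (1 - exp(-z / scale))`. Gaussian noise of sd `noise_sd` (uM) is added
#' and values are truncated at 0; solutes are sampled on
#' [porewater_grid()], where the -1 cm row is the bottom-water sample
#' (NH4 = 0 there).
#'
#' @param archetype one archetype from [default_archetypes()] (possibly
#'   with per-lake jitter applied).
#' @param noise_sd Gaussian noise sd in uM, default 1.
#' @param seed RNG seed.
#' @return list with `porewater` (data.frame `solute`, `depth_cm`,
#'   `conc_uM`) and `microprofile` (data.frame `depth_mm`, `conc_uM`).
#' @export
simulate_porewater <- function(archetype, noise_sd = 1, seed) {
  if (missing(seed)) stop("simulate_porewater requires a seed")
  set.seed(seed)
  grid <- porewater_grid()
  sed <- pmax(grid, 0)   # bottom water behaves like the SWI end-member
  no3 <- archetype$no3_swi_uM * exp(-sed / archetype$no3_scale_cm)
  so4 <- archetype$so4_swi_uM * exp(-sed / archetype$so4_scale_cm)
  nh4 <- archetype$nh4_asymptote_uM * (1 - exp(-sed / archetype$nh4_scale_cm))
  noisy <- function(x) {
    if (noise_sd == 0) return(x)
    pmax(x + rnorm(length(x), 0, noise_sd), 0)
  }
  pw <- rbind(
    data.frame(solute = "NO3", depth_cm = grid, conc_uM = noisy(no3)),
    data.frame(solute = "SO4", depth_cm = grid, conc_uM = noisy(so4)),
    data.frame(solute = "NH4", depth_cm = grid, conc_uM = noisy(nh4))
  )
  zmax <- max(8, archetype$o2_penetration_mm * 1.5)
  z <- seq(0, zmax, by = 0.1)
  o2 <- pmax(archetype$o2_bottom_uM *
               (1 - z / archetype$o2_penetration_mm), 0)
  mp <- data.frame(depth_mm = z,
                   conc_uM = if (noise_sd == 0) o2 else
                     pmax(o2 + rnorm(length(z), 0, noise_sd / 2), 0))
  list(porewater = pw, microprofile = mp)
}

#' Simulate a bulk organic-matter depth profile for one lake
#'
#' TOC, TN, d13C and d15N at 0.5 cm resolution over 0-5 cm around the
#' archetype means; TOC and TN co-vary (shared lognormal factor) so their
#' molar C/N ratio stays near the archetype value, and d13C increases
#' slightly with depth.
#'
#' @param archetype an archetype parameter set.
#' @param noise_cv relative noise on TOC/TN, default 0.05.
#' @param seed RNG seed.
#' @return data.frame `depth_cm`, `TOC_percent`, `TN_percent`,
#'   `d13C_permil`, `d15N_permil`.
#' @export
simulate_bulk_om <- function(archetype, noise_cv = 0.05, seed) {
  if (missing(seed)) stop("simulate_bulk_om requires a seed")
  set.seed(seed)
  z <- seq(0.25, 4.75, by = 0.5)
  sdlog <- sqrt(log(1 + noise_cv^2))
  shared <- rlnorm(length(z), -sdlog^2 / 2, sdlog)
  toc <- archetype$toc_percent * shared *
    rlnorm(length(z), -sdlog^2 / 8, sdlog / 2)
  tn <- archetype$tn_percent * shared *
    rlnorm(length(z), -sdlog^2 / 8, sdlog / 2)
  data.frame(depth_cm = z,
             TOC_percent = toc, TN_percent = tn,
             d13C_permil = archetype$d13C + 0.1 * z + rnorm(length(z), 0, 0.2),
             d15N_permil = archetype$d15N + rnorm(length(z), 0, 0.2))
}

#' Simulate the full 12-lake study
#'
#' Generates, for every lake of [lake_metadata()]: ground-truth per-cell
#' copy numbers for two sediment layers, metagenomic and metatranscriptomic
#' alignment tables per layer, porewater profiles and an O2 microprofile,
#' a bulk OM profile, and lake metadata. Per-lake concentration parameters
#' receive multiplicative lognormal jitter (sd `lake_jitter_sd`) around the
#' archetype values. Deterministic given `seed`.
#'
#' @param config optional list overriding defaults: `n_inserts` (1e5),
#'   `f_ambiguous` (0.2), `f_below` (0.05), `cv` (0.3), `noise_sd` (1),
#'   `lake_jitter_sd` (0.05), `catalog`.
#' @param seed RNG seed (keep below 2^31).
#' @return list of class `benthic_study`: `catalog`, `metadata`, `truth`
#'   (per lake), `alignments` (`$lake$depth$layer`), `porewater`,
#'   `microprofiles`, `bulk_om`, `params`, `seed`. Sample ids are
#'   `<lake>_<depth>`.
#' @export
simulate_study <- function(config = list(), seed = 1) {
  defaults <- list(n_inserts = 1e5, f_ambiguous = 0.2, f_below = 0.05,
                   cv = 0.3, noise_sd = 1, lake_jitter_sd = 0.05,
                   catalog = default_catalog())
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0L) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  catalog <- cfg$catalog
  meta <- lake_metadata()
  arch <- default_archetypes()
  set.seed(seed)
  subseeds <- matrix(sample.int(.Machine$integer.max - 1, nrow(meta) * 8),
                     nrow = nrow(meta))
  jitter_lake <- function(a, sj) {
    for (f in c("no3_swi_uM", "nh4_asymptote_uM", "so4_swi_uM",
                "o2_bottom_uM", "o2_penetration_mm")) {
      a[[f]] <- a[[f]] * rlnorm(1, -sj^2 / 2, sj)
    }
    a
  }
  truth <- list(); alignments <- list(); porewater <- list()
  microprofiles <- list(); bulk_om <- list()
  o2_bottom <- numeric(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    lk <- meta$lake[i]
    a <- arch[[meta$group[i]]]
    tier <- a$gene_tier[[lk]]
    set.seed(subseeds[i, 1])
    a_j <- jitter_lake(a, cfg$lake_jitter_sd)
    o2_bottom[i] <- a_j$o2_bottom_uM
    tr <- simulate_lake_truth(a$genes_per_cell[[tier]],
                              a$transcripts_per_cell, catalog,
                              cv = cfg$cv, seed = subseeds[i, 2])
    truth[[lk]] <- tr
    alignments[[lk]] <- list()
    s <- 3L
    for (dep in unique(tr$depth)) {
      tdep <- tr[tr$depth == dep, , drop = FALSE]
      alignments[[lk]][[dep]] <- list(
        metaG = simulate_alignment_table(tdep, catalog, "metaG",
                                         cfg$n_inserts, cfg$f_ambiguous,
                                         cfg$f_below, seed = subseeds[i, s]),
        metaT = simulate_alignment_table(tdep, catalog, "metaT",
                                         cfg$n_inserts, cfg$f_ambiguous,
                                         cfg$f_below, seed = subseeds[i, s + 1L])
      )
      s <- s + 2L
    }
    prof <- simulate_porewater(a_j, noise_sd = cfg$noise_sd,
                               seed = subseeds[i, 7])
    porewater[[lk]] <- prof$porewater
    microprofiles[[lk]] <- prof$microprofile
    bulk_om[[lk]] <- simulate_bulk_om(a_j, seed = subseeds[i, 8])
  }
  meta$o2_bottom_uM <- o2_bottom
  structure(list(catalog = catalog, metadata = meta, truth = truth,
                 alignments = alignments, porewater = porewater,
                 microprofiles = microprofiles, bulk_om = bulk_om,
                 params = cfg[setdiff(names(cfg), "catalog")], seed = seed),
            class = "benthic_study")
}

#' @export
print.benthic_study <- function(x, ...) {
  cat(sprintf("Synthetic benthic study: %d lakes x %d sediment layers, %d catalog genes, %g inserts/sample (seed %s)\n",
              nrow(x$metadata), length(unique(x$truth[[1]]$depth)),
              nrow(x$catalog), x$params$n_inserts, format(x$seed)))
  invisible(x)
}
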