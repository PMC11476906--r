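---
title: "benthicN: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{benthicN: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthicN)
```

This vignette is the package's own account of the science it implements:
the quantification model and its assumptions, the geochemical flux model,
the permutation statistics, what the synthetic-data generator does and
does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or the analysis
drivers do not themselves compute.

## 1. From alignments to per-cell profiles

The counting unit is the *insert* — the DNA fragment represented by a
merged read pair or an orphan read; each insert counts once regardless of
paired-end status. The chain is:

1. **Alignment filter.** Keep alignments with percent identity ≥ 95 and
   ≥ 45 aligned bases. Both thresholds are inclusive and configurable.
   Whether metatranscriptomic alignments should use the same thresholds is
   not settled; the package assumes they do (one pipeline for both
   layers), and the thresholds can be set per call if not.
2. **Fractional allocation.** An insert with one target gene contributes
   1 to that gene. An insert with several targets distributes 1 across
   them in proportion to the targets' *unique* insert counts. The
   proportions are computed once from the unique counts — a single pass,
   not an EM iteration; with same-KO paralogs the allocation error cancels
   at the KO level anyway. If none of the targets has a unique count the
   insert is split equally (default) or discarded (`zero_unique =
   "discard"`); the equal split keeps the count-conservation invariant
   Σ counts = number of distinct inserts, which the tests check to 1e-9.
   Repeated (insert, gene) rows are deduplicated with a warning.
3. **Length normalization and KO aggregation.** Counts are divided by
   gene length (counts per base) and summed over shared KEGG orthologies.
   Genes without KO are excluded and their mass reported.
4. **Per-cell normalization.** Abundances are divided by the median
   abundance of the 10 universal single-copy marker genes. Because each
   marker occurs once per genome, this median estimates the sequencing
   units contributed per cell, making the values interpretable as copies
   per cell and exactly invariant to sequencing depth (checked to 1e-12
   under deterministic rescaling). The marker median uses the standard
   midpoint median for the even count of 10. Normalization is applied
   after KO aggregation; since each marker is a single gene with its own
   KO, the ratio is unchanged by the order. The identities of the 10
   markers are treated as catalog flags (`is_marker`), not named genes.

**Annotation filter** (for building catalogs from KEGG alignments): keep
hits with subject coverage ≥ 0.70 and bit score ≥ 0.5 × the maximum
expected bit score, then one KO per gene by best bit score, ties broken
lexicographically by KO id for determinism.

## 2. Expression scores and summaries

Expression is `E(k) = metaT_per_cell(k) / metaG_per_cell(k)`, transcripts
per gene copy. Both layers are normalized by their own marker medians;
the wording of per-cell normalization does not distinguish the two, and
normalizing each layer by its own markers is the standard per-cell
reading (the generator fixes markers at 1 transcript/cell, so the metaT
scale is transcripts per cell).

Zeros force three policies, all explicit:

- metaG = 0 with metaT > 0 is *orphan transcription*: reported
  separately, never folded into E.
- `log2_transform()` replaces zeros by half the smallest positive value
  in the table (default), by a pseudocount, or by NA; the policy is
  recorded in the output attributes.
- Pathway summaries average over **all** catalog genes of a process
  (zeros included) for abundance-like inputs, but over **detected**
  entries only for expression-like inputs, mirroring heatmaps where
  missing expression is "not detected" rather than zero. Both views of
  expression (raw ratio and log2) are available; ordination of the
  expression view consumes the raw ratios, i.e. the exponential of the
  log2 scores.

Genes whose KO cannot separate nitrate reductase from nitrite
oxidoreductase (narG;nxrA, narH;nxrB) form a dedicated dual process
"NO3<->NO2" and are never double-counted into nitrification or nitrate
reduction.

**Potential classification.** A lake is "high potential" when its mean
per-cell N-transformation gene abundance strictly exceeds 0.006
genes/cell. The lake mean is the mean over the six process-level means
(averaged over the lake's samples first). This reading is forced by the
printed group values: the low-potential group's four printed process
means already sum to ≈ 0.008, above the 0.006 cutoff, so the rule cannot
apply to a summed total; applied to the across-process mean, the high
group sits at ≈ 0.0075 and the low group at ≈ 0.002, consistent with
both sides of the threshold.

**Anammox completeness.** A sample's anammox pathway is "fully expressed"
when all four genes of the default set {hzsA, hzsB, hzsC, hdh} have
detected transcripts. The four-gene composition is an assumption (the set
size is stated, the membership is not) and is overridable, with a warning
on non-default sets.

## 3. Benthic fluxes

Diffusive fluxes follow Fick's first law for sediments,
`J = -φ · Ds · dC/dz`, with the tortuosity-corrected diffusivity
`Ds = D0 / θ²`, `θ² = 1 - ln(φ²)` (Boudreau). Conventions and defaults:

- Depth is positive downward, SWI at 0; the bottom-water sample sits at
  -1 cm and never enters sediment gradients.
- Gradients: OLS slope of concentration vs depth over the first 3
  porewater points below the SWI (NO₃⁻, NH₄⁺, SO₄²⁻); for O₂, OLS over
  the upper 50 % of the oxic zone of the microsensor profile. Window
  sizes are configurable. A constant profile reports slope 0 with R² = 1
  by convention.
- Units: concentrations in µM (= mmol m⁻³), depths converted to m,
  fluxes in mmol m⁻² d⁻¹ (× 86400). Positive flux = into the sediment,
  so a downward-decreasing oxidant gives J > 0 and accumulating NH₄⁺
  gives J < 0.
- Porosity φ defaults to 0.9 (soft organic-rich lake surface sediment);
  free-solution diffusivities at ~5 °C: O₂ 1.57e-9, NO₃⁻ 9.8e-10, NH₄⁺
  1.04e-9, SO₄²⁻ 5.4e-10 m² s⁻¹. The original flux details live in
  supplementary material unavailable here, so the diffusivity model,
  windows, φ and D0 are all explicit configuration with these stated
  defaults.
- O₂ penetration depth: first linear-interpolated crossing below the
  detection limit (default 1 µM); profiles that never cross are censored
  at the maximum profiled depth; in noisy non-monotone profiles the first
  crossing is taken.

Molar C/N is `(TOC/12.011)/(TN/14.007)` from weight-percent values.

## 4. Community statistics

- **Bray–Curtis** via `vegan::vegdist`; an all-zero sample pair is
  undefined and set to 0 by convention with a warning.
- **NMDS** minimizes Kruskal stress-1 with `vegan::monoMDS` (global
  model) under a multi-start driver: start 1 is the metric (classical
  scaling) configuration, further starts are random. Because increasing
  `restarts` only appends starts to the same seeded stream, stress is
  non-increasing in the number of restarts by construction — a property
  `metaMDS`'s independent random sequences do not guarantee. Output is
  centred and principal-axis rotated, so configurations are unique up to
  reflection.
- **Environmental vector fitting** regresses each (centred) variable on
  the ordination coordinates; r² is the squared multiple correlation and
  the p-value is the fraction of row-shuffling permutations with r² at
  least the observed, with the +1 correction. The statistic is identical
  to `vegan::envfit` (asserted in the tests); the permutation loop is
  vectorized in-package because the calibration tests run a thousand
  fits. Display threshold for "best fitting" variables defaults to
  p < 0.01.
- **BIOENV** searches variable subsets exhaustively (Euclidean distance
  on z-scored variables, Spearman ρ against the community distances),
  returns the full ranking, and refuses budgets beyond 10⁴ subsets.
  Cross-checked against `vegan::bioenv`.
- **PERMANOVA** partitions the squared distances (Gower formulation)
  into between- and within-group sums, with free label permutation.
  Cross-checked against `vegan::adonis2` to 1e-10 on F and R². Note that
  with balanced groups the attainable p-value floor is not 1/(nperm+1):
  permutations preserving the partition reproduce the observed F.
- **Co-expression network**: pairwise Pearson correlations on
  log2-transformed expression profiles, pairwise-complete observations,
  undirected edge where |r| ≥ 0.8 (sign retained; negative co-expression
  is informative). The source description of the cutoff ("correlation
  with a P-value >0.8/≤0.8") is internally inconsistent — 0.8 is not a
  plausible significance level but is a conventional correlation
  threshold — so the package treats it as a correlation-magnitude cutoff,
  configurable, with a p-value mode available. Permutation tests are
  calibrated: under a true null, rejection at α = 0.05 stays within
  [0.03, 0.07] over 1000 replicates (acceptance suite).

## 5. The synthetic study: a stated world

The generator emulates the *statistical structure* of a 12-lake survey —
three archetypes × four lakes, two sediment depths, metagenome +
metatranscriptome per sample, 15-depth porewater grid ({-1 cm bottom
water} ∪ {0.25…2 cm by 0.25} ∪ {2.5…5 cm by 0.5}), 0.1 mm O₂
microprofiles — with every parameter traceable either to a printed value
or to an explicit choice below.

**Printed anchors.** Per-process genes/cell: high-potential tier
(pristine-alpine lakes plus the large-deep CON and NEU) nitrification
0.017, denitrification 0.004, nitrate reduction 0.005, anammox 0.004;
low-potential tier (agriculture-influenced plus GEN and MAG)
nitrification 0.004, denitrification 0.002, nitrate reduction 0.002,
anammox 0.00005. Study-wide transcripts/cell: nitrification 1.2, dual
NO3<->NO2 0.1, denitrification 0.04. O₂ penetration 1.2 mm
(agriculture archetype) vs 4.7 mm (pristine); agriculture NH₄⁺ exceeding
300 µM at 5 cm; pristine NO₃⁻ penetrating beyond 1 cm; lake metadata as
tabulated in `lake_metadata()`.

**Chosen once, a priori** (realistic for the lake types, with margin
analysis against the classification threshold and the printed flux
ranges, and not revisited after testing): dual-process genes/cell
0.012/0.004 (high/low; nxr-carrying nitrite oxidizers are among the more
abundant N-cycle guilds), DNRA 0.002/0.001; transcripts/cell for
unprinted processes (nitrate reduction 0.01, DNRA 0.002, anammox 0.004);
NO₃⁻ at the SWI 120/80/70 µM with decay scales 0.25/1.0/0.6 cm
(agriculture/pristine/large-deep); NH₄⁺ asymptotes 400/100/150 µM with
scales 1.5/2/2 cm; SO₄²⁻ 150 µM with scales 0.5/10/5 cm; bottom-water O₂
100/250/180 µM; bulk OM (TOC 6/1.2/3.5 %, TN 1.0/0.15/0.5 %, δ¹³C
-33/-28/-31 ‰, δ¹⁵N 6/2/4.5 ‰ — giving molar C/N ≈ 7.0/9.3/8.2, a grand
mean near 8). Porewater noise sd 1 µM; per-lake lognormal jitter sd 0.05
on concentration parameters.

**Dispersion and ambiguity models** (inventions, config-exposed): gene
copy numbers are lognormal around the process mean divided by the
symbol's paralog count, CV 0.3; transcripts are copies × a process-level
expression rate (printed transcripts/cell ÷ tier genes/cell); ambiguous
inserts (default fraction 0.2) are listed against same-KO paralog pairs;
insert identity/aligned-bases are uniform 95–100 % / 45–150 bp for
passing reads with a 5 % spiked failure fraction at 90–94.9 % identity
to exercise the filters. Markers are fixed at exactly 1 copy and 1
transcript per cell.

**What the generator does not emulate** — hence what a green test does
not establish: no read-level sequences or sequencing error, no assembly
or gene-prediction artifacts, no compositional coupling between the
N-cycle guilds and the bulk community (markers aside), no reactive
transport (porewater shapes are parametric, not mechanistic), and no
cross-KO mapping ambiguity (paralog pairs only, within KO). Results about
the real study's biology cannot be read off these simulations; results
about the *arithmetic* — conservation, invariances, recovery,
calibration, sign conventions — can.

**Recovery metric.** Accuracy is assessed at the process level (the
per-cell pathway means the analysis reports and classifies on), median
relative error over lake × depth × process. KO-level recovery at 10 %
is unattainable at 10⁵ inserts/sample in a markers-plus-N-genes catalog:
the 10 single-copy markers carry ~99.5 % of the weight, so a KO at the
low tier's anammox abundance (0.00005 genes/cell) expects well under one
insert per sample. The process-level quantity is both the reported one
and the recoverable one.

## 6. Numerical and degenerate-input choices

- All thresholds are inclusive (≥), matching their "at least" wording.
- Fractional allocation ties and KO-assignment ties break
  deterministically (equal split; lexicographic KO).
- Gradient fitting requires ≥ 2 points and positive depth variance;
  per-cell normalization refuses a zero marker median and, by default,
  fewer markers than configured (`allow_partial` downgrades to warning).
- `validate_config()` fills defaults, checks ranges (0 < φ < 1, positive
  thresholds and diffusivities) and requires a seed for every stochastic
  stage before anything executes; unknown keys error in strict mode.
- End-to-end runs are deterministic given (config, seed): reruns produce
  byte-identical numeric outputs (asserted in the tests), and every
  writer rounds at 12 significant digits so TSV round-trips are lossless
  at that precision.

## 7. Known limitations

- Absolute (per-volume) abundances are out of reach without biomass
  data; all quantities are per cell or per gene copy.
- The flux model omits production/consumption terms and
  temperature/salinity corrections of D0 beyond the static defaults; in
  steep near-interface gradients a 3-point OLS window underestimates the
  instantaneous SWI gradient of a curved profile.
- `n = 12` lakes bounds the power of envfit/BIOENV/PERMANOVA; the
  calibration tests establish type-I error, not power.
- The NMDS stress surface is non-convex; the multi-start driver
  guarantees monotonicity in restarts, not the global optimum.
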