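# Porewater and bulk organic-matter computations: concentration gradients,
# Fickian diffusive fluxes, O2 penetration depth, molar C/N ratios and a
# pairwise correlation screen.
#
# Depth is positive downward with the sediment-water interface (SWI) at 0;
# a bottom-water sample sits at negative depth and never enters sediment
# gradients. Concentrations are in uM (= mmol m^-3), depths in cm (porewater)
# or mm (O2 microprofiles); gradients are returned in SI (mmol m^-4).

#' Free-solution diffusion coefficients at 5 degrees C
#'
#' Defaults (m^2 s^-1) for the solutes handled by the flux routines,
#' appropriate for cold lake bottom water (~5 C). Override via the `d0`
#' argument of [fick_flux()] / [flux_table()] or a config file.
#'
#' @return named numeric vector (O2, NO3, NH4, SO4).
#' @export
d0_defaults <- function() {
  c(O2 = 1.57e-9, NO3 = 9.8e-10, NH4 = 1.04e-9, SO4 = 5.4e-10)
}

#' Fit a porewater concentration gradient at the SWI
#'
#' Ordinary least-squares slope of concentration against depth over the
#' first `k` measurement points below the SWI (depth >= 0). The bottom-water
#' point (negative depth) is excluded. Units in: depth cm, concentration uM;
#' the slope is converted to SI, mmol m^-4.
#'
#' @param profile data frame with columns `depth_cm` and `conc_uM`, depths
#'   strictly increasing.
#' @param k number of points in the fit window (default 3).
#' @return list with `slope` (mmol m^-4), `r_squared`, `n`, `window`
#'   (the depths used, cm).
#' @export
fit_gradient <- function(profile, k = 3) {
  stopifnot(all(c("depth_cm", "conc_uM") %in% names(profile)))
  if (is.unsorted(profile$depth_cm, strictly = TRUE))
    stop("depths must be strictly increasing")
  sed <- profile[profile$depth_cm >= 0, , drop = FALSE]
  if (nrow(sed) < 2L) stop("need at least 2 points below the SWI")
  k <- min(k, nrow(sed))
  if (k < 2L) stop("gradient window must hold at least 2 points")
  win <- sed[seq_len(k), , drop = FALSE]
  z_m <- win$depth_cm / 100           # cm -> m
  if (var(z_m) == 0) stop("zero depth variance in gradient window")
  fit <- lm(conc_uM ~ z, data = data.frame(conc_uM = win$conc_uM, z = z_m))
  ssr <- sum(residuals(fit)^2)
  sst <- sum((win$conc_uM - mean(win$conc_uM))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst   # constant profile: R^2 = 1 by convention
  list(slope = unname(coef(fit)[2L]), r_squared = r2, n = k,
       window = win$depth_cm)
}

#' Diffusive benthic flux from a concentration gradient (Fick's first law)
#'
#' Computes `J = -phi * Ds * dC/dz`, with the sediment diffusivity corrected
#' for tortuosity after Boudreau: `Ds = D0 / (1 - ln(phi^2))`. The gradient
#' is in mmol m^-4, `D0` in m^2 s^-1, and the flux is returned in
#' mmol m^-2 d^-1 (x 86400). Sign convention: positive fluxes are directed
#' from the overlying water into the sediment (a solute decreasing with
#' depth, i.e. a negative gradient, gives a positive flux).
#'
#' @param gradient dC/dz in mmol m^-4 (e.g. `fit_gradient()$slope`).
#' @param phi porosity, in (0, 1); default 0.9.
#' @param d0 free-solution diffusion coefficient, m^2 s^-1.
#' @param solute optional solute label carried through to the result.
#' @return list of class `flux_result`: `solute`, `J` (mmol m^-2 d^-1),
#'   `gradient`, `phi`, `d0`, `ds`.
#' @export
fick_flux <- function(gradient, phi = 0.9, d0, solute = NA_character_) {
  if (!is.finite(phi) || phi <= 0 || phi >= 1)
    stop("porosity phi must lie strictly between 0 and 1")
  if (!is.finite(d0) || d0 <= 0) stop("d0 must be positive")
  theta2 <- 1 - log(phi^2)
  ds <- d0 / theta2
  j <- -phi * ds * gradient * 86400
  structure(list(solute = solute, J = j, gradient = gradient,
                 phi = phi, d0 = d0, ds = ds),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("Diffusive flux%s: J = %.3g mmol m^-2 d^-1 (dC/dz = %.3g mmol m^-4, phi = %.2f)\n",
              if (is.na(x$solute)) "" else paste0(" of ", x$solute),
              x$J, x$gradient, x$phi))
  invisible(x)
}

#' Oxygen penetration depth from a microsensor profile
#'
#' First depth at which the O2 concentration falls below the detection
#' limit, linearly interpolated between the bracketing measurement points.
#' If the profile never drops below the limit the maximum profiled depth is
#' returned with `censored = TRUE`. In non-monotone noisy profiles the first
#' crossing is taken.
#'
#' @param profile data frame with columns `depth_mm`, `conc_uM`.
#' @param detection_limit detection limit in uM, default 1.
#' @return list with `depth_mm` and `censored`.
#' @export
o2_penetration <- function(profile, detection_limit = 1) {
  stopifnot(all(c("depth_mm", "conc_uM") %in% names(profile)))
  if (nrow(profile) == 0L) stop("empty O2 profile")
  below <- which(profile$conc_uM < detection_limit)
  if (length(below) == 0L)
    return(list(depth_mm = max(profile$depth_mm), censored = TRUE))
  i <- below[1L]
  if (i == 1L) return(list(depth_mm = profile$depth_mm[1L], censored = FALSE))
  z1 <- profile$depth_mm[i - 1L]; c1 <- profile$conc_uM[i - 1L]
  z2 <- profile$depth_mm[i];      c2 <- profile$conc_uM[i]
  z <- if (c1 == c2) z2 else z1 + (c1 - detection_limit) * (z2 - z1) / (c1 - c2)
  list(depth_mm = z, censored = FALSE)
}

#' O2 gradient over the upper linear part of the oxic zone
#'
#' OLS slope of the microprofile over the upper 50% of the oxic zone
#' (depths in \[0, L/2\] with L the penetration depth), converted to
#' mmol m^-4.
#'
#' @param profile data frame with `depth_mm`, `conc_uM` (depth >= 0).
#' @param detection_limit uM, default 1.
#' @return list as in [fit_gradient()].
#' @export
o2_gradient <- function(profile, detection_limit = 1) {
  pen <- o2_penetration(profile, detection_limit)
  lim <- pen$depth_mm / 2
  win <- profile[profile$depth_mm >= 0 & profile$depth_mm <= lim, , drop = FALSE]
  if (nrow(win) < 2L) stop("fewer than 2 points in the upper oxic zone")
  z_m <- win$depth_mm / 1000          # mm -> m
  fit <- lm(conc ~ z, data = data.frame(conc = win$conc_uM, z = z_m))
  ssr <- sum(residuals(fit)^2)
  sst <- sum((win$conc_uM - mean(win$conc_uM))^2)
  list(slope = unname(coef(fit)[2L]),
       r_squared = if (sst == 0) 1 else 1 - ssr / sst,
       n = nrow(win), window = win$depth_mm)
}

#' Molar C/N ratio of bulk organic matter
#'
#' `(TOC/12.011) / (TN/14.007)` from weight-percent TOC and TN.
#'
#' @param toc_percent total organic carbon, weight percent.
#' @param tn_percent total nitrogen, weight percent (> 0).
#' @return molar C/N ratio (vectorized).
#' @export
cn_molar_ratio <- function(toc_percent, tn_percent) {
  if (any(tn_percent <= 0)) stop("TN must be positive")
  (toc_percent / 12.011) / (tn_percent / 14.007)
}

#' Pairwise Pearson correlation screen across lake-level variables
#'
#' Pearson r with two-sided t-distribution p-values for every variable
#' pair, using pairwise-complete observations. Pairs with fewer than 3
#' complete observations, or with a zero-variance member, are reported as
#' NA with a reason.
#'
#' @param tab data frame or matrix, observations (lakes) x variables.
#' @return data.frame `var1`, `var2`, `r`, `p`, `n`, `note`.
#' @export
correlation_screen <- function(tab) {
  tab <- as.data.frame(tab)
  vars <- names(tab)
  if (length(vars) < 2L) stop("need at least 2 variables")
  pairs <- combn(vars, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    x <- tab[[v1]]; y <- tab[[v2]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3L)
      return(data.frame(var1 = v1, var2 = v2, r = NA_real_, p = NA_real_,
                        n = n, note = "fewer than 3 complete observations"))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(data.frame(var1 = v1, var2 = v2, r = NA_real_, p = NA_real_,
                        n = n, note = "zero variance"))
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = v1, var2 = v2, r = unname(ct$estimate),
               p = ct$p.value, n = n, note = "")
  })
  do.call(rbind, out)
}

#' Benthic flux table for a set of lakes
#'
#' Computes O2 (microprofile, upper-oxic-zone gradient), NO3 and NH4
#' (porewater, first-`k`-points gradient) diffusive fluxes per lake, in the
#' layout of a benthic flux report: one row per lake, positive values into
#' the sediment.
#'
#' @param porewater named list (per lake) of data frames `solute`,
#'   `depth_cm`, `conc_uM`.
#' @param microprofiles named list (per lake) of data frames `depth_mm`,
#'   `conc_uM`.
#' @param groups optional named character vector of lake groups.
#' @param phi porosity.
#' @param d0 named vector of diffusion coefficients, see [d0_defaults()].
#' @param k porewater gradient window size.
#' @param detection_limit O2 detection limit, uM.
#' @return data.frame `lake`, `group`, `J_O2`, `J_NH4`, `J_NO3`,
#'   `o2_penetration_mm`.
#' @export
flux_table <- function(porewater, microprofiles, groups = NULL, phi = 0.9,
                       d0 = d0_defaults(), k = 3, detection_limit = 1) {
  lakes <- names(porewater)
  out <- lapply(lakes, function(lk) {
    pw <- porewater[[lk]]
    j <- setNames(rep(NA_real_, 2), c("NO3", "NH4"))
    for (sol in c("NO3", "NH4")) {
      prof <- pw[pw$solute == sol, c("depth_cm", "conc_uM")]
      if (nrow(prof) >= 2L) {
        g <- fit_gradient(prof, k = k)
        j[sol] <- fick_flux(g$slope, phi = phi, d0 = d0[[sol]], solute = sol)$J
      }
    }
    mp <- microprofiles[[lk]]
    go2 <- o2_gradient(mp, detection_limit)
    jo2 <- fick_flux(go2$slope, phi = phi, d0 = d0[["O2"]], solute = "O2")$J
    pen <- o2_penetration(mp, detection_limit)
    data.frame(lake = lk,
               group = if (is.null(groups)) NA_character_ else groups[[lk]],
               J_O2 = jo2, J_NH4 = j[["NH4"]], J_NO3 = j[["NO3"]],
               o2_penetration_mm = pen$depth_mm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
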