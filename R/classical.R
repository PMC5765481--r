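# Classical (non-Bayesian) TEE estimation and method comparison.

#' Classical TEE estimate for one subject
#'
#' Fits both isotope curves with the chosen flavour, then derives CO2
#' production either from the natural (fitted) spaces via the Coward
#' equation, or from normalized spaces via the Schoeller equation, and
#' converts to TEE with the modified Weir equation at the constants' RQ.
#' Normalization rescales only the pool sizes; the fitted rate constants are
#' untouched.
#'
#' @param subject a [subject_record()].
#' @param method `"exponential"` (default), `"logarithmic"` or `"poisson"`.
#' @param normalize `"none"` (natural spaces, Coward equation),
#'   `"schoeller"` (ratio fixed at 1.03) or `"iaea"` (ratio 1.034).
#' @param constants a [dlw_constants()].
#' @return an object of class `dlw_tee`: a list with `tee` (kJ/day), `rco2`
#'   (mol/day), `S_natural`, `S_used`, the natural and analysis
#'   [kinetic_params()] (`kin_natural`, `kin_used`), the two `dlw_fit`
#'   objects, and `flags`, a character vector of quality warnings
#'   (`"S_outside_screen"` when the natural ratio falls outside the
#'   1.015-1.060 acceptability band; `"k_order_invalid"` when the fitted
#'   k_O does not exceed k_H).
#' @export
classical_tee <- function(subject,
                          method = c("exponential", "logarithmic", "poisson"),
                          normalize = c("none", "schoeller", "iaea"),
                          constants = dlw_constants()) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  fitter <- switch(method,
                   exponential = fit_exponential,
                   logarithmic = fit_logarithmic,
                   poisson     = fit_poisson)
  fit_H <- fitter(subject$curves[["2H"]], subject$doses[["2H"]], constants)
  fit_O <- fitter(subject$curves[["18O"]], subject$doses[["18O"]], constants)
  kin_nat <- kinetic_params(N_H = fit_H$N, N_O = fit_O$N,
                            k_H = fit_H$k, k_O = fit_O$k)
  S_nat <- kin_nat$N_H / kin_nat$N_O
  flags <- character(0)
  if (S_nat < constants$s_screen[1] || S_nat > constants$s_screen[2])
    flags <- c(flags, "S_outside_screen")
  if (kin_nat$k_O <= kin_nat$k_H)
    flags <- c(flags, "k_order_invalid")
  if (normalize == "none") {
    kin_used <- kin_nat
    rco2 <- rco2_coward(kin_nat, constants)
  } else {
    corr <- switch(normalize,
                   schoeller = normalize_spaces_schoeller(kin_nat$N_H, kin_nat$N_O, constants),
                   iaea      = normalize_spaces_iaea(kin_nat$N_H, kin_nat$N_O, constants))
    kin_used <- kinetic_params(N_H = corr$N_H, N_O = corr$N_O,
                               k_H = kin_nat$k_H, k_O = kin_nat$k_O)
    rco2 <- rco2_schoeller(kin_used, constants)
  }
  structure(list(
    id = subject$id, method = method, normalize = normalize,
    tee = weir_tee(rco2, constants$RQ), rco2 = rco2,
    S_natural = S_nat, S_used = kin_used$N_H / kin_used$N_O,
    kin_natural = kin_nat, kin_used = kin_used,
    # computed directly: flagged subjects may fall outside the physio domain
    fat_fraction = 1 - (constants$gamma1 * kin_nat$N_H +
                          constants$gamma2 * kin_nat$N_O) / subject$weight_kg,
    fit_H = fit_H, fit_O = fit_O, flags = flags
  ), class = "dlw_tee")
}

#' @export
print.dlw_tee <- function(x, ...) {
  cat(sprintf("Subject %s (%s fit, normalize=%s): TEE = %.0f kJ/day, rCO2 = %.2f mol/day, S = %.4f%s\n",
              x$id, x$method, x$normalize, x$tee, x$rco2, x$S_natural,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Approximate coefficient of variation of a classical TEE estimate
#'
#' First-order (delta-method) propagation of the per-isotope fit
#' uncertainties into the Coward-equation CO2 production.  The two isotope
#' fits are treated as independent; within each isotope the full fitted
#' `(N, k)` covariance is used.  Because TEE is proportional to rCO2 at
#' fixed RQ, the CV of TEE equals the CV of rCO2.
#'
#' @param fit_H,fit_O `dlw_fit` objects for 2H and 18O.
#' @param constants a [dlw_constants()].
#' @return the CV as a fraction (multiply by 100 for percent).
#' @export
propagate_error <- function(fit_H, fit_O, constants = dlw_constants()) {
  for (f in list(fit_H, fit_O))
    if (any(!is.finite(f$vcov_Nk)))
      stop("fit does not carry standard errors (too few residual degrees of freedom)")
  # variance of the flux x = k*N from the (N, k) covariance
  var_flux <- function(f) {
    g <- c(f$k, f$N)   # dx/dN, dx/dk
    as.numeric(t(g) %*% f$vcov_Nk %*% g)
  }
  kin <- kinetic_params(N_H = fit_H$N, N_O = fit_O$N,
                        k_H = fit_H$k, k_O = fit_O$k)
  rco2 <- rco2_coward(kin, constants)
  denom <- 2 * constants$f3 + constants$coward_scale * (constants$f2 - constants$f1)
  sd_rco2 <- sqrt(var_flux(fit_H) + var_flux(fit_O)) / denom
  sd_rco2 / rco2
}

#' Bland-Altman agreement statistics for paired TEE series
#'
#' Differences are taken as `b - a`; limits of agreement are
#' `mean(diff) +/- 1.96 * sd(diff)`, and the slope is the least-squares
#' slope of the differences on the pair means (a nonzero slope indicates
#' magnitude-dependent disagreement, e.g. hierarchical shrinkage).
#'
#' @param a,b paired numeric series (same length, n >= 3), kJ/day.
#' @return an object of class `dlw_bland_altman` with `n`, `mean_diff`,
#'   `median_diff`, `sd_diff`, `loa_lower`, `loa_upper`, `slope`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("at least 3 complete pairs required")
  d <- b - a
  m <- (a + b) / 2
  sd_d <- stats::sd(d)
  slope <- if (stats::var(m) > 0) unname(stats::coef(stats::lm(d ~ m))[2]) else 0
  structure(list(
    n = length(a),
    mean_diff = mean(d), median_diff = stats::median(d), sd_diff = sd_d,
    loa_lower = mean(d) - 1.96 * sd_d, loa_upper = mean(d) + 1.96 * sd_d,
    slope = slope
  ), class = "dlw_bland_altman")
}

#' @export
print.dlw_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n=%d): median diff %.0f, mean diff %.0f, LoA [%.0f, %.0f], slope %.3f\n",
              x$n, x$median_diff, x$mean_diff, x$loa_lower, x$loa_upper, x$slope))
  invisible(x)
}
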