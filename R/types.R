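#' Isotope enrichment time series
#'
#' One isotope's post-dose enrichment curve: times in days post-dose, the
#' measured enrichments delta(t) in per mil vs VSMOW, and the pre-dose
#' (basal) enrichment delta_b.
#'
#' @param isotope `"2H"` or `"18O"`.
#' @param times days post-dose, non-negative, strictly increasing.
#' @param deltas enrichment in per mil vs VSMOW, same length as `times`.
#' @param basal pre-dose enrichment, per mil vs VSMOW.
#' @return object of class `isotope_curve`.
#' @export
isotope_curve <- function(isotope = c("2H", "18O"), times, deltas, basal) {
  isotope <- match.arg(isotope)
  times <- as.numeric(times); deltas <- as.numeric(deltas)
  basal <- as.numeric(basal)
  if (length(times) != length(deltas))
    stop("times and deltas must have equal length")
  if (length(times) < 1L) stop("at least one timepoint required")
  if (any(!is.finite(times)) || any(!is.finite(deltas)) || !is.finite(basal))
    stop("non-finite values in isotope curve")
  if (any(times < 0)) stop("times must be non-negative (days post-dose)")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  structure(list(isotope = isotope, times = times, deltas = deltas,
                 basal = basal),
            class = "isotope_curve")
}

#' Dose preparation record
#'
#' Masses and enrichments describing the administered dose and its diluted
#' aliquot, needed to convert the curve intercept into a pool size: the
#' subject received `dose_g` grams; `aliquot_g` grams of the same dose water
#' were diluted into `tapwater_g` grams of water of enrichment `delta_tap`,
#' giving the measured diluted-dose enrichment `delta_dd`.
#'
#' @param dose_g dose administered to the subject, g.
#' @param aliquot_g dose aliquot diluted for measurement, g.
#' @param tapwater_g mass of dilution water, g.
#' @param delta_dd enrichment of the diluted dose, per mil.
#' @param delta_tap enrichment of the dilution water, per mil.
#' @return object of class `dose_prep`.
#' @export
dose_prep <- function(dose_g, aliquot_g, tapwater_g, delta_dd, delta_tap) {
  vals <- c(dose_g = dose_g, aliquot_g = aliquot_g, tapwater_g = tapwater_g)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("dose_g, aliquot_g and tapwater_g must be positive")
  if (!is.finite(delta_dd) || !is.finite(delta_tap))
    stop("non-finite dose enrichments")
  if (delta_dd <= delta_tap)
    stop("delta_dd must exceed delta_tap (the dose must be enriched)")
  structure(list(dose_g = dose_g, aliquot_g = aliquot_g,
                 tapwater_g = tapwater_g, delta_dd = delta_dd,
                 delta_tap = delta_tap),
            class = "dose_prep")
}

#' One subject's DLW record
#'
#' @param id subject identifier (coerced to character).
#' @param sex `"F"` or `"M"`.
#' @param weight_kg body weight W, kg, positive.
#' @param doses named list with elements `"2H"` and `"18O"`, each a
#'   [dose_prep()].
#' @param curves named list with elements `"2H"` and `"18O"`, each an
#'   [isotope_curve()] of the matching isotope.
#' @return object of class `subject_record`.
#' @export
subject_record <- function(id, sex = c("F", "M"), weight_kg, doses, curves) {
  sex <- match.arg(sex)
  if (!is.finite(weight_kg) || weight_kg <= 0) stop("weight_kg must be positive")
  for (iso in c("2H", "18O")) {
    if (is.null(doses[[iso]]) || !inherits(doses[[iso]], "dose_prep"))
      stop("doses must contain a dose_prep for isotope ", iso)
    if (is.null(curves[[iso]]) || !inherits(curves[[iso]], "isotope_curve"))
      stop("curves must contain an isotope_curve for isotope ", iso)
    if (curves[[iso]]$isotope != iso)
      stop("curve stored under ", iso, " is labelled ", curves[[iso]]$isotope)
  }
  structure(list(id = as.character(id), sex = sex, weight_kg = weight_kg,
                 doses = doses[c("2H", "18O")], curves = curves[c("2H", "18O")]),
            class = "subject_record")
}

#' Kinetic parameters (pool sizes and elimination rate constants)
#'
#' @param N_H,N_O dilution spaces (pool sizes) of 2H and 18O, mol.
#' @param k_H,k_O first-order elimination rate constants, per day.
#' @return object of class `kinetic_params`.  Values must be strictly
#'   positive; `k_O <= k_H` is physiologically invalid for DLW and is left
#'   to callers to flag (it is not rejected here, so that noisy fits can be
#'   represented).
#' @export
kinetic_params <- function(N_H, N_O, k_H, k_O) {
  N_H <- unname(N_H); N_O <- unname(N_O)
  k_H <- unname(k_H); k_O <- unname(k_O)
  v <- c(N_H = N_H, N_O = N_O, k_H = k_H, k_O = k_O)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("kinetic parameters must be finite and strictly positive")
  structure(as.list(v), class = "kinetic_params")
}

#' Physiological parameters of the DLW model
#'
#' The four parameters of the re-parameterized model: CO2 production rate
#' `rco2` (mol/day), dilution-space ratio `S = N_H/N_O`, water turnover
#' `R_W` (mol/day) and body-fat fraction `F`.
#'
#' @param rco2 CO2 production, mol/day, in (0, 100).
#' @param S space ratio, dimensionless, positive.
#' @param R_W water turnover, mol/day, in (0, 1000).
#' @param F_fat body-fat fraction in (0, 1).
#' @return object of class `physio_params`.
#' @export
physio_params <- function(rco2, S, R_W, F_fat) {
  rco2 <- unname(rco2); S <- unname(S); R_W <- unname(R_W)
  F_fat <- unname(F_fat)
  v <- c(rco2 = rco2, S = S, R_W = R_W, F = F_fat)
  if (any(!is.finite(v))) stop("physiological parameters must be finite")
  if (rco2 <= 0 || rco2 >= 100) stop("rco2 must lie in (0, 100) mol/day")
  if (R_W <= 0 || R_W >= 1000) stop("R_W must lie in (0, 1000) mol/day")
  if (F_fat <= 0 || F_fat >= 1) stop("F must lie in (0, 1)")
  if (S <= 0) stop("S must be positive")
  structure(list(rco2 = rco2, S = S, R_W = R_W, F = F_fat),
            class = "physio_params")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("DLW subject %s (%s, %.1f kg): %d x 2H and %d x 18O timepoints\n",
              x$id, x$sex, x$weight_kg,
              length(x$curves[["2H"]]$times), length(x$curves[["18O"]]$times)))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("N_H = %.1f mol, N_O = %.1f mol, k_H = %.4f /day, k_O = %.4f /day (S = %.4f)\n",
              x$N_H, x$N_O, x$k_H, x$k_O, x$N_H / x$N_O))
  invisible(x)
}

#' @export
print.physio_params <- function(x, ...) {
  cat(sprintf("rCO2 = %.2f mol/day, S = %.4f, R_W = %.1f mol/day, F = %.3f\n",
              x$rco2, x$S, x$R_W, x$F))
  invisible(x)
}
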