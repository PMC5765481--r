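# CO2 production equations and dilution-space normalization algebra.

#' CO2 production from natural (non-normalized) spaces: Coward's equation
#'
#' `rCO2 = (kO*NO - kH*NH - 27.3*(f2 - f1)) / (2*f3 + 1.1*(f2 - f1))`,
#' for use with the pool sizes as fitted (natural spaces).
#'
#' @param kin a [kinetic_params()].
#' @param constants a [dlw_constants()].
#' @return CO2 production, mol/day.
#' @export
rco2_coward <- function(kin, constants = dlw_constants()) {
  cc <- constants
  fdiff <- cc$f2 - cc$f1
  (kin$k_O * kin$N_O - kin$k_H * kin$N_H - cc$coward_offset * fdiff) /
    (2 * cc$f3 + cc$coward_scale * fdiff)
}

#' CO2 production from normalized spaces: the Schoeller equation
#'
#' `rCO2 = (kO*NO - kH*NH) / (2*f3 + 2.1*(f2 - f1))`, for pool sizes that
#' have been normalized to a fixed space ratio (see
#' [normalize_spaces_schoeller()] and [normalize_spaces_iaea()]).
#'
#' @inheritParams rco2_coward
#' @return CO2 production, mol/day.
#' @export
rco2_schoeller <- function(kin, constants = dlw_constants()) {
  cc <- constants
  (kin$k_O * kin$N_O - kin$k_H * kin$N_H) /
    (2 * cc$f3 + cc$schoeller_scale * (cc$f2 - cc$f1))
}

#' Normalize dilution spaces to a fixed ratio of 1.03 (Schoeller)
#'
#' Weights the observed spaces so the corrected ratio is exactly 1.03:
#' `N_H_corr = (N_H_obs + 1.03*N_O_obs)/2`,
#' `N_O_corr = (N_H_obs/1.03 + N_O_obs)/2`.
#'
#' @param N_H_obs,N_O_obs observed (fitted) dilution spaces, mol, positive.
#'   Vectorized.
#' @param constants a [dlw_constants()] (supplies the 1.03 target).
#' @return named list with `N_H` and `N_O`, the corrected spaces.
#' @export
normalize_spaces_schoeller <- function(N_H_obs, N_O_obs,
                                       constants = dlw_constants()) {
  if (any(N_H_obs <= 0) || any(N_O_obs <= 0))
    stop("observed spaces must be positive")
  r <- constants$ratio_schoeller
  list(N_H = (N_H_obs + r * N_O_obs) / 2,
       N_O = (N_H_obs / r + N_O_obs) / 2)
}

#' Normalize dilution spaces to a ratio of 1.034 (IAEA)
#'
#' The IAEA convention rescales the mean of the individually corrected pools
#' by each isotope's overestimation factor:
#' `N_H_corr = 1.041 * (N_H_obs/1.041 + N_O_obs/1.007) / 2`,
#' `N_O_corr = 1.007 * (N_H_obs/1.041 + N_O_obs/1.007) / 2`,
#' which fixes the corrected ratio at 1.041/1.007 = 1.034 (3 d.p.).
#'
#' @inheritParams normalize_spaces_schoeller
#' @return named list with `N_H` and `N_O`, the corrected spaces.
#' @export
normalize_spaces_iaea <- function(N_H_obs, N_O_obs,
                                  constants = dlw_constants()) {
  if (any(N_H_obs <= 0) || any(N_O_obs <= 0))
    stop("observed spaces must be positive")
  rH <- constants$ratio_iaea_H; rO <- constants$ratio_iaea_O
  inner <- (N_H_obs / rH + N_O_obs / rO) / 2
  list(N_H = rH * inner, N_O = rO * inner)
}

#' Predicted TEE change from normalizing the space ratio
#'
#' Since TEE is linear in the isotope flux difference,
#' `TEE = lambda*(kO - S*kH)*NO + mu` with `lambda = 532.26*alpha1` and
#' `mu = 532.26*alpha2` (at RQ = 0.85), replacing the natural ratio
#' `S = N_H/N_O` by a target `S'` (which rescales
#' `N_O' = (S/S' + 1)/2 * N_O`) shifts the estimate by
#' \deqn{TEE' - TEE = \lambda (S/S' - 1) \frac{k_O + S' k_H}{2} N_O.}
#' The bracketed term approximates the average of the two isotope fluxes, so
#' the shift is nearly proportional to `S - S'` in a population:
#' normalization lowers TEE for subjects whose natural ratio is below the
#' target and raises it above.
#'
#' @param kin a [kinetic_params()] with natural (fitted) spaces.
#' @param S_target the normalization target ratio S'.
#' @param constants a [dlw_constants()].
#' @return the TEE shift (normalized minus natural), kJ/day.
#' @export
normalization_tee_shift <- function(kin, S_target,
                                    constants = dlw_constants()) {
  if (S_target <= 0) stop("S_target must be positive")
  S <- kin$N_H / kin$N_O
  lam <- weir_lambda(constants)
  lam * (S / S_target - 1) * (kin$k_O + S_target * kin$k_H) / 2 * kin$N_O
}
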