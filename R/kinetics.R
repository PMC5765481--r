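# Forward kinetic model and the kinetic <-> physiological transformations.

# Intercept numerator D*T*(delta_dd - delta_tap)/(18.02*d): dividing by the
# pool size N gives the t=0 excess enrichment above basal, in per mil.
dose_factor <- function(dose, constants = dlw_constants()) {
  dose$dose_g * dose$tapwater_g * (dose$delta_dd - dose$delta_tap) /
    (constants$water_molar_mass * dose$aliquot_g)
}

#' Predicted isotope enrichment under first-order elimination
#'
#' Single-pool, first-order kinetics: the enrichment at `t` days post-dose is
#' `delta(t) = D*T*(delta_dd - delta_tap) / (18.02 * N * d) * exp(-k*t) + delta_b`,
#' where the first factor is the initial excess enrichment implied by the
#' dose preparation and the pool size.
#'
#' @param t days post-dose (vectorized, non-negative).
#' @param dose a [dose_prep()].
#' @param N pool size, mol, positive.
#' @param k elimination rate constant, per day, non-negative.
#' @param basal pre-dose enrichment delta_b, per mil.
#' @param constants a [dlw_constants()].
#' @return predicted enrichment(s), per mil vs VSMOW.
#' @export
#' @examples
#' d <- dose_prep(100, 5, 495, 1000, -7)
#' enrichment_at(c(0, 7, 14), d, N = 2500, k = 0.11, basal = -7)
enrichment_at <- function(t, dose, N, k, basal, constants = dlw_constants()) {
  if (any(t < 0)) stop("t must be non-negative")
  if (!is.finite(N) || N <= 0) stop("pool size N must be positive")
  if (!is.finite(k) || k < 0) stop("rate constant k must be non-negative")
  dose_factor(dose, constants) / N * exp(-k * t) + basal
}

#' Physiological parameters from kinetic parameters
#'
#' Maps pool sizes and rate constants to the four physiological parameters:
#' \deqn{rCO2 = \alpha_1 (k_O N_O - k_H N_H) + \alpha_2}
#' \deqn{S = N_H / N_O}
#' \deqn{R_W = \beta_1 k_H N_H + (1-\beta_1) k_O N_O + \beta_2}
#' \deqn{F = 1 - (\gamma_1 N_H + \gamma_2 N_O) / W}
#'
#' @param kin a [kinetic_params()].
#' @param weight_kg body weight W, kg.
#' @param constants a [dlw_constants()].
#' @return a [physio_params()].
#' @export
physio_from_kinetic <- function(kin, weight_kg, constants = dlw_constants()) {
  if (!is.finite(weight_kg) || weight_kg <= 0) stop("weight_kg must be positive")
  cc <- constants
  rco2 <- cc$alpha1 * (kin$k_O * kin$N_O - kin$k_H * kin$N_H) + cc$alpha2
  S <- kin$N_H / kin$N_O
  rw <- cc$beta1 * kin$k_H * kin$N_H + (1 - cc$beta1) * kin$k_O * kin$N_O + cc$beta2
  Ffat <- 1 - (cc$gamma1 * kin$N_H + cc$gamma2 * kin$N_O) / weight_kg
  physio_params(rco2, S, rw, Ffat)
}

#' Kinetic parameters from physiological parameters
#'
#' The algebraic inverse of [physio_from_kinetic()]:
#' \deqn{N_O = W (1 - F) / (\gamma_1 S + \gamma_2), \quad N_H = S N_O}
#' and, writing \eqn{\Delta = (rCO2 - \alpha_2)/\alpha_1} for the flux
#' difference \eqn{k_O N_O - k_H N_H},
#' \deqn{k_H N_H = R_W - \beta_2 - (1 - \beta_1)\Delta, \quad
#'       k_O N_O = R_W - \beta_2 + \beta_1 \Delta.}
#' This lets the Bayesian model sample physiological parameters from their
#' priors and predict the observed kinetics.
#'
#' @inheritParams physio_from_kinetic
#' @param phys a [physio_params()].
#' @return a [kinetic_params()]; errors if the parameters imply a
#'   non-positive pool size or rate constant.
#' @export
kinetic_from_physio <- function(phys, weight_kg, constants = dlw_constants()) {
  if (!is.finite(weight_kg) || weight_kg <= 0) stop("weight_kg must be positive")
  cc <- constants
  denom <- cc$gamma1 * phys$S + cc$gamma2
  if (denom <= 0) stop("gamma1*S + gamma2 must be positive")
  N_O <- weight_kg * (1 - phys$F) / denom
  N_H <- phys$S * N_O
  delta_flux <- (phys$rco2 - cc$alpha2) / cc$alpha1
  flux_H <- phys$R_W - cc$beta2 - (1 - cc$beta1) * delta_flux
  flux_O <- phys$R_W - cc$beta2 + cc$beta1 * delta_flux
  if (flux_H <= 0 || flux_O <= 0)
    stop("parameters imply a non-positive isotope flux")
  kinetic_params(N_H = N_H, N_O = N_O, k_H = flux_H / N_H, k_O = flux_O / N_O)
}
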