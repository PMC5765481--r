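# Likelihood of the observed enrichments under the re-parameterized model.

# Fast closure over one subject's data: takes theta = c(rco2, S, R_W, F)
# and returns the Gaussian log-likelihood (including normalizing constants),
# or -Inf when theta implies invalid kinetics.
make_subject_loglik <- function(subject, priors = prior_spec(),
                                constants = dlw_constants()) {
  cc <- constants
  W <- subject$weight_kg
  a1 <- cc$alpha1; a2 <- cc$alpha2
  b1 <- cc$beta1;  b2 <- cc$beta2
  g1 <- cc$gamma1; g2 <- cc$gamma2
  cH <- subject$curves[["2H"]];  cO <- subject$curves[["18O"]]
  CH <- dose_factor(subject$doses[["2H"]], cc)
  CO <- dose_factor(subject$doses[["18O"]], cc)
  sdH <- priors$noise_sd[["2H"]]; sdO <- priors$noise_sd[["18O"]]
  tH <- cH$times; yH <- cH$deltas; bH <- cH$basal
  tO <- cO$times; yO <- cO$deltas; bO <- cO$basal
  lconst <- -length(tH) * log(sdH * sqrt(2 * pi)) -
    length(tO) * log(sdO * sqrt(2 * pi))
  function(theta) {
    S <- theta[2]; Ff <- theta[4]
    denom <- g1 * S + g2
    if (denom <= 0 || Ff >= 1) return(-Inf)
    NO <- W * (1 - Ff) / denom
    NH <- S * NO
    if (NO <= 0 || NH <= 0) return(-Inf)
    dflux <- (theta[1] - a2) / a1
    fH <- theta[3] - b2 - (1 - b1) * dflux
    fO <- theta[3] - b2 + b1 * dflux
    if (fH <= 0 || fO <= 0) return(-Inf)
    predH <- CH / NH * exp(-(fH / NH) * tH) + bH
    predO <- CO / NO * exp(-(fO / NO) * tO) + bO
    lconst - 0.5 * (sum(((yH - predH) / sdH)^2) + sum(((yO - predO) / sdO)^2))
  }
}

theta_from_phys <- function(phys) {
  if (inherits(phys, "physio_params"))
    c(phys$rco2, phys$S, phys$R_W, phys$F)
  else {
    stopifnot(all(c("rco2", "S", "R_W", "F") %in% names(phys)))
    unname(phys[c("rco2", "S", "R_W", "F")])
  }
}

# log prior density of theta (unnormalized for the uniform components)
log_prior_theta <- function(theta, priors) {
  if (theta[1] <= priors$rco2_range[1] || theta[1] >= priors$rco2_range[2] ||
      theta[3] <= priors$rw_range[1]   || theta[3] >= priors$rw_range[2] ||
      theta[4] <= priors$f_range[1]    || theta[4] >= priors$f_range[2])
    return(-Inf)
  stats::dnorm(theta[2], priors$s_mean, priors$s_sd, log = TRUE)
}

#' Log-likelihood of one subject's enrichments given physiological parameters
#'
#' Maps the physiological parameters to kinetic ones, predicts every observed
#' enrichment under first-order elimination, and sums independent Gaussian
#' log-densities with the isotope-specific measurement sds from `priors`.
#' Parameters outside the prior support (or implying invalid kinetics)
#' return `-Inf` rather than raising an error, so samplers can reject them.
#'
#' @param subject a [subject_record()].
#' @param phys a [physio_params()] or a named numeric vector with elements
#'   `rco2`, `S`, `R_W`, `F`.
#' @param priors a [prior_spec()] (supplies the noise sds and supports).
#' @param constants a [dlw_constants()].
#' @return the log-likelihood (a scalar, possibly `-Inf`).
#' @export
log_likelihood <- function(subject, phys, priors = prior_spec(),
                           constants = dlw_constants()) {
  theta <- theta_from_phys(phys)
  if (!is.finite(log_prior_theta(theta, priors))) return(-Inf)
  make_subject_loglik(subject, priors, constants)(theta)
}
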