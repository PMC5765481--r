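# Prior and MCMC configuration containers.

#' Priors for the per-subject (independent) Bayesian model
#'
#' Vague uniform priors on CO2 production, water turnover and fat fraction,
#' an informative normal prior on the dilution-space ratio, and fixed
#' measurement-noise standard deviations for the two isotopes:
#' `rCO2 ~ U(0, 100)` mol/day, `R_W ~ U(0, 1000)` mol/day, `F ~ U(0, 1)`,
#' `S ~ N(1.035, sd 0.01)` (precision 10000), noise sd 2 per mil for 2H and
#' 0.5 per mil for 18O.
#'
#' @param rco2_range,rw_range,f_range uniform prior supports.
#' @param s_mean,s_sd normal prior on the space ratio.
#' @param noise_sd named vector of measurement sds (per mil) for `"2H"` and
#'   `"18O"`.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(rco2_range = c(0, 100), rw_range = c(0, 1000),
                       f_range = c(0, 1), s_mean = 1.035, s_sd = 0.01,
                       noise_sd = c("2H" = 2, "18O" = 0.5)) {
  stopifnot(diff(rco2_range) > 0, diff(rw_range) > 0, diff(f_range) > 0,
            s_sd > 0, all(noise_sd > 0),
            all(c("2H", "18O") %in% names(noise_sd)))
  structure(list(rco2_range = rco2_range, rw_range = rw_range,
                 f_range = f_range, s_mean = s_mean, s_sd = s_sd,
                 noise_sd = noise_sd),
            class = "prior_spec")
}

#' Priors for the hierarchical (population) Bayesian model
#'
#' Individual parameters are drawn from normal population distributions
#' `theta_i ~ N(mu, 1/tau)`.  The population precisions have
#' `tau ~ Gamma(0.01, 0.01)` for rCO2, R_W and F, and
#' `tau_S ~ U(1, 100000)` for the space ratio (reflecting the richer prior
#' information for S).  Hypermeans take the same vague priors as the
#' per-subject model in `base` (including the informative normal on the
#' space-ratio hypermean).
#'
#' @param base a [prior_spec()] supplying hypermean priors and noise sds.
#' @param tau_shape,tau_rate Gamma hyperprior on the precisions of rCO2,
#'   R_W and F.
#' @param tau_s_range uniform hyperprior support for the precision of S.
#' @return object of class `hier_prior_spec`.
#' @export
hier_prior_spec <- function(base = prior_spec(), tau_shape = 0.01,
                            tau_rate = 0.01, tau_s_range = c(1, 1e5)) {
  stopifnot(inherits(base, "prior_spec"), tau_shape > 0, tau_rate > 0,
            diff(tau_s_range) > 0, tau_s_range[1] > 0)
  structure(c(unclass(base),
              list(tau_shape = tau_shape, tau_rate = tau_rate,
                   tau_s_range = tau_s_range)),
            class = c("hier_prior_spec", "prior_spec"))
}

#' MCMC configuration
#'
#' @param iterations total iterations per chain (default 50000).
#' @param burnin initial iterations discarded (default 4000); proposal
#'   scales adapt only during burn-in, preserving detailed balance in the
#'   retained draws.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of chains (default 2; use 1 for single-chain runs).
#' @param seed integer seed; chain `c` uses `seed + c - 1`.  `NULL` leaves
#'   the RNG state untouched (not reproducible).
#' @param proposal_scale optional named vector of initial random-walk sds
#'   for `rco2`, `S`, `R_W`, `F`.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 50000, burnin = 4000, thin = 1,
                        chains = 2, seed = NULL, proposal_scale = NULL) {
  stopifnot(iterations > burnin, burnin >= 0, thin >= 1, chains >= 1)
  if (!is.null(seed)) stopifnot(is.finite(seed))
  default_scale <- c(rco2 = 2, S = 0.01, R_W = 20, F = 0.05)
  if (!is.null(proposal_scale)) {
    stopifnot(all(names(proposal_scale) %in% names(default_scale)),
              all(proposal_scale > 0))
    default_scale[names(proposal_scale)] <- proposal_scale
  }
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 chains = as.integer(chains), seed = seed,
                 proposal_scale = default_scale),
            class = "mcmc_config")
}
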