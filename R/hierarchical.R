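# Hierarchical (population) sampler: Metropolis-within-Gibbs.  Individual
# parameters are updated by component-wise random-walk Metropolis against
# likelihood x N(mu, 1/tau); the hypermeans and precisions have conjugate
# full conditionals and are updated by exact Gibbs draws.

rtrunc_norm1 <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  if (phi - plo < 1e-12)   # far tail: pin at the nearest bound
    return(min(max(mean, lo), hi))
  u <- stats::runif(1, plo, phi)
  min(max(mean + sd * stats::qnorm(u), lo), hi)
}

rtrunc_gamma1 <- function(shape, rate, lo, hi) {
  plo <- stats::pgamma(lo, shape, rate)
  phi <- stats::pgamma(hi, shape, rate)
  if (phi - plo < 1e-12) {
    mode <- if (shape >= 1) (shape - 1) / rate else lo
    return(min(max(mode, lo), hi))
  }
  u <- stats::runif(1, plo, phi)
  min(max(stats::qgamma(u, shape, rate), lo), hi)
}

hier_log_prior <- function(theta, mu, tau, priors) {
  if (theta[1] <= priors$rco2_range[1] || theta[1] >= priors$rco2_range[2] ||
      theta[3] <= priors$rw_range[1]   || theta[3] >= priors$rw_range[2] ||
      theta[4] <= priors$f_range[1]    || theta[4] >= priors$f_range[2])
    return(-Inf)
  sum(stats::dnorm(theta, mu, 1 / sqrt(tau), log = TRUE))
}

#' Hierarchical Bayesian estimation for a cohort
#'
#' Joint MCMC over per-subject physiological parameters and population
#' hyperparameters for a single stratum (the caller splits by sex).  Each
#' individual parameter is drawn from a normal population distribution
#' `theta_i ~ N(mu, 1/tau)`; precisions have Gamma(0.01, 0.01) hyperpriors
#' (uniform on \[1, 1e5\] for the space-ratio precision), and hypermeans take
#' the same vague priors as the per-subject model, including the informative
#' `N(1.035, 0.01)` prior on the space-ratio hypermean (reported as `mu_S`,
#' the population ratio S_g).  Individual parameters are constrained to the
#' per-subject prior supports.
#'
#' @param subjects list of [subject_record()]s (a warning is raised below 3
#'   subjects, where the population distribution is barely identified).
#' @param priors a [hier_prior_spec()].
#' @param config an [mcmc_config()].
#' @param constants a [dlw_constants()].
#' @return a `dlw_posterior` of type `"hierarchical"` whose draw columns are
#'   `rco2[id]`, `S[id]`, `R_W[id]`, `F[id]`, `TEE[id]` per subject plus the
#'   hyperparameters `mu_rco2`, `mu_S`, `mu_R_W`, `mu_F`, `tau_*` and the
#'   population TEE `TEE_pop` (Weir factor times `mu_rco2`).  Use
#'   [subject_medians()] / [cohort_ranges()] for cohort reporting.
#' @export
sample_hierarchical <- function(subjects, priors = hier_prior_spec(),
                                config = mcmc_config(),
                                constants = dlw_constants()) {
  stopifnot(inherits(priors, "hier_prior_spec"), length(subjects) >= 1)
  n <- length(subjects)
  if (n < 3)
    warning("hierarchical model with fewer than 3 subjects: population ",
            "parameters are driven largely by their priors", call. = FALSE)
  ids <- vapply(subjects, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  logliks <- lapply(subjects, make_subject_loglik, priors = priors,
                    constants = constants)
  wf <- weir_factor(constants$RQ)
  ranges <- list(priors$rco2_range, NULL, priors$rw_range, priors$f_range)
  # variance floors keep initial precisions finite for tight cohorts
  var_floor <- c(0.25, 1 / priors$tau_s_range[2], 25, 1e-4)

  # subject-major order: rco2[id1], S[id1], ..., TEE[id1], rco2[id2], ...
  base_par_cols <- as.vector(outer(c(PAR_NAMES, "TEE"), ids,
                                   function(p, i) paste0(p, "[", i, "]")))
  hyper_cols <- c(paste0("mu_", PAR_NAMES), paste0("tau_", PAR_NAMES),
                  "TEE_pop")
  all_cols <- c(base_par_cols, hyper_cols)
  n_keep <- (config$iterations - config$burnin) %/% config$thin

  chains <- vector("list", config$chains)
  accept_all <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    if (!is.null(config$seed)) set.seed(config$seed + ch - 1L)
    theta <- t(vapply(subjects, default_init, numeric(4),
                      priors = priors, constants = constants,
                      use_likelihood = TRUE))
    if (ch > 1L) theta <- theta * (1 + 0.02 * stats::rnorm(length(theta)))
    mu <- colMeans(theta)
    tau <- 1 / pmax(apply(theta, 2, stats::var), var_floor)
    tau[2] <- min(max(tau[2], priors$tau_s_range[1]), priors$tau_s_range[2])
    scales <- matrix(rep(config$proposal_scale, each = n), n, 4)
    ll_cur <- vapply(seq_len(n), function(i) logliks[[i]](theta[i, ]), 0)
    if (any(!is.finite(ll_cur)))
      stop("invalid initial state for subject(s): ",
           paste(ids[!is.finite(ll_cur)], collapse = ", "))
    out <- matrix(NA_real_, n_keep, length(all_cols),
                  dimnames = list(NULL, all_cols))
    batch_acc <- matrix(0, n, 4); batch_n <- 0L; batch_index <- 0L
    acc_post <- matrix(0, n, 4); n_post <- 0L
    row <- 0L
    for (it in seq_len(config$iterations)) {
      # --- individual parameters: component-wise random-walk Metropolis
      for (i in seq_len(n)) {
        th <- theta[i, ]
        lp_prior <- hier_log_prior(th, mu, tau, priors)
        ll <- ll_cur[i]
        for (j in 1:4) {
          prop <- th
          prop[j] <- th[j] + stats::rnorm(1, 0, scales[i, j])
          lp_prior_prop <- hier_log_prior(prop, mu, tau, priors)
          if (!is.finite(lp_prior_prop)) next
          ll_prop <- logliks[[i]](prop)
          if (!is.finite(ll_prop)) next
          if (log(stats::runif(1)) < (ll_prop + lp_prior_prop) - (ll + lp_prior)) {
            th <- prop; ll <- ll_prop; lp_prior <- lp_prior_prop
            if (it <= config$burnin) batch_acc[i, j] <- batch_acc[i, j] + 1
            else acc_post[i, j] <- acc_post[i, j] + 1
          }
        }
        theta[i, ] <- th
        ll_cur[i] <- ll
      }
      # --- hyperparameters: exact Gibbs draws from full conditionals
      for (p in c(1L, 3L, 4L)) {
        mu[p] <- rtrunc_norm1(mean(theta[, p]), 1 / sqrt(n * tau[p]),
                              ranges[[p]][1], ranges[[p]][2])
        ss <- sum((theta[, p] - mu[p])^2)
        tau[p] <- stats::rgamma(1, priors$tau_shape + n / 2,
                                priors$tau_rate + ss / 2)
      }
      prec_s <- 1 / priors$s_sd^2 + n * tau[2]
      mean_s <- (priors$s_mean / priors$s_sd^2 + tau[2] * sum(theta[, 2])) / prec_s
      mu[2] <- stats::rnorm(1, mean_s, 1 / sqrt(prec_s))
      ss_s <- sum((theta[, 2] - mu[2])^2)
      tau[2] <- rtrunc_gamma1(1 + n / 2, ss_s / 2,
                              priors$tau_s_range[1], priors$tau_s_range[2])
      # --- adaptation / storage
      if (it <= config$burnin) {
        batch_n <- batch_n + 1L
        if (batch_n == ADAPT_BATCH) {
          batch_index <- batch_index + 1L
          step <- min(0.5, 1 / sqrt(batch_index))
          scales <- scales * exp(step * (batch_acc / batch_n - TARGET_ACCEPT))
          batch_acc[] <- 0; batch_n <- 0L
        }
      } else {
        n_post <- n_post + 1L
        if ((it - config$burnin) %% config$thin == 0L) {
          row <- row + 1L
          out[row, ] <- c(as.vector(t(cbind(theta, wf * theta[, 1]))),
                          mu, tau, wf * mu[1])
        }
      }
    }
    chains[[ch]] <- out
    accept_all[[ch]] <- acc_post / max(n_post, 1L)
  }
  acc <- do.call(rbind, lapply(accept_all, as.vector))
  notes <- character(0)
  if (any(acc < 0.05) || any(acc > 0.95)) {
    notes <- "acceptance rate outside [0.05, 0.95] for some subject-level updates"
    warning(notes, call. = FALSE)
  }
  new_dlw_posterior(chains, type = "hierarchical", ids = ids,
                    config = config, constants = constants, accept = acc,
                    notes = notes, hyper_names = hyper_cols)
}
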