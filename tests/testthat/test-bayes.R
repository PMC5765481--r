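# Likelihood and the independent-subject sampler.

naive_loglik <- function(subject, phys, priors, constants) {
  kin <- kinetic_from_physio(phys, subject$weight_kg, constants)
  ll <- 0
  for (iso in c("2H", "18O")) {
    cv <- subject$curves[[iso]]
    N <- if (iso == "2H") kin$N_H else kin$N_O
    k <- if (iso == "2H") kin$k_H else kin$k_O
    for (j in seq_along(cv$times)) {
      pred <- enrichment_at(cv$times[j], subject$doses[[iso]], N, k,
                            cv$basal, constants)
      ll <- ll + dnorm(cv$deltas[j], pred, priors$noise_sd[[iso]], log = TRUE)
    }
  }
  ll
}

test_that("log_likelihood matches a naive per-point evaluation", {
  set.seed(41)
  s <- helper_subject(noise = c("2H" = 2, "18O" = 0.5))
  cc <- dlw_constants()
  for (pr in list(prior_spec(),
                  prior_spec(noise_sd = c("2H" = 4, "18O" = 1)))) {
    for (i in 1:5) {
      m <- rand_phys_matrix(1)
      p <- physio_params(m[1], m[2], m[3], m[4])
      expect_equal(log_likelihood(s, p, pr, cc), naive_loglik(s, p, pr, cc),
                   tolerance = 1e-10)
    }
  }
})

test_that("log_likelihood is maximal at the generating parameters of clean data", {
  s <- helper_subject()    # noise-free
  truth <- attr(s, "truth_phys")
  ll0 <- log_likelihood(s, truth)
  for (fac in c(0.97, 1.03)) {
    for (par in c("rco2", "S", "R_W", "F")) {
      p <- unlist(truth)[c("rco2", "S", "R_W", "F")]
      p[par] <- p[par] * fac
      expect_lt(log_likelihood(s, p), ll0)
    }
  }
})

test_that("parameters outside the prior support give -Inf, not an error", {
  s <- helper_subject()
  expect_identical(log_likelihood(s, c(rco2 = 150, S = 1.03, R_W = 400, F = 0.3)),
                   -Inf)
  expect_identical(log_likelihood(s, c(rco2 = 25, S = 1.03, R_W = 400, F = 1.2)),
                   -Inf)
})

test_that("sampling is deterministic given the seed and proportional in TEE", {
  set.seed(42)
  s <- helper_subject(noise = c("2H" = 2, "18O" = 0.5))
  cfg <- mcmc_config(iterations = 3000, burnin = 500, chains = 2, seed = 7)
  p1 <- sample_independent(s, config = cfg)
  p2 <- sample_independent(s, config = cfg)
  expect_identical(posterior_draws(p1), posterior_draws(p2))
  d <- posterior_draws(p1)
  expect_equal(d[, "TEE"], weir_factor(0.85) * d[, "rco2"], tolerance = 0)
  # draw count bookkeeping
  expect_equal(nrow(d), 2 * (3000 - 500))
})

test_that("the posterior tightens as measurement noise shrinks", {
  set.seed(43)
  s <- helper_subject(noise = c("2H" = 0.2, "18O" = 0.05))
  cfg <- mcmc_config(iterations = 6000, burnin = 1000, chains = 1, seed = 5)
  wide <- sample_independent(s, priors = prior_spec(), config = cfg)
  tight <- sample_independent(
    s, priors = prior_spec(noise_sd = c("2H" = 0.2, "18O" = 0.05)),
    config = cfg)
  sd_wide <- sd(posterior_draws(wide, "rco2"))
  sd_tight <- sd(posterior_draws(tight, "rco2"))
  expect_lt(sd_tight, sd_wide / 2)
})

test_that("posterior TEE uncertainty at study noise is a few percent", {
  set.seed(44)
  s <- helper_subject(noise = c("2H" = 2, "18O" = 0.5))
  cfg <- mcmc_config(iterations = 8000, burnin = 1500, chains = 1, seed = 9)
  post <- sample_independent(s, config = cfg)
  sm <- summary(post)
  cv_tee <- sm$cv[sm$parameter == "TEE"]
  expect_gt(cv_tee, 0.01); expect_lt(cv_tee, 0.10)
})

test_that("summaries of fixed (degenerate) draws are exact", {
  s <- helper_subject()
  fix <- c(rco2 = 20, S = 1.04, R_W = 300, F = 0.35)
  cfg <- mcmc_config(iterations = 600, burnin = 100, chains = 1, seed = 2)
  post <- sample_independent(s, config = cfg, fix = fix,
                             use_likelihood = FALSE)
  sm <- summary(post)
  expect_identical(sm$sd[sm$parameter == "rco2"], 0)
  expect_identical(sm$median[sm$parameter == "S"], 1.04)
  expect_equal(sm$median[sm$parameter == "TEE"],
               weir_factor(0.85) * 20, tolerance = 1e-12)
})

test_that("pathological acceptance rates are reported, never silent", {
  s <- helper_subject(noise = c("2H" = 2, "18O" = 0.5))
  # no burn-in, so no adaptation can rescue an absurd proposal scale
  cfg <- mcmc_config(iterations = 400, burnin = 0, chains = 1, seed = 3,
                     proposal_scale = c(S = 50))
  expect_warning(post <- sample_independent(s, config = cfg),
                 "acceptance rate")
  expect_true(length(post$notes) > 0)
})
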