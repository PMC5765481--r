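# Synthetic-cohort generator: determinism, calibration and recovery.

test_that("a seeded design reproduces the cohort byte for byte", {
  d <- cohort_design(n_women = 4, n_men = 3, seed = 61)
  s1 <- simulate_cohort(d); s2 <- simulate_cohort(d)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$subjects, s2$subjects)
  expect_equal(nrow(s1$truth), 7)
  expect_equal(sum(s1$truth$sex == "F"), 4)
})

test_that("population medians land on the configured sex-specific targets", {
  d <- cohort_design(n_women = 10000, n_men = 10000, seed = 62)
  truth <- draw_population(d)
  w <- truth[truth$sex == "F", ]; m <- truth[truth$sex == "M", ]
  expect_equal(median(w$rco2), 18.1, tolerance = 0.02)
  expect_equal(median(m$rco2), 25.9, tolerance = 0.02)
  expect_equal(median(w$F), 0.376, tolerance = 0.02)
  expect_equal(median(m$F), 0.274, tolerance = 0.02)
  expect_equal(median(truth$S), 1.038, tolerance = 0.002)
  expect_equal(sd(truth$S), 0.008, tolerance = 0.1)
  # truth rows are self-consistent under the core transformations
  i <- 17
  p <- physio_params(truth$rco2[i], truth$S[i], truth$R_W[i], truth$F[i])
  k <- kinetic_from_physio(p, truth$weight_kg[i])
  expect_equal(k$N_H, truth$N_H[i], tolerance = 1e-12)
  expect_equal(k$k_O, truth$k_O[i], tolerance = 1e-12)
})

test_that("an all-male design yields only male records", {
  d <- cohort_design(n_women = 0, n_men = 5, seed = 63)
  truth <- draw_population(d)
  expect_true(all(truth$sex == "M"))
})

test_that("noise-free synthesis is recovered exactly by the classical fits", {
  d <- cohort_design(n_women = 1, n_men = 1, seed = 64,
                     noise_sd = c("2H" = 1e-12, "18O" = 1e-12))
  sim <- simulate_cohort(d)
  for (i in 1:2) {
    fH <- fit_exponential(sim$subjects[[i]]$curves[["2H"]],
                          sim$subjects[[i]]$doses[["2H"]])
    fO <- fit_logarithmic(sim$subjects[[i]]$curves[["18O"]],
                          sim$subjects[[i]]$doses[["18O"]])
    expect_equal(fH$N, sim$truth$N_H[i], tolerance = 1e-8)
    expect_equal(fH$k, sim$truth$k_H[i], tolerance = 1e-8)
    expect_equal(fO$N, sim$truth$N_O[i], tolerance = 1e-8)
    expect_equal(fO$k, sim$truth$k_O[i], tolerance = 1e-8)
  }
})

test_that("noise applied to 2H leaves the 18O curve unchanged", {
  base <- cohort_design(n_women = 1, n_men = 0, seed = 65,
                        noise_sd = c("2H" = 0, "18O" = 0))
  noisy <- cohort_design(n_women = 1, n_men = 0, seed = 65,
                         noise_sd = c("2H" = 2, "18O" = 0))
  s0 <- simulate_cohort(base)$subjects[[1]]
  s1 <- simulate_cohort(noisy)$subjects[[1]]
  expect_identical(s0$curves[["18O"]]$deltas, s1$curves[["18O"]]$deltas)
  expect_false(identical(s0$curves[["2H"]]$deltas, s1$curves[["2H"]]$deltas))
})

test_that("classically estimated ratios of a default cohort span the reported range", {
  d <- cohort_design(seed = 66)   # 37 women + 22 men
  sim <- simulate_cohort(d)
  S_hat <- vapply(sim$subjects, function(s) {
    ct <- classical_tee(s, method = "logarithmic", normalize = "none")
    ct$S_natural
  }, 0)
  expect_gt(diff(range(S_hat)), 0.03)   # spread comparable to 1.010-1.069
  expect_true(all(S_hat > 0.99 & S_hat < 1.09))
  expect_equal(median(S_hat), 1.038, tolerance = 0.01)
})

test_that("the fixed example subjects are seed-stable and Table-1-like", {
  f1 <- make_prentice_like_fixtures()
  f2 <- make_prentice_like_fixtures()
  expect_identical(f1, f2)
  expect_length(f1, 3)
  ct <- classical_tee(f1[[1]], method = "exponential", normalize = "none")
  expect_gt(ct$S_natural, 1.030); expect_lt(ct$S_natural, 1.036)
  expect_equal(ct$kin_natural$N_H, 2520, tolerance = 0.02)
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(make_prentice_like_fixtures()); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the day-11 outlier inflates the 18O residual of subject 3", {
  f <- make_prentice_like_fixtures()
  s3 <- f[[3]]
  fit_all <- fit_exponential(s3$curves[["18O"]], s3$doses[["18O"]])
  keep <- s3$curves[["18O"]]$times != 11
  cv_trim <- isotope_curve("18O", s3$curves[["18O"]]$times[keep],
                           s3$curves[["18O"]]$deltas[keep],
                           s3$curves[["18O"]]$basal)
  fit_trim <- fit_exponential(cv_trim, s3$doses[["18O"]])
  expect_lt(fit_trim$rms_residual, fit_all$rms_residual)
})
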