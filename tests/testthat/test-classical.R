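# Classical TEE pipeline, error propagation and Bland-Altman comparison.

test_that("classical TEE composes the rCO2 equations with the Weir factor", {
  s <- helper_subject()
  cc <- dlw_constants()
  nat <- classical_tee(s, normalize = "none")
  expect_identical(nat$tee, weir_tee(nat$rco2, cc$RQ))
  expect_equal(nat$rco2, rco2_coward(nat$kin_natural, cc), tolerance = 1e-12)
  nrm <- classical_tee(s, normalize = "schoeller")
  expect_equal(nrm$S_used, 1.03, tolerance = 1e-14)
  expect_equal(nrm$rco2, rco2_schoeller(nrm$kin_used, cc), tolerance = 1e-12)
  # normalization rescales pools only; fitted rate constants are untouched
  expect_identical(nrm$kin_used$k_H, nrm$kin_natural$k_H)
  expect_identical(nrm$kin_used$k_O, nrm$kin_natural$k_O)
})

test_that("natural and normalized TEE agree when the true ratio equals the target", {
  # noise-free subject whose natural ratio is exactly the Schoeller target;
  # the remaining difference is the (small) Coward-vs-Schoeller equation gap
  s <- helper_subject(phys = physio_params(25, 1.03, 400, 0.30))
  nat <- classical_tee(s, normalize = "none")
  nrm <- classical_tee(s, normalize = "schoeller")
  expect_equal(nrm$tee, nat$tee, tolerance = 5e-3)
})

test_that("normalization changes TEE linearly in the natural space ratio", {
  cc <- dlw_constants()
  set.seed(31)
  S_true <- seq(1.012, 1.065, length.out = 12)
  rows <- lapply(S_true, function(S) {
    s <- helper_subject(phys = physio_params(22, S, 300, 0.30),
                        noise = c("2H" = 0.5, "18O" = 0.15), id = paste0("L", S))
    nat <- classical_tee(s, normalize = "none")
    nrm <- classical_tee(s, normalize = "schoeller")
    c(S_nat = nat$S_natural, diff = nrm$tee - nat$tee,
      shift = normalization_tee_shift(nat$kin_natural, 1.03, cc),
      tee = nat$tee)
  })
  m <- do.call(rbind, rows)
  fit <- lm(m[, "diff"] ~ m[, "S_nat"])
  expect_gt(coef(fit)[2], 0)                       # increasing in S_natural
  expect_gt(summary(fit)$r.squared, 0.99)          # and highly linear
  # closed-form shift predicts the realized difference to < 1% of TEE
  expect_lt(max(abs(m[, "diff"] - m[, "shift"]) / m[, "tee"]), 0.01)
})

test_that("subjects with k_O <= k_H or out-of-band ratios are flagged, not dropped", {
  cc <- dlw_constants()
  dose <- std_dose(200, 2500, constants = cc)
  mk_curve <- function(iso, N, k) {
    d <- std_dose(if (iso == "2H") 300 else 120, N, constants = cc)
    list(dose = d,
         curve = isotope_curve(iso, 1:10,
                               enrichment_at(1:10, d, N, k, -7, cc), -7))
  }
  H <- mk_curve("2H", 2600, 0.12); O <- mk_curve("18O", 2400, 0.08)
  s <- subject_record("bad", "M", 70, list("2H" = H$dose, "18O" = O$dose),
                      list("2H" = H$curve, "18O" = O$curve))
  ct <- classical_tee(s, normalize = "none")
  expect_true("k_order_invalid" %in% ct$flags)
  expect_true("S_outside_screen" %in% ct$flags)   # S = 2600/2400 = 1.083
})

test_that("delta-method CV is zero without noise and scales with the noise level", {
  s <- helper_subject()
  nat <- classical_tee(s, normalize = "none")
  expect_lt(propagate_error(nat$fit_H, nat$fit_O), 1e-6)
  set.seed(32)
  s1 <- helper_subject(noise = c("2H" = 2, "18O" = 0.5), id = "n1")
  # same noise realisation doubled: residuals (and hence fit SEs) double
  s2 <- s1
  for (iso in c("2H", "18O")) {
    clean <- enrichment_at(s1$curves[[iso]]$times, s1$doses[[iso]],
                           attr(s1, "truth_kin")[[if (iso == "2H") "N_H" else "N_O"]],
                           attr(s1, "truth_kin")[[if (iso == "2H") "k_H" else "k_O"]],
                           s1$curves[[iso]]$basal)
    s2$curves[[iso]]$deltas <- clean + 2 * (s1$curves[[iso]]$deltas - clean)
  }
  ct1 <- classical_tee(s1, normalize = "none")
  ct2 <- classical_tee(s2, normalize = "none")
  cv1 <- propagate_error(ct1$fit_H, ct1$fit_O)
  cv2 <- propagate_error(ct2$fit_H, ct2$fit_O)
  expect_equal(cv2 / cv1, 2, tolerance = 0.15)
  # at the study noise levels the TEE CV sits in the low single digits
  expect_gt(cv1, 0.002); expect_lt(cv1, 0.10)
})

test_that("Bland-Altman statistics behave on degenerate and known inputs", {
  a <- c(10000, 11000, 12000, 13000)
  ident <- bland_altman(a, a)
  expect_identical(ident$median_diff, 0)
  expect_identical(ident$sd_diff, 0)
  expect_identical(ident$slope, 0)
  shifted <- bland_altman(a, a + 100)
  expect_equal(shifted$median_diff, 100)
  expect_equal(shifted$slope, 0, tolerance = 1e-12)
  expect_error(bland_altman(1:2, 3:4), "at least 3")
  expect_error(bland_altman(1:4, 1:5), "equal length")
  set.seed(33)
  x <- rnorm(2000, 12000, 1500)
  y <- x + rnorm(2000, 50, 300)   # known difference sd 300
  ba <- bland_altman(x, y)
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * 300, tolerance = 0.08)
  expect_true(ba$loa_lower <= ba$median_diff && ba$median_diff <= ba$loa_upper)
})
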