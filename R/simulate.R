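# Synthetic DLW cohort generator with known ground truth.

rtrunc_norm_n <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  if (phi - plo < 1e-10)
    stop("infeasible truncation: (", lo, ", ", hi, ") for N(", mean, ", ", sd, ")")
  mean + sd * stats::qnorm(stats::runif(n, plo, phi))
}

default_population <- function() {
  list(
    F = list(rco2 = list(mean = 18.1, sd = 2.8, range = c(10, 30)),
             fat  = list(mean = 0.376, sd = 0.072, range = c(0.15, 0.60)),
             rw   = list(mean = 150, sd = 25, range = c(60, 400)),
             weight = list(mean = 69, sd = 12, range = c(45, 120))),
    M = list(rco2 = list(mean = 25.9, sd = 3.3, range = c(14, 40)),
             fat  = list(mean = 0.274, sd = 0.072, range = c(0.05, 0.50)),
             rw   = list(mean = 210, sd = 30, range = c(80, 500)),
             weight = list(mean = 83, sd = 13, range = c(55, 130)))
  )
}

#' Design of a synthetic DLW cohort
#'
#' Describes the cohort the generator emulates: 37 women and 22 men, 14
#' daily post-dose timepoints, Gaussian measurement noise of 2 per mil (2H)
#' and 0.5 per mil (18O), sex-specific truncated-normal distributions of
#' CO2 production, fat fraction, water turnover and weight, and space
#' ratios around 1.038 with between-subject sd 0.008 (natural ratios
#' spanning roughly 1.01-1.07).
#'
#' @param n_women,n_men subject counts (defaults 37 and 22).
#' @param times sampling days post-dose (default `1:14`).
#' @param noise_sd named measurement sds, per mil, for `"2H"` and `"18O"`.
#' @param population per-sex list of truncated-normal specs (`mean`, `sd`,
#'   `range`) for `rco2` (mol/day), `fat` (fraction), `rw` (mol/day) and
#'   `weight` (kg); see the defaults in the package vignette.
#' @param s_mean,s_sd population mean and between-subject sd of the
#'   dilution-space ratio; draws are truncated to `s_range`.
#' @param s_range truncation for individual space ratios.
#' @param dose dose scheme: target initial excess enrichments (per mil) per
#'   isotope, the administered dose mass, and the aliquot/tap-water dilution
#'   masses; the diluted-dose enrichment is back-computed so each subject's
#'   t = 0 excess hits the target.
#' @param basal basal-enrichment model: `o_mean`/`o_sd` for the 18O basal
#'   (per mil), and `mwl = TRUE` places the 2H basal on the meteoric water
#'   line (`delta2H = 8 * delta18O + 10`) with scatter `mwl_sd`.
#' @param seed optional integer; when set, [draw_population()] and
#'   [simulate_cohort()] seed the RNG for byte-identical output.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_women = 37, n_men = 22, times = 1:14,
                          noise_sd = c("2H" = 2, "18O" = 0.5),
                          population = default_population(),
                          s_mean = 1.038, s_sd = 0.008,
                          s_range = c(1.005, 1.075),
                          dose = list(excess = c("2H" = 300, "18O" = 120),
                                      dose_g = 100, aliquot_g = 5,
                                      tapwater_g = 495,
                                      delta_tap = c("2H" = -46, "18O" = -7)),
                          basal = list(o_mean = -7, o_sd = 0.5,
                                       mwl = TRUE, mwl_sd = 2),
                          seed = NULL) {
  stopifnot(n_women >= 0, n_men >= 0, n_women + n_men >= 1,
            !is.unsorted(times, strictly = TRUE), all(times >= 0),
            all(noise_sd >= 0), s_sd > 0,
            all(c("F", "M") %in% names(population)))
  structure(list(n_women = n_women, n_men = n_men, times = times,
                 noise_sd = noise_sd, population = population,
                 s_mean = s_mean, s_sd = s_sd, s_range = s_range,
                 dose = dose, basal = basal, seed = seed),
            class = "cohort_design")
}

#' Draw a population of true physiological parameters
#'
#' Draws per-subject ground-truth physiological parameters from the
#' sex-specific distributions in the design and derives the consistent
#' kinetic parameters.  Column `S` is drawn from
#' `N(s_mean, s_sd)` truncated to `s_range`.
#'
#' @param design a [cohort_design()].
#' @param constants a [dlw_constants()].
#' @return a data.frame (class `dlw_truth`) with one row per subject:
#'   `id`, `sex`, `weight_kg`, the true `rco2`, `S`, `R_W`, `F`, `TEE`, and
#'   the implied `N_H`, `N_O`, `k_H`, `k_O`.
#' @export
draw_population <- function(design = cohort_design(),
                            constants = dlw_constants()) {
  if (!is.null(design$seed)) set.seed(design$seed)
  sexes <- c(rep("F", design$n_women), rep("M", design$n_men))
  n <- length(sexes)
  draw1 <- function(spec, k) rtrunc_norm_n(k, spec$mean, spec$sd,
                                           spec$range[1], spec$range[2])
  rows <- lapply(c("F", "M"), function(sx) {
    k <- sum(sexes == sx)
    if (k == 0) return(NULL)
    pop <- design$population[[sx]]
    data.frame(sex = rep(sx, k),
               weight_kg = draw1(pop$weight, k),
               rco2 = draw1(pop$rco2, k),
               S = rtrunc_norm_n(k, design$s_mean, design$s_sd,
                                 design$s_range[1], design$s_range[2]),
               R_W = draw1(pop$rw, k),
               F = draw1(pop$fat, k))
  })
  truth <- do.call(rbind, rows)
  truth <- cbind(data.frame(id = sprintf("S%02d", seq_len(n))), truth)
  kin <- t(vapply(seq_len(n), function(i) {
    k <- kinetic_from_physio(
      physio_params(truth$rco2[i], truth$S[i], truth$R_W[i], truth$F[i]),
      truth$weight_kg[i], constants)
    c(k$N_H, k$N_O, k$k_H, k$k_O)
  }, numeric(4)))
  colnames(kin) <- c("N_H", "N_O", "k_H", "k_O")
  truth$TEE <- weir_tee(truth$rco2, constants$RQ)
  truth <- cbind(truth, as.data.frame(kin))
  class(truth) <- c("dlw_truth", "data.frame")
  truth
}

#' Synthesize one subject's measured DLW record from ground truth
#'
#' Builds the dose preparations (the diluted-dose enrichment is chosen so
#' the noise-free t = 0 excess equals the design target), computes the
#' noise-free curves from the true kinetics via [enrichment_at()], and adds
#' independent Gaussian measurement noise with the design sds.  Basal
#' enrichments are drawn near natural abundance, with the 2H basal on the
#' meteoric water line when `design$basal$mwl` is set.
#'
#' @param truth one row of a [draw_population()] result (data.frame row or
#'   named list with `id`, `sex`, `weight_kg`, `N_H`, `N_O`, `k_H`, `k_O`).
#' @param design a [cohort_design()].
#' @param constants a [dlw_constants()].
#' @return a [subject_record()].
#' @export
synthesize_subject <- function(truth, design = cohort_design(),
                               constants = dlw_constants()) {
  basal_O <- stats::rnorm(1, design$basal$o_mean, design$basal$o_sd)
  basal_H <- if (isTRUE(design$basal$mwl))
    8 * basal_O + 10 + stats::rnorm(1, 0, design$basal$mwl_sd)
  else stats::rnorm(1, 8 * design$basal$o_mean + 10, design$basal$mwl_sd)
  basal <- c("2H" = basal_H, "18O" = basal_O)
  pools <- c("2H" = truth$N_H, "18O" = truth$N_O)
  rates <- c("2H" = truth$k_H, "18O" = truth$k_O)
  doses <- list(); curves <- list()
  for (iso in c("2H", "18O")) {
    # delta_dd placing the t=0 excess at the design target for this pool
    target_C <- design$dose$excess[[iso]] * pools[[iso]]
    delta_dd <- design$dose$delta_tap[[iso]] +
      target_C * constants$water_molar_mass * design$dose$aliquot_g /
      (design$dose$dose_g * design$dose$tapwater_g)
    doses[[iso]] <- dose_prep(design$dose$dose_g, design$dose$aliquot_g,
                              design$dose$tapwater_g, delta_dd,
                              design$dose$delta_tap[[iso]])
    clean <- enrichment_at(design$times, doses[[iso]], pools[[iso]],
                           rates[[iso]], basal[[iso]], constants)
    noisy <- clean + stats::rnorm(length(clean), 0, design$noise_sd[[iso]])
    curves[[iso]] <- isotope_curve(iso, design$times, noisy, basal[[iso]])
  }
  subject_record(truth$id, truth$sex, truth$weight_kg, doses, curves)
}

#' Simulate a full synthetic cohort
#'
#' [draw_population()] followed by [synthesize_subject()] for every subject,
#' under the design's seed when one is set.
#'
#' @inheritParams draw_population
#' @return a list with `subjects` (list of [subject_record()]) and `truth`
#'   (the `dlw_truth` data.frame).
#' @export
simulate_cohort <- function(design = cohort_design(),
                            constants = dlw_constants()) {
  truth <- draw_population(design, constants)   # seeds the RNG if asked
  subjects <- lapply(seq_len(nrow(truth)), function(i)
    synthesize_subject(truth[i, ], design, constants))
  list(subjects = subjects, truth = truth)
}

#' Three fixed synthetic example subjects (70 kg, Table-1-like kinetics)
#'
#' Builds three seed-stable synthetic subjects with kinetics in the
#' neighbourhood of N_H ~ 2520 mol, N_O ~ 2440 mol, k_H ~ 0.083 /day,
#' k_O ~ 0.109 /day at an assigned weight of 70 kg, sampled daily for 14
#' days with measurement noise 2 / 0.5 per mil.  The third subject carries
#' a single outlying 18O point on day 11 (+11 per mil), for exercising
#' outlier behaviour.  These are synthetic stand-ins constructed from
#' published summary kinetics, not measured data.
#'
#' @param constants a [dlw_constants()].
#' @return list of three [subject_record()]s; the generating kinetics are
#'   attached as `attr(x, "truth")` (a `dlw_truth` data.frame).
#' @export
make_prentice_like_fixtures <- function(constants = dlw_constants()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(1002)   # fixed: realisations stay in the advertised neighbourhood
  base_kin <- list(N_H = 2520, N_O = 2437, k_H = 0.0834, k_O = 0.1088)
  perturb <- list(c(1, 1), c(1.03, 0.97), c(0.98, 1.02))  # (pool, rate) factors
  design <- cohort_design(n_women = 0, n_men = 3, seed = NULL)
  subjects <- vector("list", 3)
  truth_rows <- vector("list", 3)
  for (i in 1:3) {
    kin <- kinetic_params(N_H = base_kin$N_H * perturb[[i]][1],
                          N_O = base_kin$N_O * perturb[[i]][1],
                          k_H = base_kin$k_H * perturb[[i]][2],
                          k_O = base_kin$k_O * perturb[[i]][2])
    phys <- physio_from_kinetic(kin, 70, constants)
    tr <- data.frame(id = paste0("P", i), sex = "M", weight_kg = 70,
                     rco2 = phys$rco2, S = phys$S, R_W = phys$R_W,
                     F = phys$F, TEE = weir_tee(phys$rco2, constants$RQ),
                     N_H = kin$N_H, N_O = kin$N_O, k_H = kin$k_H,
                     k_O = kin$k_O)
    subj <- synthesize_subject(tr, design, constants)
    if (i == 3) {   # outlying 18O point on day 11
      cv <- subj$curves[["18O"]]
      day11 <- which(cv$times == 11)
      cv$deltas[day11] <- cv$deltas[day11] + 11
      subj$curves[["18O"]] <- cv
    }
    subjects[[i]] <- subj
    truth_rows[[i]] <- tr
  }
  truth <- do.call(rbind, truth_rows)
  class(truth) <- c("dlw_truth", "data.frame")
  attr(subjects, "truth") <- truth
  subjects
}
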