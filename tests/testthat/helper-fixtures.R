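# Shared fixtures: deterministic subjects built from known physiology.

std_dose <- function(excess, N, delta_tap = -7,
                     constants = dlw_constants()) {
  # delta_dd chosen so the t=0 excess enrichment is exactly `excess`
  delta_dd <- delta_tap +
    excess * N * constants$water_molar_mass * 5 / (100 * 495)
  dose_prep(100, 5, 495, delta_dd, delta_tap)
}

# Subject with exactly known kinetics; noise sds of 0 give noise-free curves.
helper_subject <- function(phys = physio_params(25, 1.035, 400, 0.30),
                           weight_kg = 70, times = 1:14,
                           noise = c("2H" = 0, "18O" = 0),
                           basal = c("2H" = -46, "18O" = -7),
                           id = "X1", sex = "M",
                           constants = dlw_constants()) {
  kin <- kinetic_from_physio(phys, weight_kg, constants)
  pools <- c("2H" = kin$N_H, "18O" = kin$N_O)
  rates <- c("2H" = kin$k_H, "18O" = kin$k_O)
  excess <- c("2H" = 300, "18O" = 120)
  doses <- list(); curves <- list()
  for (iso in c("2H", "18O")) {
    doses[[iso]] <- std_dose(excess[[iso]], pools[[iso]], basal[[iso]] - 1,
                             constants)
    y <- enrichment_at(times, doses[[iso]], pools[[iso]], rates[[iso]],
                       basal[[iso]], constants)
    if (noise[[iso]] > 0) y <- y + rnorm(length(y), 0, noise[[iso]])
    curves[[iso]] <- isotope_curve(iso, times, y, basal[[iso]])
  }
  subj <- subject_record(id, sex, weight_kg, doses, curves)
  attr(subj, "truth_phys") <- phys
  attr(subj, "truth_kin") <- kin
  subj
}

# Random physiological parameters inside the prior support, as a matrix.
rand_phys_matrix <- function(n) {
  cbind(rco2 = runif(n, 5, 40), S = runif(n, 1.00, 1.08),
        R_W = runif(n, 50, 500), F = runif(n, 0.05, 0.60))
}

rand_kinetics <- function(n) {
  lapply(seq_len(n), function(i) {
    N_O <- runif(1, 1500, 3500)
    kinetic_params(N_H = runif(1, 1.0, 1.08) * N_O, N_O = N_O,
                   k_H = runif(1, 0.05, 0.12), k_O = runif(1, 0.125, 0.2))
  })
}
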