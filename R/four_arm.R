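# The four analysis arms side by side: natural non-Bayesian, normalized
# non-Bayesian, independent Bayesian, hierarchical Bayesian (split by sex).

#' Run the four-arm DLW analysis on a cohort
#'
#' For every subject computes TEE, S, rCO2 and fat fraction under
#' (1) classical fitting with natural spaces and the Coward equation,
#' (2) classical fitting with normalized spaces and the Schoeller equation,
#' (3) the independent Bayesian model (posterior medians), and
#' (4) the hierarchical Bayesian model run separately per sex stratum
#' (posterior medians), then assembles per-sex median (range) summaries and
#' Bland-Altman comparisons between arms.  An arm failing for a subject is
#' reported (`$failures`) and left `NA`; the other arms are still emitted.
#'
#' @param subjects list of [subject_record()]s.
#' @param method classical fit flavour passed to [classical_tee()].
#' @param normalize normalization for the normalized arm: `"schoeller"`
#'   (default) or `"iaea"`.
#' @param priors a [prior_spec()] for the independent arm.
#' @param hier_priors a [hier_prior_spec()] for the hierarchical arm.
#' @param mcmc an [mcmc_config()].
#' @param constants a [dlw_constants()].
#' @param pool_sexes run one hierarchical analysis on the pooled cohort
#'   instead of per-sex strata (default `FALSE`: sexes are analysed
#'   separately since CO2 production and body composition differ between
#'   the strata).
#' @return an object of class `dlw_four_arm`: a list with `per_subject`
#'   (data.frame, one row per subject, columns `<param>_<arm>`), `by_sex`
#'   (median/min/max per sex x parameter x arm), `bland_altman` (TEE
#'   comparisons between arms), `failures` (messages), and the posterior
#'   objects (`independent`, `hierarchical`).
#' @export
run_four_arm_analysis <- function(subjects,
                                  method = "exponential",
                                  normalize = c("schoeller", "iaea"),
                                  priors = prior_spec(),
                                  hier_priors = hier_prior_spec(),
                                  mcmc = mcmc_config(),
                                  constants = dlw_constants(),
                                  pool_sexes = FALSE) {
  normalize <- match.arg(normalize)
  ids <- vapply(subjects, function(s) s$id, "")
  sexes <- vapply(subjects, function(s) s$sex, "")
  n <- length(subjects)
  failures <- character(0)
  note_failure <- function(arm, id, e) {
    msg <- sprintf("%s arm failed for subject %s: %s", arm, id,
                   conditionMessage(e))
    failures <<- c(failures, msg)
    NULL
  }
  empty <- data.frame(TEE = NA_real_, S = NA_real_, rco2 = NA_real_,
                      F = NA_real_)
  grab_classical <- function(ct) {
    if (is.null(ct)) return(empty)
    data.frame(TEE = ct$tee,
               S = if (ct$normalize == "none") ct$S_natural else ct$S_used,
               rco2 = ct$rco2, F = ct$fat_fraction)
  }
  nat <- do.call(rbind, lapply(subjects, function(s) grab_classical(
    tryCatch(classical_tee(s, method, "none", constants),
             error = function(e) note_failure("natural", s$id, e)))))
  nrm <- do.call(rbind, lapply(subjects, function(s) grab_classical(
    tryCatch(classical_tee(s, method, normalize, constants),
             error = function(e) note_failure("normalized", s$id, e)))))
  indep_posts <- lapply(subjects, function(s)
    tryCatch(sample_independent(s, priors, mcmc, constants),
             error = function(e) note_failure("independent", s$id, e)))
  grab_medians <- function(draws) {
    if (is.null(draws)) return(empty)
    med <- apply(draws, 2, stats::median)
    data.frame(TEE = med[["TEE"]], S = med[["S"]], rco2 = med[["rco2"]],
               F = med[["F"]])
  }
  ind <- do.call(rbind, lapply(indep_posts, function(p)
    grab_medians(if (is.null(p)) NULL else posterior_draws(p))))
  # hierarchical arm, by sex stratum (or pooled on request)
  strata <- if (pool_sexes) list(all = seq_len(n))
            else split(seq_len(n), sexes)
  hier_posts <- list()
  hier <- empty[rep(1, n), ]; rownames(hier) <- NULL
  for (st in names(strata)) {
    idx <- strata[[st]]
    post <- tryCatch(
      sample_hierarchical(subjects[idx], hier_priors, mcmc, constants),
      error = function(e) note_failure(paste0("hierarchical(", st, ")"),
                                       paste(ids[idx], collapse = ","), e))
    hier_posts[[st]] <- post
    if (!is.null(post)) {
      med <- subject_medians(post)
      hier[idx, ] <- med[match(ids[idx], med$id),
                         c("TEE", "S", "rco2", "F")]
    }
  }
  arms <- list(natural = nat, normalized = nrm, independent = ind,
               hierarchical = hier)
  per_subject <- data.frame(id = ids, sex = sexes)
  for (a in names(arms)) {
    block <- arms[[a]]
    names(block) <- paste0(names(block), "_", a)
    per_subject <- cbind(per_subject, block)
  }
  # per-sex (and combined) median + range of each parameter under each arm
  by_sex <- do.call(rbind, lapply(c(unique(sexes), "combined"), function(sx) {
    sel <- if (sx == "combined") rep(TRUE, n) else sexes == sx
    do.call(rbind, lapply(names(arms), function(a) {
      do.call(rbind, lapply(c("TEE", "S", "rco2", "F"), function(p) {
        v <- arms[[a]][[p]][sel]
        v <- v[is.finite(v)]
        data.frame(sex = sx, arm = a, parameter = p,
                   median = if (length(v)) stats::median(v) else NA_real_,
                   min = if (length(v)) min(v) else NA_real_,
                   max = if (length(v)) max(v) else NA_real_)
      }))
    }))
  }))
  ba <- list()
  pairs <- list(normalized_vs_natural = c("natural", "normalized"),
                independent_vs_normalized = c("normalized", "independent"),
                hierarchical_vs_normalized = c("normalized", "hierarchical"))
  for (nm in names(pairs)) {
    a <- arms[[pairs[[nm]][1]]]$TEE; b <- arms[[pairs[[nm]][2]]]$TEE
    ba[[nm]] <- tryCatch(bland_altman(a, b), error = function(e) NULL)
  }
  structure(list(per_subject = per_subject, by_sex = by_sex,
                 bland_altman = ba, failures = failures,
                 independent = indep_posts, hierarchical = hier_posts),
            class = "dlw_four_arm")
}

#' @export
print.dlw_four_arm <- function(x, ...) {
  cat("Four-arm DLW analysis of", nrow(x$per_subject), "subjects\n")
  tee <- x$by_sex[x$by_sex$parameter == "TEE", ]
  for (sx in unique(tee$sex)) {
    cat(" ", sx, "TEE median (range) by arm:\n")
    rows <- tee[tee$sex == sx, ]
    for (i in seq_len(nrow(rows)))
      cat(sprintf("    %-12s %6.0f (%.0f-%.0f) kJ/day\n", rows$arm[i],
                  rows$median[i], rows$min[i], rows$max[i]))
  }
  if (length(x$failures)) cat("failures:\n ", paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}
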