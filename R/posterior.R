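# Posterior container, summaries, and convergence diagnostics.

new_dlw_posterior <- function(chains, type, ids, config, constants,
                              accept = NULL, notes = character(0),
                              hyper_names = character(0)) {
  structure(list(chains = chains, type = type, ids = ids, config = config,
                 constants = constants, accept = accept, notes = notes,
                 hyper_names = hyper_names),
            class = "dlw_posterior")
}

#' Extract posterior draws as one matrix
#'
#' @param x a `dlw_posterior`.
#' @param parameter optional column name(s) to select.
#' @return a matrix with chains stacked row-wise.
#' @export
posterior_draws <- function(x, parameter = NULL) {
  stopifnot(inherits(x, "dlw_posterior"))
  d <- do.call(rbind, x$chains)
  if (!is.null(parameter)) d <- d[, parameter, drop = FALSE]
  d
}

# Split-chain potential scale reduction factor.  Each chain is split in
# half; returns NA for (near-)constant draws (e.g. fixed parameters).
split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    n <- length(ch); h <- n %/% 2L
    halves <- c(halves, list(ch[seq_len(h)], ch[(h + 1L):(2L * h)]))
  }
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  if (!is.finite(W) || W < .Machine$double.eps * max(abs(means), 1)^2)
    return(NA_real_)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial monotone positive sequence on
# the chain-averaged autocorrelations.
ess_imse <- function(chain_list) {
  n <- length(chain_list[[1]])
  m <- length(chain_list)
  if (stats::var(unlist(chain_list)) == 0) return(NA_real_)
  max_lag <- min(n - 1L, 500L)
  rho <- rep(0, max_lag + 1L)
  for (ch in chain_list) {
    a <- stats::acf(ch, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    rho <- rho + a / m
  }
  # sum pairs rho[2t] + rho[2t+1] while positive and non-increasing
  tau <- rho[1]
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
    t <- t + 2L
  }
  max(m * n / tau, 1)
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, sd, median, CV, central 95% interval, and
#' split-chain R-hat and effective sample size.
#'
#' @param object a `dlw_posterior`.
#' @param ... unused.
#' @return a data.frame with one row per parameter.
#' @export
summary.dlw_posterior <- function(object, ...) {
  pars <- colnames(object$chains[[1]])
  if (length(object$chains[[1]]) == 0 || nrow(object$chains[[1]]) == 0)
    stop("posterior contains no draws")
  rows <- lapply(pars, function(p) {
    per_chain <- lapply(object$chains, function(m) m[, p])
    all_d <- unlist(per_chain)
    q <- stats::quantile(all_d, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(all_d), sd = stats::sd(all_d),
               median = q[2], cv = stats::sd(all_d) / abs(mean(all_d)),
               q2.5 = q[1], q97.5 = q[3],
               rhat = if (length(per_chain) >= 1 && length(per_chain[[1]]) >= 4)
                 split_rhat(per_chain) else NA_real_,
               ess = ess_imse(per_chain))
  })
  do.call(rbind, rows)
}

#' @export
print.dlw_posterior <- function(x, ...) {
  n <- sum(vapply(x$chains, nrow, 0L))
  cat(sprintf("DLW posterior (%s model): %d draws (%d chain(s)), %d parameter(s)\n",
              x$type, n, length(x$chains), ncol(x$chains[[1]])))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Cohort-level ranges of per-subject posterior medians
#'
#' For a hierarchical (cohort) posterior, returns the median and the min-max
#' range, across subjects, of the per-subject posterior medians of each
#' physiological parameter and TEE (the form in which cohort results are
#' reported).
#'
#' @param x a `dlw_posterior` from [sample_hierarchical()], or a list of
#'   per-subject `dlw_posterior` objects from [sample_independent()].
#' @return a data.frame with columns `parameter`, `median`, `min`, `max`.
#' @export
cohort_ranges <- function(x) {
  med_tab <- subject_medians(x)
  pars <- setdiff(colnames(med_tab), "id")
  do.call(rbind, lapply(pars, function(p) {
    v <- med_tab[[p]]
    data.frame(parameter = p, median = stats::median(v),
               min = min(v), max = max(v))
  }))
}

#' Per-subject posterior medians
#'
#' @param x as in [cohort_ranges()].
#' @return a data.frame with one row per subject and columns `id`, `rco2`,
#'   `S`, `R_W`, `F`, `TEE`.
#' @export
subject_medians <- function(x) {
  base_pars <- c(PAR_NAMES, "TEE")
  if (inherits(x, "dlw_posterior")) {
    stopifnot(x$type == "hierarchical")
    rows <- lapply(x$ids, function(id) {
      cols <- paste0(base_pars, "[", id, "]")
      d <- posterior_draws(x, cols)
      out <- as.data.frame(as.list(apply(d, 2, stats::median)))
      names(out) <- base_pars
      cbind(data.frame(id = id), out)
    })
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "dlw_posterior")))
    rows <- lapply(x, function(post) {
      d <- posterior_draws(post, base_pars)
      out <- as.data.frame(as.list(apply(d, 2, stats::median)))
      names(out) <- base_pars
      cbind(data.frame(id = post$ids), out)
    })
  }
  do.call(rbind, rows)
}
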