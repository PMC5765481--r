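# Per-isotope elimination-curve fits.  All three flavours estimate the same
# model delta(t) = A*exp(-k*t) + basal; they differ in the assumed error
# structure: logarithmic = OLS on log-excess (proportionate error), poisson =
# weighted log-scale fit (variance ~ excess), exponential = untransformed
# nonlinear least squares (constant per-mil error).

new_dlw_fit <- function(method, curve, A, k, N, se, vcov_Nk, used) {
  fitted <- A * exp(-k * curve$times) + curve$basal
  residuals <- curve$deltas - fitted
  structure(list(
    method = method, isotope = curve$isotope,
    A = A, k = k, N = N, basal = curve$basal,
    se = se, vcov_Nk = vcov_Nk,
    times = curve$times, fitted = fitted, residuals = residuals,
    n_used = sum(used), dropped = which(!used),
    rms_residual = sqrt(mean(residuals[used]^2))
  ), class = "dlw_fit")
}

# Shared preparation: excess enrichments with below-basal points excluded.
usable_excess <- function(curve) {
  excess <- curve$deltas - curve$basal
  used <- excess > 0
  if (any(!used))
    warning(sprintf("%s curve: %d point(s) at or below basal excluded from log-scale fit (day %s)",
                    curve$isotope, sum(!used),
                    paste(curve$times[!used], collapse = ", ")),
            call. = FALSE)
  if (sum(used) < 2)
    stop("fewer than 2 usable timepoints above basal", call. = FALSE)
  list(excess = excess, used = used)
}

# Log-scale linear fit; weights on the log scale (NULL = unweighted).
fit_logscale <- function(curve, dose, constants, weights = NULL, method) {
  ue <- usable_excess(curve)
  t_u <- curve$times[ue$used]
  y_u <- log(ue$excess[ue$used])
  w_u <- if (is.null(weights)) NULL else weights[ue$used]
  fit <- if (is.null(w_u)) stats::lm(y_u ~ t_u) else stats::lm(y_u ~ t_u, weights = w_u)
  b <- stats::coef(fit)
  k <- -b[[2]]
  if (!is.finite(k) || k <= 0)
    stop("fitted rate constant is not positive; curve does not decay", call. = FALSE)
  A <- exp(b[[1]])
  N <- dose_factor(dose, constants) / A
  if (stats::df.residual(fit) >= 1) {
    # noise-free validation data triggers the "essentially perfect fit"
    # warning from summary.lm; a perfect fit is a supported case here
    V <- withCallingHandlers(
      stats::vcov(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    # A = exp(b0), k = -b1, N = C*exp(-b0): delta method on (b0, b1)
    vcov_Nk <- matrix(c(N^2 * V[1, 1], N * V[1, 2],
                        N * V[1, 2], V[2, 2]), 2, 2,
                      dimnames = list(c("N", "k"), c("N", "k")))
    se <- c(A = A * sqrt(V[1, 1]), k = sqrt(V[2, 2]), N = N * sqrt(V[1, 1]))
  } else {
    vcov_Nk <- matrix(NA_real_, 2, 2, dimnames = list(c("N", "k"), c("N", "k")))
    se <- c(A = NA_real_, k = NA_real_, N = NA_real_)
  }
  new_dlw_fit(method, curve, A, k, N, se, vcov_Nk, ue$used)
}

#' Logarithmic (semi-log least squares) curve fit
#'
#' Ordinary least squares of `log(delta(t) - basal)` on `t`; the intercept is
#' back-transformed and converted to a pool size via the dose preparation
#' (`N = D*T*(delta_dd - delta_tap) / (18.02 * d * A)` with `A` the t = 0
#' excess enrichment).  Points at or below basal are excluded with a warning.
#'
#' @param curve an [isotope_curve()].
#' @param dose the matching [dose_prep()].
#' @param constants a [dlw_constants()].
#' @return an object of class `dlw_fit` with elements `A` (t = 0 excess, per
#'   mil), `k` (per day), `N` (mol), standard errors, the `(N, k)` covariance
#'   matrix, and per-timepoint fitted values and residuals on the delta scale.
#' @export
fit_logarithmic <- function(curve, dose, constants = dlw_constants()) {
  fit_logscale(curve, dose, constants, weights = NULL, method = "logarithmic")
}

#' Poisson-weighted curve fit
#'
#' Weighted least squares on the log scale with weights proportional to the
#' excess enrichment, the error model in which the variance of `delta(t)` is
#' proportional to the excess (Poisson-like).  Intermediate between the
#' logarithmic and exponential error assumptions.
#'
#' @inheritParams fit_logarithmic
#' @return an object of class `dlw_fit`; see [fit_logarithmic()].
#' @export
fit_poisson <- function(curve, dose, constants = dlw_constants()) {
  excess <- curve$deltas - curve$basal
  w <- pmax(excess, 0)
  fit_logscale(curve, dose, constants, weights = w, method = "poisson")
}

#' Exponential (untransformed nonlinear least squares) curve fit
#'
#' Levenberg-Marquardt least squares of `delta(t) = A*exp(-k*t) + basal` on
#' the untransformed delta scale, initialized from [fit_logarithmic()].  This
#' is the error model matching constant per-mil measurement noise, and the
#' curve form used by the Bayesian model.  All timepoints participate
#' (below-basal points are admissible on this scale).
#'
#' @inheritParams fit_logarithmic
#' @param start optional named vector `c(A = , k = )` overriding the
#'   logarithmic-fit starting values.
#' @return an object of class `dlw_fit`; see [fit_logarithmic()].  On
#'   non-convergence an error of class `dlw_fit_error` is signalled carrying
#'   the logarithmic initializer fit in its `init` field.
#' @export
fit_exponential <- function(curve, dose, constants = dlw_constants(),
                            start = NULL) {
  init <- fit_logarithmic(curve, dose, constants)
  if (!is.null(start)) {
    stopifnot(all(c("A", "k") %in% names(start)), all(start > 0))
    init$A <- start[["A"]]; init$k <- start[["k"]]
  }
  df <- data.frame(t = curve$times, y = curve$deltas)
  basal <- curve$basal
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-k * t) + basal, data = df,
                      start = list(A = init$A, k = init$k),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(structure(class = c("dlw_fit_error", "error", "condition"),
                     list(message = paste0("exponential fit failed to converge (",
                                           conditionMessage(e),
                                           "); initializer fit attached"),
                          call = sys.call(-1), init = init)))
    })
  b <- stats::coef(fit)
  A <- b[["A"]]; k <- b[["k"]]
  if (!is.finite(k) || k <= 0 || !is.finite(A) || A <= 0)
    stop("exponential fit converged to a non-positive A or k", call. = FALSE)
  N <- dose_factor(dose, constants) / A
  V <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  # N = C/A: dN/dA = -N/A
  vcov_Nk <- matrix(c((N / A)^2 * V[1, 1], -(N / A) * V[1, 2],
                      -(N / A) * V[1, 2], V[2, 2]), 2, 2,
                    dimnames = list(c("N", "k"), c("N", "k")))
  se <- c(A = sqrt(V[1, 1]), k = sqrt(V[2, 2]), N = (N / A) * sqrt(V[1, 1]))
  used <- rep(TRUE, length(curve$times))
  new_dlw_fit("exponential", curve, A, k, N, se, vcov_Nk, used)
}

#' @export
print.dlw_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): A = %.1f permil, k = %.4f /day, N = %.1f mol; rms residual %.2f permil (%d/%d points)\n",
              x$method, x$isotope, x$A, x$k, x$N, x$rms_residual,
              x$n_used, length(x$times)))
  invisible(x)
}
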