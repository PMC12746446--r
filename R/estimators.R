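#' Thermodynamic integration over the lambda grid
#'
#' Composite quadrature of the per-window mean `dU/dlambda` over
#' `lambda in [0, 1]`. `"simpson"` needs an odd number of windows (an even
#' number of panels; the default 101-window grid satisfies this) and falls
#' back to a trapezoid on the last panel otherwise (with a message).
#'
#' @param per_window_means mean `dU/dlambda` per window, physical-state
#'   samples only.
#' @param grid a [lambda_grid()].
#' @param rule `"simpson"` or `"trapezoid"`.
#' @return object of class `ti_result` with elements `dg` (kT), `rule`, and
#'   the quadrature `weights` used.
#' @export
ti_integrate <- function(per_window_means, grid,
                         rule = c("simpson", "trapezoid")) {
  rule <- match.arg(rule)
  n <- grid$n_windows
  stopifnot(length(per_window_means) == n)
  if (any(!is.finite(per_window_means)))
    stop("mean dU/dlambda must be defined at every window", call. = FALSE)
  w <- quadrature_weights(n, rule)
  structure(list(dg = sum(w * per_window_means) * grid$delta_lambda,
                 rule = attr(w, "rule"), weights = w * grid$delta_lambda),
            class = "ti_result")
}

quadrature_weights <- function(n, rule) {
  if (rule == "simpson" && n %% 2 == 0L) {
    message("Simpson's rule needs an odd number of windows; ",
            "using a trapezoid on the last panel")
    w <- quadrature_weights(n - 1L, "simpson")
    w <- c(w, 0)
    w[n - 1L] <- w[n - 1L] + 0.5
    w[n] <- 0.5
    attr(w, "rule") <- "simpson+trapezoid"
    return(w)
  }
  w <- if (rule == "simpson" && n >= 3L) {
    ww <- rep(c(2, 4), length.out = n) / 3
    ww[c(1L, n)] <- 1 / 3
    ww
  } else {
    ww <- rep(1, n)
    ww[c(1L, n)] <- 0.5
    ww
  }
  attr(w, "rule") <- if (rule == "simpson") "simpson" else "trapezoid"
  w
}

#' @export
print.ti_result <- function(x, ...) {
  cat(sprintf("<TI estimate> dG = %.6f kT (%s rule)\n", x$dg, x$rule))
  invisible(x)
}

#' Autocorrelation, statistical inefficiency, and effective sample size
#'
#' `autocorrelation()` estimates `rho_k = Cov(X_t, X_{t+k}) / Var(X_t)` with
#' the biased (divisor N) covariance about the overall series mean.
#' `statistical_inefficiency()` computes `g = 1 + 2 sum_k rho_k`, truncating
#' the sum at the first lag where the estimated autocorrelation has decayed
#' to (at or below) zero, and floors the result at 1. `effective_samples()`
#' returns `N_eff = N / g` and the sampling efficiency `eta = 1 / g`;
#' `standard_error()` returns `sd(series) / sqrt(N_eff)`, the autocorrelation-
#' corrected standard error of the series mean.
#'
#' @param series numeric time series of `dU/dlambda` (or any observable).
#' @param lag integer lag (>= 0, < length of series).
#' @return `autocorrelation()`: a scalar in `[-1, 1]` (up to estimator
#'   noise); `statistical_inefficiency()`: `g >= 1`; `effective_samples()`:
#'   list with `n_eff` and `eta`; `standard_error()`: a scalar.
#' @export
autocorrelation <- function(series, lag) {
  n <- length(series)
  stopifnot(lag >= 0, lag < n)
  xc <- series - mean(series)
  c0 <- sum(xc^2) / n
  if (c0 == 0) stop("series has zero variance", call. = FALSE)
  if (lag == 0) return(1)
  sum(xc[1:(n - lag)] * xc[(lag + 1):n]) / n / c0
}

#' @rdname autocorrelation
#' @export
statistical_inefficiency <- function(series) {
  n <- length(series)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  if (stats::var(series) == 0) stop("series has zero variance", call. = FALSE)
  lag_max <- min(100L, n - 1L)
  repeat {
    rho <- stats::acf(series, lag.max = lag_max, plot = FALSE,
                      demean = TRUE)$acf[-1L]
    cut <- which(rho <= 0)
    if (length(cut) > 0 || lag_max >= n - 1L) break
    lag_max <- min(n - 1L, lag_max * 4L)
  }
  kcut <- if (length(cut) > 0) cut[1L] - 1L else length(rho)
  g <- 1 + 2 * sum(rho[seq_len(kcut)])
  max(1, g)
}

#' @rdname autocorrelation
#' @export
effective_samples <- function(series) {
  g <- statistical_inefficiency(series)
  list(n_eff = length(series) / g, eta = 1 / g)
}

#' @rdname autocorrelation
#' @export
standard_error <- function(series) {
  stats::sd(series) / sqrt(effective_samples(series)$n_eff)
}

#' Spread of replicate means and the sampling-quality ratio
#'
#' `replicate_spread()` is the (n-1)-denominator standard deviation of the
#' per-replicate mean values, the external-reproducibility scale sigma_Abar.
#' `sampling_quality()` compares it with the mean within-run standard error:
#' for complete conformational sampling the two scales agree (ratio near 1),
#' while trapped replicates inflate the across-replicate spread. The ratio is
#' flagged `"ok"` up to 2, `"warning"` in (2, 5], `"severe"` above 5.
#'
#' @param replicate_means per-replicate mean values (n >= 2).
#' @param sigma_across across-replicate standard deviation.
#' @param mean_se mean within-run standard error (> 0).
#' @return `replicate_spread()`: a scalar; `sampling_quality()`: list with
#'   `ratio` and `flag`.
#' @export
replicate_spread <- function(replicate_means) {
  if (length(replicate_means) < 2)
    stop("need at least 2 replicate means", call. = FALSE)
  stats::sd(replicate_means)
}

#' @rdname replicate_spread
#' @export
sampling_quality <- function(sigma_across, mean_se) {
  if (!is.finite(mean_se) || mean_se <= 0)
    stop("mean standard error must be positive", call. = FALSE)
  ratio <- sigma_across / mean_se
  flag <- if (ratio > 5) "severe" else if (ratio > 2) "warning" else "ok"
  list(ratio = ratio, flag = flag)
}

#' Per-window diagnostics for a sample table
#'
#' Computes, for each lambda window of a sample table (columns `lam_index`,
#' `dudl`, optionally `gamma_state`), the statistical inefficiency `g`,
#' effective sample size, sampling efficiency `eta`, and standard error of
#' the window mean. Dummy-state samples are excluded. Long window series are
#' thinned-by-truncation to `max_series` points for the autocorrelation fit.
#'
#' @param records sample table (data frame).
#' @param grid a [lambda_grid()].
#' @param max_series cap on the series length used per window.
#' @return data frame with one row per window: `lam_index`, `n`, `mean`,
#'   `sd`, `g`, `n_eff`, `eta`, `se`.
#' @export
window_diagnostics <- function(records, grid, max_series = 50000L) {
  if (!is.null(records$gamma_state))
    records <- records[records$gamma_state == "physical", , drop = FALSE]
  by_win <- split(records$dudl,
                  factor(records$lam_index, levels = seq_len(grid$n_windows)))
  out <- lapply(seq_len(grid$n_windows), function(i) {
    x <- by_win[[i]]
    n <- length(x)
    if (n < 10 || stats::var(x) == 0) {
      return(data.frame(lam_index = i, n = n,
                        mean = if (n) mean(x) else NA_real_,
                        sd = if (n > 1) stats::sd(x) else NA_real_,
                        g = NA_real_, n_eff = NA_real_, eta = NA_real_,
                        se = NA_real_))
    }
    xs <- if (n > max_series) x[seq_len(max_series)] else x
    g <- statistical_inefficiency(xs)
    n_eff <- n / g
    data.frame(lam_index = i, n = n, mean = mean(x), sd = stats::sd(x),
               g = g, n_eff = n_eff, eta = 1 / g,
               se = stats::sd(x) / sqrt(n_eff))
  })
  do.call(rbind, out)
}

# Propagated standard error of a single run's TI estimate: quadrature weights
# squared times per-window variance over effective counts. (The first-power
# interval form used for allocation decisions is not a variance of the
# quadrature sum and would over-scale this by ~1/sqrt(dl).)
run_propagated_se <- function(diag, grid, rule = "simpson") {
  w <- quadrature_weights(grid$n_windows, rule) * grid$delta_lambda
  ok <- is.finite(diag$sd) & is.finite(diag$n_eff) & diag$n_eff > 0
  if (!all(ok)) return(NA_real_)
  sqrt(sum(w^2 * diag$sd^2 / diag$n_eff))
}
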