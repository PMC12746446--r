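#' Lambda grid and bias profile
#'
#' `lambda_grid()` discretises the alchemical coordinate into `n_windows`
#' equally spaced values from 0 to 1 (default 101, i.e. spacing 0.01).
#' `bias_profile()` holds the per-window bias free energies `F_i` that are
#' added to the potential in the lambda-jump weights; `F_1` is gauge-fixed to
#' zero. The bias that flattens the landscape is the negative of the free
#' energy profile, i.e. `F_i = -integral_0^lambda_i <dU/dlambda> dlambda`.
#'
#' @param n_windows number of lambda windows (>= 2).
#' @param f_values numeric vector of per-window bias free energies (kT).
#' @param source provenance label (`"prescan"`, `"running-update"`,
#'   `"exact"`, ...).
#' @return an object of class `lambda_grid` / `bias_profile`.
#' @export
lambda_grid <- function(n_windows = 101L) {
  n_windows <- as.integer(n_windows)
  if (n_windows < 2) stop("need at least 2 lambda windows", call. = FALSE)
  structure(list(n_windows = n_windows,
                 delta_lambda = 1 / (n_windows - 1),
                 values = seq(0, 1, length.out = n_windows)),
            class = "lambda_grid")
}

#' @rdname lambda_grid
#' @export
bias_profile <- function(f_values, source = "running-update") {
  if (!all(is.finite(f_values)))
    stop("bias free energies must be finite", call. = FALSE)
  structure(list(f_values = as.numeric(f_values) - f_values[1L],
                 source = source),
            class = "bias_profile")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("<lambda grid> %d windows, spacing %.4g\n",
              x$n_windows, x$delta_lambda))
  invisible(x)
}

#' Phase 1: sequential scan over all lambda windows
#'
#' Visits the windows 0...1 in order exactly once, propagating the walker at
#' each, and returns the per-window mean `dU/dlambda` and sample counts used
#' to seed the initial bias profile and variance estimates.
#'
#' @inheritParams propagate
#' @param steps_per_window propagation steps spent at each window (>= 1).
#' @param ... further arguments passed to [propagate()].
#' @return list with `means`, `counts`, the advanced `state`, and the raw
#'   `records`.
#' @export
sequential_scan <- function(state, model, grid, steps_per_window, beta = 1,
                            ...) {
  stopifnot(steps_per_window >= 1)
  means <- numeric(grid$n_windows)
  counts <- integer(grid$n_windows)
  recs <- vector("list", grid$n_windows)
  for (i in seq_len(grid$n_windows)) {
    state$lam_index <- i
    out <- tryCatch(
      propagate(state, model, grid, steps_per_window, beta = beta, ...),
      error = function(e) stop("sequential scan failed at window ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    state <- out$state
    means[i] <- mean(out$records$dudl)
    counts[i] <- nrow(out$records)
    recs[[i]] <- out$records
  }
  list(means = means, counts = counts, state = state,
       records = do.call(rbind, recs))
}

#' Build the bias profile by Simpson's rule
#'
#' Integrates the per-window mean `dU/dlambda` with the two-panel Simpson
#' recursion `F_i = F_{i-2} - (dl/3) (y_{i-2} + 4 y_{i-1} + y_i)`, so the bias
#' is the negative of the accumulated free energy profile. The recursion needs
#' two starting values: `F_1 = 0` (gauge) and `F_2` from the trapezoid rule
#' over the first panel (an O(dl^3) one-panel closure).
#'
#' @param dudl_means per-window mean `dU/dlambda` (length `grid$n_windows`).
#' @param grid a [lambda_grid()].
#' @return a [bias_profile()].
#' @export
build_bias_simpson <- function(dudl_means, grid) {
  n <- grid$n_windows
  if (n < 3) stop("Simpson bias needs at least 3 windows", call. = FALSE)
  if (length(dudl_means) != n)
    stop("need one mean per window (", n, ")", call. = FALSE)
  dl <- grid$delta_lambda
  f <- numeric(n)
  f[2L] <- -dl / 2 * (dudl_means[1L] + dudl_means[2L])
  for (i in 3:n)
    f[i] <- f[i - 2L] - dl / 3 * (dudl_means[i - 2L] + 4 * dudl_means[i - 1L] +
                                    dudl_means[i])
  bias_profile(f, source = "running-update")
}

#' Log-weights for a heat-bath lambda jump
#'
#' For the walker's current configuration `r` at window `i`, the log-weight of
#' candidate window `j` is `-beta [U(r, lambda_j) - U(r, lambda_i) + F_j -
#' F_i]`, combining the energetic and bias contributions. The entry at the
#' current window is identically zero (it is excluded from the jump
#' normalisation downstream). Windows with non-finite energy get `-Inf`.
#'
#' @inheritParams propagate
#' @param bias a [bias_profile()].
#' @return numeric vector of log-weights, one per window.
#' @export
jump_log_weights <- function(state, model, grid, bias, beta = 1) {
  i <- state$lam_index
  gamma <- gamma_value(state)
  u <- energy_lambdas(model, state$coords, grid$values, gamma)
  lw <- -beta * ((u - u[i]) + (bias$f_values - bias$f_values[i]))
  bad <- !is.finite(lw)
  bad[i] <- FALSE
  if (any(bad)) {
    warning("non-finite energies at ", sum(bad), " window(s); excluded")
    lw[bad] <- -Inf
  }
  lw
}

#' Heat-bath selection of the next lambda window
#'
#' Samples the next window `j != i` with probability
#' `exp(logw_j) / sum_{k != i} exp(logw_k)` (max-subtracted for overflow
#' safety). The current window is excluded from the normalisation, so the
#' move is forced whenever any candidate has finite weight; this is the
#' printed heat-bath form. `rule = "metropolized"` additionally applies the
#' Metropolized-Gibbs acceptance factor `min(1, (1 - p_i) / (1 - p_j))`
#' (with `p` normalised over all windows including `i`), which restores exact
#' detailed balance with respect to the biased expanded ensemble.
#'
#' @param log_weights log-weight vector from [jump_log_weights()].
#' @param current_index the walker's current window.
#' @param rule `"forced"` (printed heat-bath form) or `"metropolized"`.
#' @return the new window index (may equal `current_index` when all
#'   candidates are `-Inf`, or on a Metropolized rejection).
#' @export
heat_bath_jump <- function(log_weights, current_index,
                           rule = c("forced", "metropolized")) {
  rule <- match.arg(rule)
  n <- length(log_weights)
  if (n < 2) stop("need at least 2 windows", call. = FALSE)
  probs <- heat_bath_probabilities(log_weights, current_index)
  if (all(probs == 0)) return(current_index)  # jump declined
  j <- sample.int(n, 1L, prob = probs)
  if (rule == "metropolized") {
    # p over all windows including the current one
    m <- max(log_weights[is.finite(log_weights)])
    w <- exp(log_weights - m)
    p <- w / sum(w)
    acc <- min(1, (1 - p[current_index]) / (1 - p[j]))
    if (stats::runif(1) >= acc) return(current_index)
  }
  j
}

#' @rdname heat_bath_jump
#' @export
heat_bath_probabilities <- function(log_weights, current_index) {
  lw <- log_weights
  lw[current_index] <- -Inf
  if (all(!is.finite(lw))) return(rep(0, length(lw)))
  m <- max(lw)
  w <- exp(lw - m)
  w[w < 1e-300] <- 0
  w / sum(w)
}
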