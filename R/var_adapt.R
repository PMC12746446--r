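#' Running per-window moments of dU/dlambda
#'
#' A variance tracker keeps a count, running mean, and running sum of squared
#' deviations for each lambda window, updated by Welford's one-pass algorithm
#' (chunk updates use the parallel-merge form, numerically equivalent).
#' The variance is the population form `M2 / n`, matching the definition
#' `Var_i = <x^2>_i - <x>_i^2` used for the variance-proportional targets.
#'
#' @param n_windows number of lambda windows tracked.
#' @param tracker a `variance_tracker`.
#' @param window 1-based window index.
#' @param values numeric vector of new `dU/dlambda` samples for that window.
#' @return `variance_tracker()` and `tracker_update()` return a tracker;
#'   `tracker_variance()` / `tracker_mean()` return per-window vectors
#'   (`NA` where a window has no samples).
#' @export
variance_tracker <- function(n_windows) {
  structure(list(count = integer(n_windows), mean = numeric(n_windows),
                 m2 = numeric(n_windows)),
            class = "variance_tracker")
}

#' @rdname variance_tracker
#' @export
tracker_update <- function(tracker, window, values) {
  stopifnot(window >= 1, window <= length(tracker$count))
  nb <- length(values)
  if (nb == 0) return(tracker)
  mb <- mean(values)
  m2b <- sum((values - mb)^2)
  na <- tracker$count[window]
  if (na == 0L) {
    tracker$count[window] <- nb
    tracker$mean[window] <- mb
    tracker$m2[window] <- m2b
  } else {
    n <- na + nb
    delta <- mb - tracker$mean[window]
    tracker$mean[window] <- tracker$mean[window] + delta * nb / n
    tracker$m2[window] <- tracker$m2[window] + m2b + delta^2 * na * nb / n
    tracker$count[window] <- n
  }
  tracker
}

#' @rdname variance_tracker
#' @export
tracker_variance <- function(tracker) {
  v <- tracker$m2 / tracker$count
  v[tracker$count == 0L] <- NA_real_
  v
}

#' @rdname variance_tracker
#' @export
tracker_mean <- function(tracker) {
  m <- tracker$mean
  m[tracker$count == 0L] <- NA_real_
  m
}

#' Variance-proportional target probabilities with a minimum-probability floor
#'
#' Implements the two-step rule: (1) raw targets proportional to the local
#' variance of `dU/dlambda`, `P_i = Var_i / sum_j Var_j`; (2) a floor
#' `P_i = max(floor_frac * P_max, P_i)` followed by renormalisation, so no
#' window is starved. Windows whose sample count is below `min_samples`
#' have untrusted variance estimates and inherit the mean variance of the
#' trusted windows. If every variance is zero (or nothing is trusted) the
#' uniform distribution is returned.
#'
#' @param x a [variance_tracker()] or a plain numeric variance vector (then
#'   assumed fully trusted).
#' @param min_samples counts below this leave a window's variance untrusted.
#' @param floor_frac floor as a fraction of the maximum raw probability
#'   (default 0.1).
#' @return probability vector (non-negative, sums to 1).
#' @export
target_probabilities <- function(x, min_samples = 10L, floor_frac = 0.1) {
  if (inherits(x, "variance_tracker")) {
    v <- tracker_variance(x)
    trusted <- !is.na(v) & x$count >= min_samples
  } else {
    v <- as.numeric(x)
    trusted <- is.finite(v)
  }
  n <- length(v)
  if (!any(trusted) || all(v[trusted] == 0)) return(rep(1 / n, n))
  v[!trusted] <- mean(v[trusted])
  p <- v / sum(v)
  p <- pmax(p, floor_frac * max(p))
  p / sum(p)
}

#' Variance-weighted modification of jump probabilities
#'
#' Scales the base jump probabilities by the ratio of target probabilities,
#' `P'(i -> j) = P(i -> j) * P_target(j) / P_target(i)`, and renormalises over
#' the candidates so the result is again a probability vector. Entries with
#' zero base probability stay zero.
#'
#' @param base_probabilities base jump probability vector (e.g. from
#'   [heat_bath_probabilities()]).
#' @param targets strictly positive target probabilities (the floor in
#'   [target_probabilities()] guarantees this).
#' @param current_index the walker's current window.
#' @return modified probability vector over the same windows.
#' @export
apply_var_weight <- function(base_probabilities, targets, current_index) {
  stopifnot(length(base_probabilities) == length(targets))
  if (targets[current_index] <= 0)
    stop("target probability at the current window is zero; ",
         "the floor rule should prevent this", call. = FALSE)
  w <- base_probabilities * targets / targets[current_index]
  s <- sum(w)
  if (s == 0) return(w)
  w / s
}

#' Propagated variance of the TI free energy estimate
#'
#' `sigma2_dG = sum_i (dl_i^p / N_i) sigma_i^2` over windows, with `p = 1`
#' the printed error-propagation form and `p = 2` the quadrature-weight
#' variant (`delta_power` switch).
#'
#' @param delta_lambdas per-window lambda intervals.
#' @param n_samples per-window (effective) sample counts, all >= 1.
#' @param variances per-window variances of `dU/dlambda`.
#' @param delta_power exponent on the lambda interval (1 or 2).
#' @return total variance of the TI estimate (scalar, >= 0).
#' @export
ti_variance <- function(delta_lambdas, n_samples, variances,
                        delta_power = 1) {
  stopifnot(length(delta_lambdas) == length(n_samples),
            length(n_samples) == length(variances))
  if (any(n_samples <= 0)) {
    stop("window(s) ", paste(which(n_samples <= 0), collapse = ", "),
         " have no samples", call. = FALSE)
  }
  sum(delta_lambdas^delta_power / n_samples * variances)
}

#' Optimal sample allocation across lambda windows
#'
#' Distributes `total_samples` across windows to control the propagated TI
#' variance. Two rules are available:
#'
#' * `"neyman"` (default): `N_i` proportional to `sqrt(dl_i^p) * sigma_i`,
#'   the exact minimiser of [ti_variance()] at fixed total (Cauchy-Schwarz);
#'   it strictly beats uniform allocation whenever the variances are
#'   heterogeneous.
#' * `"variance"`: `N_i` proportional to `dl_i^p * sigma_i^2`, the
#'   variance-proportional rule used for the sampling-time target
#'   probabilities; it equalises the per-window contribution
#'   `dl_i^p sigma_i^2 / N_i` (uniform marginal contribution), but for
#'   constant `dl` its total [ti_variance()] is identical to uniform
#'   allocation.
#'
#' Integer allocations use largest-remainder rounding, sum exactly to
#' `total_samples`, and every window receives at least one sample. All-zero
#' variances give a uniform allocation.
#'
#' @inheritParams ti_variance
#' @param total_samples total budget (>= number of windows).
#' @param rule allocation rule, see above.
#' @return integer vector of per-window sample counts.
#' @export
neyman_allocation <- function(variances, delta_lambdas, total_samples,
                              rule = c("neyman", "variance"),
                              delta_power = 1) {
  rule <- match.arg(rule)
  n <- length(variances)
  stopifnot(length(delta_lambdas) == n, total_samples >= n,
            all(variances >= 0))
  w <- if (rule == "neyman") {
    sqrt(delta_lambdas^delta_power) * sqrt(variances)
  } else {
    delta_lambdas^delta_power * variances
  }
  if (all(w == 0)) w <- rep(1, n)
  largest_remainder(w / sum(w) * total_samples, total_samples)
}

# Hamilton apportionment with a minimum of one per cell.
largest_remainder <- function(target, total) {
  base <- floor(target)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  # lift empty cells to 1, taking from the largest cells
  while (any(base == 0)) {
    i <- which(base == 0)[1L]
    j <- which.max(base)
    base[i] <- 1
    base[j] <- base[j] - 1
  }
  as.integer(base)
}
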