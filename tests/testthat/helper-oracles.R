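# Independent brute-force oracles and shared fixtures for the suite.

# Literal autocorrelation table: biased covariance about the overall mean.
brute_autocorrelation <- function(x, k) {
  n <- length(x)
  xc <- x - mean(x)
  sum(xc[seq_len(n - k)] * xc[(k + 1):n]) / n / (sum(xc^2) / n)
}

# Literal g = 1 + 2 sum rho_k with the full rho table, truncated at the first
# non-positive autocorrelation, floored at 1.
brute_statistical_inefficiency <- function(x) {
  n <- length(x)
  rho <- vapply(seq_len(n - 1), function(k) brute_autocorrelation(x, k),
                numeric(1))
  first_nonpos <- which(rho <= 0)
  kcut <- if (length(first_nonpos)) first_nonpos[1] - 1 else length(rho)
  max(1, 1 + 2 * sum(rho[seq_len(kcut)]))
}

# Exact composite quadrature oracle on a function of lambda.
brute_quadrature <- function(f, n) {
  g <- alchemTI::lambda_grid(n)
  alchemTI::ti_integrate(f(g$values), g)$dg
}

# Barrier-escape fixture, calibrated once by a pilot scan of step sizes and
# budgets on the 10 kT double-well torsion model and then frozen: step size
# 0.1 keeps the crossing rate below ~4e-7 per step (no spontaneous escape on
# the budget), while 4e5 steps give enough physical-state episodes for the
# occupancy estimate.
aces_fixture <- list(
  model_args = list(n_angles = 1, v = 5, n_fold = 2, phase = 0,
                    k0 = 0.01, k1 = 0.01),
  budget = 4e5, step_size = 0.1, exchange_interval = 100,
  seed_trapped = 1, seed_aces = 101)

# One walker on the torsion double well, optionally with gamma flips; returns
# the fraction of physical-state observations in the theta > 0 well.
run_double_well <- function(aces, budget, step_size, seed,
                            exchange_interval = 100) {
  m <- do.call(alchemTI::torsion_model, aces_fixture$model_args)
  g <- alchemTI::lambda_grid(11)
  st <- alchemTI::walker_state(m, coords = pi / 2, lam_index = 1, seed = seed)
  tot <- 0L; pos <- 0L
  for (i in seq_len(budget / exchange_interval)) {
    out <- alchemTI::propagate(st, m, g, exchange_interval,
                               step_size = step_size, record_interval = 0L)
    st <- out$state
    if (st$gamma_state == "physical") {
      tot <- tot + 1L
      if (st$coords[1] > 0) pos <- pos + 1L
    }
    if (aces) st <- alchemTI::aces_exchange_attempt(st, m, g)$state
  }
  list(occupancy_start = pos / tot, n_physical = tot)
}
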