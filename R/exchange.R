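#' Replica exchange between two walkers
#'
#' Attempts a Metropolis swap of the complete physical payload (coordinates,
#' velocities, lambda index, gamma label) between two walkers. The acceptance
#' criterion uses only true potential energies, never bias terms:
#' `dU = U(r_n, lam_m) + U(r_m, lam_n) - U(r_m, lam_m) - U(r_n, lam_n)`,
#' accepted with probability `min(1, exp(-beta dU))`. Cross energies are
#' evaluated with each configuration's own gamma state (the gamma label
#' travels with the configuration). Each walker's private RNG stream stays
#' with its replica slot; the randomness for the attempt is drawn from
#' `state_m`'s stream.
#'
#' @param state_m,state_n two [walker_state()]s.
#' @param model an [alchemical model][model_systems].
#' @param grid a [lambda_grid()].
#' @param beta inverse temperature (1/kT).
#' @return list with the (possibly swapped) states `state_m`, `state_n`,
#'   `accepted`, and the energy difference `delta_u`. Attempts with
#'   non-finite cross energies are rejected.
#' @export
replica_exchange_attempt <- function(state_m, state_n, model, grid,
                                     beta = 1) {
  lam_m <- grid$values[state_m$lam_index]
  lam_n <- grid$values[state_n$lam_index]
  u_mm <- potential_energy(model, state_m$coords, lam_m, gamma_value(state_m))
  u_nn <- potential_energy(model, state_n$coords, lam_n, gamma_value(state_n))
  u_mn <- potential_energy(model, state_m$coords, lam_n, gamma_value(state_m))
  u_nm <- potential_energy(model, state_n$coords, lam_m, gamma_value(state_n))
  delta_u <- u_nm + u_mn - u_mm - u_nn
  if (!is.finite(delta_u)) {
    return(list(state_m = state_m, state_n = state_n, accepted = FALSE,
                delta_u = delta_u))
  }
  res <- with_stream(state_m$rng_state,
                     delta_u <= 0 || stats::runif(1) < exp(-beta * delta_u))
  state_m$rng_state <- res$rng_state
  accepted <- res$value
  if (accepted) {
    payload <- c("coords", "velocities", "lam_index", "gamma_state")
    tmp <- state_m[payload]
    state_m[payload] <- state_n[payload]
    state_n[payload] <- tmp
  }
  list(state_m = state_m, state_n = state_n, accepted = accepted,
       delta_u = delta_u)
}

#' Pairing schedule for replica exchange rounds
#'
#' The `"fixed"` scheme pairs neighbours (1,2), (3,4), ... every round (the
#' default adjacent-pair protocol for 8 independent walkers). The
#' `"alternating"` scheme interleaves (2,3), (4,5), ... on odd rounds, the
#' usual even/odd sweep for exchange along a ladder.
#'
#' @param n_replicas number of replicas (>= 2).
#' @param round_index 1-based exchange round counter.
#' @param scheme `"fixed"` or `"alternating"`.
#' @return list of integer pairs (1-based, disjoint).
#' @export
pair_schedule <- function(n_replicas, round_index = 1L,
                          scheme = c("fixed", "alternating")) {
  scheme <- match.arg(scheme)
  if (n_replicas < 2) stop("need at least 2 replicas", call. = FALSE)
  offset <- if (scheme == "alternating" && round_index %% 2 == 1L) 1L else 0L
  first <- seq.int(1L + offset, n_replicas - 1L, by = 2L)
  lapply(first, function(i) c(i, i + 1L))
}

#' Two-state torsion-scaling exchange (enhanced-sampling flip)
#'
#' Proposes flipping the walker between the physical state (gamma = 1, full
#' torsional barriers) and the dummy state (gamma = 0, barriers removed) at
#' fixed coordinates and lambda, accepted by the Metropolis criterion on the
#' total Hamiltonian difference `dU = U(r, lam, gamma_new) - U(r, lam,
#' gamma_old)`. A physical -> dummy flip always lowers (or keeps) the energy
#' and is always accepted; the reverse pays the current torsional energy.
#' Dummy-state samples are flagged by `gamma_state` and must be excluded from
#' thermodynamic integration, which runs along the physical coordinate only.
#'
#' @inheritParams replica_exchange_attempt
#' @param state a [walker_state()].
#' @return list with the updated `state`, `accepted`, and `delta_u`.
#' @export
aces_exchange_attempt <- function(state, model, grid, beta = 1) {
  if (!isTRUE(model$has_torsions))
    stop("torsion-scaling exchange requires a model with torsions",
         call. = FALSE)
  lam <- grid$values[state$lam_index]
  g_old <- gamma_value(state)
  g_new <- 1 - g_old
  delta_u <- potential_energy(model, state$coords, lam, g_new) -
    potential_energy(model, state$coords, lam, g_old)
  res <- with_stream(state$rng_state,
                     delta_u <= 0 || stats::runif(1) < exp(-beta * delta_u))
  state$rng_state <- res$rng_state
  if (res$value)
    state$gamma_state <- if (state$gamma_state == "physical") "dummy"
                         else "physical"
  list(state = state, accepted = res$value, delta_u = delta_u)
}
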