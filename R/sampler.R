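#' Walker state for expanded-ensemble sampling
#'
#' A walker bundles everything replica exchange swaps or a sampler advances:
#' coordinates (optionally velocities), the current lambda window index, the
#' gamma state label (`"physical"` = gamma 1, `"dummy"` = gamma 0), a running
#' step counter, and a private RNG stream so that independent replicas have
#' independent, reproducible randomness.
#'
#' @param model an [alchemical model][model_systems].
#' @param coords starting coordinates (default: the origin).
#' @param lam_index 1-based lambda window index.
#' @param gamma_state `"physical"` or `"dummy"`.
#' @param seed integer seed for this walker's private RNG stream.
#' @return an object of class `walker_state`.
#' @export
walker_state <- function(model, coords = rep(0, model$dimension),
                         lam_index = 1L, gamma_state = "physical",
                         seed = 1L) {
  check_coords(model, coords)
  stopifnot(lam_index >= 1, gamma_state %in% c("physical", "dummy"))
  structure(
    list(coords = as.numeric(coords), velocities = NULL,
         lam_index = as.integer(lam_index), gamma_state = gamma_state,
         step = 0L, rng_state = make_rng_stream(seed)),
    class = "walker_state")
}

#' @export
print.walker_state <- function(x, ...) {
  cat(sprintf("<walker> window %d, %s state, step %d, coords [%s]\n",
              x$lam_index, x$gamma_state, x$step,
              paste(signif(x$coords, 4), collapse = ", ")))
  invisible(x)
}

gamma_value <- function(state) if (state$gamma_state == "physical") 1 else 0

# -- private RNG streams ------------------------------------------------------
# Each walker carries its own .Random.seed snapshot; code that consumes the
# stream swaps it into the global RNG, runs, and captures the advanced state.

make_rng_stream <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  get(".Random.seed", envir = globalenv())
}

restore_rng <- function(saved) {
  if (is.null(saved)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", saved, envir = globalenv())
}

# run expr with the walker's stream active; returns list(value, rng_state)
with_stream <- function(rng_state, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng_state, envir = globalenv())
  value <- force(expr)
  new_state <- get(".Random.seed", envir = globalenv())
  restore_rng(old)
  list(value = value, rng_state = new_state)
}

#' Propagate a walker at fixed lambda and gamma
#'
#' Canonical-ensemble propagation at the walker's current window. The default
#' sampler is Metropolis random-walk Monte Carlo, whose invariant distribution
#' is exactly `exp(-beta U(., lambda, gamma))`; a BAOAB-discretised Langevin
#' integrator is available for realism (small-step-size bias applies). One
#' sample record (step, window, gamma state, dU/dlambda, U) is emitted every
#' `record_interval` steps. Identical seeds give identical streams.
#'
#' @param state a [walker_state()].
#' @param model an [alchemical model][model_systems].
#' @param grid a [lambda_grid()] giving the lambda value of `state$lam_index`.
#' @param n_steps number of propagation steps (>= 0).
#' @param beta inverse temperature (1/kT).
#' @param step_size Metropolis proposal half-width, or Langevin time step.
#' @param record_interval record every this many steps (default 1).
#' @param sampler `"metropolis"` (exact) or `"langevin"` (BAOAB).
#' @param gamma_mapping `"fixed"` (two-state scheme) or `"direct"`
#'   (`gamma(lambda) = lambda`); controls both the gamma used in the potential
#'   and the definition of the recorded `dU/dlambda`.
#' @param friction Langevin friction (1/time).
#' @return list with the advanced `state` and a `records` data frame with
#'   columns `step`, `lam_index`, `gamma_state`, `dudl`, `u`, and `coord`
#'   (the coordinate for 1-D models, the collective coordinate
#'   `mean(sin(theta))` for torsion chains).
#' @export
propagate <- function(state, model, grid, n_steps, beta = 1, step_size = 0.5,
                      record_interval = 1L, sampler = c("metropolis",
                                                        "langevin"),
                      gamma_mapping = c("fixed", "direct"), friction = 1) {
  sampler <- match.arg(sampler)
  gamma_mapping <- match.arg(gamma_mapping)
  stopifnot(inherits(state, "walker_state"), n_steps >= 0,
            state$lam_index >= 1, state$lam_index <= grid$n_windows)
  if (n_steps == 0)
    return(list(state = state, records = empty_records()))
  lam <- grid$values[state$lam_index]
  gamma <- if (gamma_mapping == "direct") lam else gamma_value(state)
  res <- with_stream(state$rng_state, {
    if (sampler == "metropolis") {
      propagate_metropolis(model, state$coords, lam, gamma, n_steps, beta,
                           step_size, record_interval,
                           direct = gamma_mapping == "direct")
    } else {
      propagate_baoab(model, state, lam, gamma, n_steps, beta, step_size,
                      friction, record_interval)
    }
  })
  out <- res$value
  if (!all(is.finite(out$u)))
    stop("non-finite energy during propagation at step ",
         state$step + out$step[which(!is.finite(out$u))[1L]], call. = FALSE)
  state$rng_state <- res$rng_state
  state$coords <- out$coords
  if (!is.null(out$velocities)) state$velocities <- out$velocities
  n_rec <- length(out$step)
  records <- structure(
    list(step = state$step + out$step,
         lam_index = rep.int(state$lam_index, n_rec),
         gamma_state = rep.int(state$gamma_state, n_rec),
         dudl = out$dudl, u = out$u, coord = out$coord),
    class = "data.frame", row.names = c(NA_integer_, -n_rec))
  state$step <- state$step + as.integer(n_steps)
  list(state = state, records = records)
}

# fast row-bind of homogeneous record tables
bind_records <- function(lst) {
  lst <- lst[vapply(lst, NROW, 0L) > 0L]
  if (!length(lst)) return(empty_records())
  cols <- names(lst[[1L]])
  out <- lapply(cols, function(cl) unlist(lapply(lst, `[[`, cl),
                                          use.names = FALSE))
  names(out) <- cols
  structure(out, class = "data.frame",
            row.names = c(NA_integer_, -length(out[[1L]])))
}

empty_records <- function() {
  data.frame(step = integer(), lam_index = integer(),
             gamma_state = character(), dudl = numeric(), u = numeric(),
             coord = numeric())
}

propagate_metropolis <- function(model, coords, lam, gamma, n_steps, beta,
                                 step_size, record_interval, direct) {
  if (model$family == "quad") {
    p <- model$parameters
    r <- mc_propagate_quad(coords[1L], lam, p$k0, p$k1, p$c, as.integer(n_steps),
                           beta, step_size, as.integer(record_interval))
    list(coords = r$x, step = r$step, dudl = r$dudl, u = r$u, coord = r$coord)
  } else {
    p <- model$parameters
    r <- mc_propagate_torsion(coords, lam, gamma, p$v, p$n_fold, p$phase,
                              p$scaled, p$k0, p$k1, as.integer(n_steps), beta,
                              step_size, as.integer(record_interval),
                              as.integer(direct))
    list(coords = r$theta, step = r$step, dudl = r$dudl, u = r$u,
         coord = r$coord)
  }
}

# BAOAB splitting of underdamped Langevin dynamics; exact for the Ornstein-
# Uhlenbeck part, velocity-Verlet-like for the rest. Unit masses.
propagate_baoab <- function(model, state, lam, gamma, n_steps, beta, dt,
                            friction, record_interval) {
  d <- model$dimension
  x <- state$coords
  v <- state$velocities
  if (is.null(v)) v <- stats::rnorm(d, sd = sqrt(1 / beta))
  c1 <- exp(-friction * dt)
  c2 <- sqrt((1 - c1^2) / beta)
  grad <- gradient_energy(model, x, lam, gamma)
  n_rec <- if (record_interval > 0) n_steps %/% record_interval else 0
  rec_step <- integer(n_rec); rec_dudl <- numeric(n_rec)
  rec_u <- numeric(n_rec); rec_coord <- numeric(n_rec)
  ir <- 0L
  mapping <- if (gamma == lam && model$has_torsions) "direct" else "fixed"
  for (i in seq_len(n_steps)) {
    v <- v - 0.5 * dt * grad
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * stats::rnorm(d)
    x <- x + 0.5 * dt * v
    if (model$family == "torsion") x <- wrap_angles(x)
    grad <- gradient_energy(model, x, lam, gamma)
    v <- v - 0.5 * dt * grad
    if (record_interval > 0 && i %% record_interval == 0) {
      ir <- ir + 1L
      rec_step[ir] <- i
      rec_dudl[ir] <- dudl(model, x, lam, gamma, mapping = mapping)
      rec_u[ir] <- potential_energy(model, x, lam, gamma)
      rec_coord[ir] <- if (model$family == "torsion") mean(sin(x)) else x[1L]
    }
  }
  list(coords = x, velocities = v, step = rec_step, dudl = rec_dudl,
       u = rec_u, coord = rec_coord)
}

wrap_angles <- function(a) {
  w <- (a + pi) %% (2 * pi)
  w[w <= 0] <- w[w <= 0] + 2 * pi
  w - pi
}
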