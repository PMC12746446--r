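#' Analytic model systems for alchemical free energy calculations
#'
#' The package ships three small model systems with closed-form properties so
#' that every sampler, bias, and estimator component can be validated against
#' an exact answer. Each model exposes a potential energy `U(r, lambda, gamma)`
#' where `lambda` in `[0, 1]` is the alchemical coupling parameter and `gamma`
#' in `[0, 1]` scales selected torsional terms (`gamma = 1` is the physical
#' Hamiltonian, `gamma = 0` the barrier-free dummy state). Energies are in
#' reduced units (kT at `beta = 1`).
#'
#' * `harmonic_model()`: a 1-D oscillator `U = k(lambda) x^2 / 2` with
#'   `k(lambda) = (1 - lambda) k0 + lambda k1`. The free energy profile is
#'   known exactly: `G(lambda) = log(k(lambda)/k0) / (2 beta)` up to a
#'   constant, so `dG(0 -> 1) = log(k1/k0) / (2 beta)`.
#' * `charging_model()`: `U = k(lambda) x^2 / 2 + lambda c x`, a charging-type
#'   coupling with closed-form `G(lambda)` by Gaussian completion. With
#'   `k0 != k1` the variance of `dU/dlambda` changes strongly along lambda,
#'   which is what the variance-adaptive resampling component exploits; with
#'   `k0 = k1` it reduces to a pure linear charging toy with constant variance.
#' * `torsion_model()`: `d` periodic angles with cosine barriers
#'   `v (1 + cos(n theta - phase))` that are multiplied by `gamma` when listed
#'   in `scaled`, plus a lambda-coupled harmonic well on the collective
#'   coordinate `s = mean(sin(theta))`. A two-fold barrier (`n_fold = 2`,
#'   `phase = 0`) gives a symmetric double well at `theta = +/- pi/2` with
#'   barrier height `2 v`, the standard kinetic trap for enhanced-sampling
#'   tests.
#'
#' @param k0,k1 spring constants at the `lambda = 0` and `lambda = 1` end
#'   states (kT per squared coordinate unit).
#' @param c linear coupling strength of the charging term.
#' @param n_angles number of torsion angles.
#' @param v barrier prefactor(s), kT; the double-well barrier height is `2 v`.
#' @param n_fold torsion multiplicities.
#' @param phase torsion phases (radians).
#' @param scaled integer indices of the torsions subject to gamma scaling
#'   (one index gives an sACES-style setup, several an mACES-style one).
#' @return an object of class `alchemical_model`.
#' @examples
#' m <- harmonic_model(k0 = 1, k1 = 4)
#' potential_energy(m, 1, lam = 0.5)
#' analytic_dg(m)            # log(2)
#' @name model_systems
NULL

new_model <- function(name, family, dimension, parameters,
                      has_analytic_dg, has_torsions, class) {
  structure(
    list(name = name, family = family, dimension = as.integer(dimension),
         parameters = parameters, has_analytic_dg = has_analytic_dg,
         has_torsions = has_torsions),
    class = c(class, "alchemical_model"))
}

#' @rdname model_systems
#' @export
harmonic_model <- function(k0 = 1, k1 = 4) {
  stopifnot(k0 > 0, k1 > 0)
  new_model("harmonic", "quad", 1L, list(k0 = k0, k1 = k1, c = 0),
            has_analytic_dg = TRUE, has_torsions = FALSE, "harmonic_model")
}

#' @rdname model_systems
#' @export
charging_model <- function(c = 2, k0 = 1, k1 = 4) {
  stopifnot(k0 > 0, k1 > 0)
  new_model("charging", "quad", 1L, list(k0 = k0, k1 = k1, c = c),
            has_analytic_dg = TRUE, has_torsions = FALSE, "charging_model")
}

#' @rdname model_systems
#' @export
torsion_model <- function(n_angles = 1, v = 5, n_fold = 2, phase = 0,
                          k0 = 1, k1 = 4, scaled = seq_len(n_angles)) {
  stopifnot(n_angles >= 1, k0 > 0, k1 > 0)
  v <- rep_len(v, n_angles)
  n_fold <- rep_len(n_fold, n_angles)
  phase <- rep_len(phase, n_angles)
  stopifnot(all(v >= 0), all(scaled >= 1), all(scaled <= n_angles))
  sc <- seq_len(n_angles) %in% scaled
  new_model("torsion", "torsion", n_angles,
            list(v = v, n_fold = n_fold, phase = phase,
                 k0 = k0, k1 = k1, scaled = sc),
            has_analytic_dg = FALSE, has_torsions = TRUE, "torsion_model")
}

#' @export
print.alchemical_model <- function(x, ...) {
  cat(sprintf("<alchemical model '%s'> dimension %d\n", x$name, x$dimension))
  cat("  parameters:",
      paste(names(x$parameters),
            vapply(x$parameters, function(p) paste(signif(unlist(p), 4),
                                                   collapse = ","), ""),
            sep = "=", collapse = "  "), "\n")
  cat(sprintf("  analytic dG: %s   torsions: %s\n",
              x$has_analytic_dg, x$has_torsions))
  invisible(x)
}

check_coords <- function(model, coords) {
  if (!is.numeric(coords) || length(coords) != model$dimension)
    stop("coords must be a numeric vector of length ", model$dimension,
         call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coords must be finite", call. = FALSE)
  invisible(coords)
}

check_unit <- function(x, what) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1) || any(!is.finite(x)))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

k_of_lambda <- function(p, lam) (1 - lam) * p$k0 + lam * p$k1

#' Potential energy, dU/dlambda, and energy gradient of a model system
#'
#' `potential_energy()` evaluates `U(coords, lam, gamma)` in kT units;
#' torsional terms listed as scaled are multiplied by `gamma`, all other terms
#' are gamma-independent. `dudl()` returns the alchemical derivative
#' `dU/dlambda` at fixed coordinates; with `mapping = "fixed"` (the two-state
#' enhanced-sampling scheme) gamma is held constant, while
#' `mapping = "direct"` treats `gamma(lambda) = lambda` so the scaled torsion
#' term contributes its own derivative. `gradient_energy()` returns
#' `dU/dcoords` (used by the Langevin integrator).
#'
#' @param model an [alchemical model][model_systems].
#' @param coords numeric coordinate vector of length `model$dimension`.
#' @param lam alchemical coupling parameter in `[0, 1]`.
#' @param gamma torsion scaling parameter in `[0, 1]`.
#' @param mapping how gamma rides lambda in the derivative (see above).
#' @return a scalar energy (kT), scalar derivative (kT per unit lambda), or
#'   gradient vector.
#' @export
potential_energy <- function(model, coords, lam, gamma = 1) {
  UseMethod("potential_energy")
}

#' @export
potential_energy.alchemical_model <- function(model, coords, lam, gamma = 1) {
  check_coords(model, coords)
  check_unit(lam, "lam"); check_unit(gamma, "gamma")
  energy_lambdas(model, coords, lam, gamma)
}

# vectorised over lam: U(coords, lam_j, gamma) for a whole lambda grid in one
# call (the hot path of the heat-bath jump weights)
energy_lambdas <- function(model, coords, lams, gamma) {
  p <- model$parameters
  if (model$family == "quad") {
    x <- coords[1L]
    0.5 * k_of_lambda(p, lams) * x^2 + lams * p$c * x
  } else {
    g <- ifelse(p$scaled, gamma, 1)
    etors <- sum(g * p$v * (1 + cos(p$n_fold * coords - p$phase)))
    s <- mean(sin(coords))
    etors + 0.5 * k_of_lambda(p, lams) * s^2
  }
}

#' @rdname potential_energy
#' @export
dudl <- function(model, coords, lam, gamma = 1,
                 mapping = c("fixed", "direct")) {
  UseMethod("dudl")
}

#' @export
dudl.alchemical_model <- function(model, coords, lam, gamma = 1,
                                  mapping = c("fixed", "direct")) {
  mapping <- match.arg(mapping)
  check_coords(model, coords)
  check_unit(lam, "lam"); check_unit(gamma, "gamma")
  p <- model$parameters
  if (model$family == "quad") {
    x <- coords[1L]
    0.5 * (p$k1 - p$k0) * x^2 + p$c * x
  } else {
    s <- mean(sin(coords))
    out <- 0.5 * (p$k1 - p$k0) * s^2
    if (mapping == "direct")
      out <- out + sum(p$v[p$scaled] *
                         (1 + cos(p$n_fold[p$scaled] * coords[p$scaled] -
                                    p$phase[p$scaled])))
    out
  }
}

#' @rdname potential_energy
#' @export
gradient_energy <- function(model, coords, lam, gamma = 1) {
  UseMethod("gradient_energy")
}

#' @export
gradient_energy.alchemical_model <- function(model, coords, lam, gamma = 1) {
  check_coords(model, coords)
  check_unit(lam, "lam"); check_unit(gamma, "gamma")
  p <- model$parameters
  if (model$family == "quad") {
    k_of_lambda(p, lam) * coords[1L] + lam * p$c
  } else {
    g <- ifelse(p$scaled, gamma, 1)
    d <- model$dimension
    s <- mean(sin(coords))
    -g * p$v * p$n_fold * sin(p$n_fold * coords - p$phase) +
      k_of_lambda(p, lam) * s * cos(coords) / d
  }
}

#' Exact free energy difference between two lambda states
#'
#' For models with a closed-form partition function this returns the exact
#' Helmholtz free energy difference `G(lam_b) - G(lam_a)` (kT units), the
#' oracle against which thermodynamic-integration estimates are checked.
#' For the quadratic family, completing the square in
#' `U = k(lambda) x^2 / 2 + lambda c x` gives
#' `G(lambda) = log(k(lambda)) / (2 beta) - lambda^2 c^2 / (2 k(lambda))`
#' up to an additive constant.
#'
#' @inheritParams potential_energy
#' @param lam_a,lam_b end points of the transformation, in `[0, 1]`.
#' @param beta inverse temperature (1/kT); default 1.
#' @return free energy difference in kT, or an error for models without an
#'   analytic oracle (check `model$has_analytic_dg`).
#' @export
analytic_dg <- function(model, lam_a = 0, lam_b = 1, beta = 1) {
  UseMethod("analytic_dg")
}

#' @export
analytic_dg.alchemical_model <- function(model, lam_a = 0, lam_b = 1,
                                         beta = 1) {
  if (!isTRUE(model$has_analytic_dg))
    stop("analytic free energy unavailable for model '", model$name, "'",
         call. = FALSE)
  check_unit(lam_a, "lam_a"); check_unit(lam_b, "lam_b")
  stopifnot(beta > 0)
  g <- function(lam) {
    p <- model$parameters
    k <- k_of_lambda(p, lam)
    log(k) / (2 * beta) - lam^2 * p$c^2 / (2 * k)
  }
  g(lam_b) - g(lam_a)
}

#' Analytic conditional moments of dU/dlambda
#'
#' For the quadratic family the equilibrium distribution at fixed lambda is
#' Gaussian, so the mean and variance of `dU/dlambda = (k1 - k0) x^2 / 2 + c x`
#' are available in closed form. These analytic profiles drive the exact-bias
#' and variance-adaptive oracles in the test-suite.
#'
#' @inheritParams analytic_dg
#' @param lam lambda value(s) in `[0, 1]` (vectorised).
#' @return numeric vector of conditional means (`analytic_dudl_mean`) or
#'   variances (`analytic_dudl_var`).
#' @export
analytic_dudl_mean <- function(model, lam, beta = 1) {
  stopifnot(model$family == "quad", beta > 0)
  check_unit(lam, "lam")
  p <- model$parameters
  k <- k_of_lambda(p, lam)
  a <- 0.5 * (p$k1 - p$k0)
  mu <- -lam * p$c / k
  s2 <- 1 / (beta * k)
  a * (mu^2 + s2) + p$c * mu
}

#' @rdname analytic_dudl_mean
#' @export
analytic_dudl_var <- function(model, lam, beta = 1) {
  stopifnot(model$family == "quad", beta > 0)
  check_unit(lam, "lam")
  p <- model$parameters
  k <- k_of_lambda(p, lam)
  a <- 0.5 * (p$k1 - p$k0)
  mu <- -lam * p$c / k
  s2 <- 1 / (beta * k)
  2 * a^2 * s2^2 + 4 * a^2 * mu^2 * s2 + 4 * a * p$c * mu * s2 + p$c^2 * s2
}

#' Exact bias profile from the analytic free energy
#'
#' Returns the per-window bias `F_i = -(G(lambda_i) - G(lambda_0))` computed
#' from the model's closed-form free energy, i.e. the bias that flattens the
#' lambda landscape perfectly. Used as the oracle in flat-histogram tests.
#'
#' @inheritParams analytic_dg
#' @param grid a [lambda_grid()].
#' @return a [bias_profile()] with source `"exact"`.
#' @export
exact_bias_profile <- function(model, grid, beta = 1) {
  f <- -vapply(grid$values, function(l) analytic_dg(model, 0, l, beta),
               numeric(1))
  bias_profile(f, source = "exact")
}
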