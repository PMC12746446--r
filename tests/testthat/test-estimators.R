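test_that("TI quadrature: exactness classes and the harmonic oracle", {
  g <- lambda_grid(101)
  expect_equal(ti_integrate(rep(0, 101), g)$dg, 0)
  expect_equal(ti_integrate(rep(2.5, 101), g)$dg, 2.5)
  m <- harmonic_model(1, 4)
  est <- ti_integrate(analytic_dudl_mean(m, g$values), g)
  expect_equal(est$dg, log(2), tolerance = 3e-8)
  expect_lt(abs(est$dg - log(2)), 2e-8)
  # trapezoid is first-order worse but consistent
  est_t <- ti_integrate(analytic_dudl_mean(m, g$values), g,
                        rule = "trapezoid")
  expect_equal(est_t$dg, log(2), tolerance = 1e-4)
  # even window count falls back to a trapezoid panel, with a message
  g2 <- lambda_grid(100)
  expect_message(ti_integrate(analytic_dudl_mean(m, g2$values), g2),
                 "trapezoid")
  expect_error(ti_integrate(c(rep(0, 100), NA), g), "every window")
})

test_that("autocorrelation estimator on constructed series", {
  x <- rep_len(c(1, -1), 200)
  expect_equal(autocorrelation(x, 0), 1)
  expect_equal(autocorrelation(x, 1), -199 / 200)  # biased estimator
  set.seed(3)
  z <- rnorm(1e5)
  expect_lt(abs(autocorrelation(z, 1)), 3 / sqrt(1e5))
  expect_error(autocorrelation(rep(2, 50), 1), "zero variance")
})

test_that("statistical inefficiency matches the brute-force oracle exactly", {
  set.seed(14)
  series <- list(
    rnorm(200),
    as.numeric(stats::arima.sim(list(ar = 0.8), 500)),
    as.numeric(stats::arima.sim(list(ar = -0.4), 300)),
    cumsum(rnorm(2000)),                       # strongly correlated
    as.numeric(stats::arima.sim(list(ar = 0.95), 2000)))
  for (x in series)
    expect_equal(statistical_inefficiency(x),
                 brute_statistical_inefficiency(x), tolerance = 1e-12)
})

test_that("statistical inefficiency recovers AR(1) closed forms", {
  set.seed(8)
  z <- rnorm(1e5)
  expect_equal(statistical_inefficiency(z), 1, tolerance = 0.05)
  for (phi in c(0.5, 0.9)) {
    x <- as.numeric(stats::arima.sim(list(ar = phi), 1e5))
    expect_equal(statistical_inefficiency(x), (1 + phi) / (1 - phi),
                 tolerance = 0.15)
  }
})

test_that("effective samples, efficiency, and standard error definitions", {
  set.seed(21)
  z <- rnorm(1000)
  es <- effective_samples(z)
  expect_equal(es$n_eff, 1000 / statistical_inefficiency(z))
  expect_equal(es$eta, 1 / statistical_inefficiency(z))
  expect_true(es$eta > 0 && es$eta <= 1)
  expect_equal(standard_error(z), sd(z) / sqrt(es$n_eff))
  # duplicating every value roughly halves the efficiency
  dup <- rep(z, each = 2)
  expect_equal(effective_samples(dup)$eta, es$eta / 2, tolerance = 0.15)
  # homogeneity: scaling the series scales the SE
  expect_equal(standard_error(3 * z), 3 * standard_error(z))
  # iid normal, N = 100: SE near 1/10
  z2 <- rnorm(100)
  expect_equal(standard_error(z2), 0.1, tolerance = 0.35)
  expect_error(statistical_inefficiency(rnorm(5)), "at least 10")
  expect_error(statistical_inefficiency(rep(1, 50)), "zero variance")
})

test_that("replicate spread and the sampling-quality flags", {
  expect_equal(replicate_spread(c(2, 2, 2)), 0)
  expect_equal(replicate_spread(c(0, 2)), sqrt(2))
  means <- c(0.1, -0.4, 0.7)
  expect_equal(replicate_spread(means + 5), replicate_spread(means))
  expect_error(replicate_spread(1), "at least 2")
  expect_identical(sampling_quality(1, 1)$flag, "ok")
  expect_identical(sampling_quality(3, 1)$flag, "warning")
  expect_identical(sampling_quality(6, 1)$flag, "severe")
  expect_equal(sampling_quality(3, 2)$ratio, 1.5)
  expect_error(sampling_quality(1, 0), "positive")
})

test_that("trapped replicates are detected by the quality ratio", {
  fx <- generate_fixture("dual_well_replicates",
                         list(n = 500, n_replicates = 8, well_mean = 1,
                              within_sd = 0.05), seed = 42)
  means <- tapply(fx$value, fx$replicate, mean)
  ses <- tapply(fx$value, fx$replicate, standard_error)
  q <- sampling_quality(replicate_spread(as.numeric(means)),
                        mean(as.numeric(ses)))
  expect_gt(q$ratio, 2)
  expect_identical(q$flag, "severe")
})

test_that("window diagnostics summarise a sample table per window", {
  m <- harmonic_model(1, 4)
  g <- lambda_grid(5)
  st <- walker_state(m, seed = 2)
  recs <- list()
  for (i in 1:5) {
    st$lam_index <- i
    out <- propagate(st, m, g, 2000)
    st <- out$state
    recs[[i]] <- out$records
  }
  tab <- alchemTI:::bind_records(recs)
  d <- window_diagnostics(tab, g)
  expect_identical(d$n, rep(2000L, 5))
  expect_true(all(d$g >= 1))
  expect_true(all(d$eta > 0 & d$eta <= 1))
  expect_equal(d$n_eff, d$n / d$g)
  expect_equal(d$se, d$sd / sqrt(d$n_eff))
})
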