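test_that("config validation and method labels", {
  expect_error(run_config(model = harmonic_model(), aces = TRUE), "torsions")
  expect_error(run_config(burn_in = 0.6), "burn_in")
  labs <- c(method_label(run_config()),
            method_label(run_config(var = TRUE)),
            method_label(run_config(re = TRUE)),
            method_label(run_config(var = TRUE, re = TRUE)))
  expect_identical(labs, c("ST", "ST+VAR", "ST+RE", "ST+VAR+RE"))
  tm1 <- torsion_model(n_angles = 2, scaled = 1)
  tm2 <- torsion_model(n_angles = 2, scaled = 1:2)
  expect_identical(method_label(run_config(model = tm1, aces = TRUE)),
                   "ST+sACES")
  expect_identical(method_label(run_config(model = tm2, var = TRUE,
                                           re = TRUE, aces = TRUE)),
                   "ST+VAR+RE+mACES")
})

test_that("runs are reproducible bit-for-bit from the master seed", {
  cfg <- run_config(model = harmonic_model(1, 4), n_windows = 21,
                    n_replicas = 3, total_steps = 3e4, seed = 99)
  r1 <- run_samti(cfg)
  r2 <- run_samti(cfg)
  expect_identical(r1$dg, r2$dg)
  expect_identical(r1$visitation, r2$visitation)
  expect_identical(r1$records, r2$records)
  r3 <- run_samti(run_config(model = harmonic_model(1, 4), n_windows = 21,
                             n_replicas = 3, total_steps = 3e4, seed = 100))
  expect_false(identical(r1$dg, r3$dg))
})

test_that("budget accounting is exact for every method label", {
  for (cfg in list(
    run_config(model = harmonic_model(1, 4), n_windows = 21, n_replicas = 3,
               total_steps = 33333, seed = 5),
    run_config(model = harmonic_model(1, 4), n_windows = 21, n_replicas = 3,
               total_steps = 30000, var = TRUE, re = TRUE, seed = 5))) {
    rep <- run_samti(cfg)
    expect_equal(rep$budget$total, cfg$total_steps)
    # one record per step at record_interval 1; 10% burn-in discarded
    expect_lte(abs(nrow(rep$records) - 0.9 * cfg$total_steps),
               cfg$n_replicas + 2)
  }
  ref <- run_reference_ti(run_config(model = harmonic_model(1, 4),
                                     total_steps = 10007, seed = 2), 21)
  expect_equal(ref$budget$total, 10007)
  # uniform per-window allocation up to the integer remainder (pre-burn-in
  # streams differ by at most one chunk's worth of rounding)
  cnt <- tabulate(ref$records$lam_index, 21)
  expect_lte(diff(range(cnt)), 2)
})

test_that("variance weighting never enters the exchange criterion", {
  base <- list(model = harmonic_model(1, 4), n_windows = 21, n_replicas = 4,
               total_steps = 4e4, re = TRUE, seed = 31)
  for (v in c(FALSE, TRUE)) {
    rep <- do.call(run_config, c(base, list(var = v)))
    out <- run_samti(rep)
    log <- out$exchange_log
    expect_true(all(log$accepted[log$delta_u <= 0]))
    # acceptance of uphill swaps consistent with min(1, exp(-dU))
    up <- log[log$delta_u > 0, ]
    if (nrow(up) > 50) {
      p_exp <- mean(pmin(1, exp(-up$delta_u)))
      p_obs <- mean(up$accepted)
      expect_lt(abs(p_obs - p_exp),
                3 * sqrt(p_exp * (1 - p_exp) / nrow(up)) + 0.05)
    }
    # per-pair acceptance rate equals accepts / attempts exactly
    acc <- out$exchange_acceptance
    for (i in seq_len(nrow(acc))) {
      sel <- log$a == acc$a[i] & log$b == acc$b[i]
      expect_equal(acc$rate[i], mean(log$accepted[sel]))
      expect_equal(acc$attempts[i], sum(sel))
    }
  }
})

test_that("adaptive run recovers the analytic free energy", {
  cfg <- run_config(model = harmonic_model(1, 4), n_windows = 51,
                    n_replicas = 4, total_steps = 2e5, var = TRUE, re = TRUE,
                    seed = 7)
  rep <- run_samti(cfg, keep_records = FALSE)
  expect_lt(abs(rep$dg - log(2)), 3 * rep$sigma_abar)
  expect_true(all(rep$diagnostics$n > 0))
  expect_identical(rep$quality$flag, "ok")
})

test_that("seed sweep: across-run spread is consistent with the reported SE", {
  dgs <- numeric(20)
  ses <- numeric(20)
  for (s in 1:20) {
    cfg <- run_config(model = harmonic_model(1, 4), n_windows = 21,
                      n_replicas = 1, total_steps = 2.1e4, seed = 200 + s)
    rep <- run_reference_ti(cfg, n_windows = 21)
    dgs[s] <- rep$dg
    d <- rep$diagnostics
    w <- alchemTI:::quadrature_weights(21, "simpson") / 20
    ses[s] <- sqrt(sum(w^2 * d$sd^2 / d$n_eff))
  }
  ratio <- sd(dgs) / mean(ses)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("fixture generators carry their documented ground truth", {
  iid <- generate_fixture("iid", list(n = 2e4), seed = 1)
  expect_identical(generate_fixture("iid", list(n = 2e4), seed = 1), iid)
  expect_equal(statistical_inefficiency(iid$value), 1, tolerance = 0.1)
  g_hat <- mean(vapply(1:3, function(s) {
    ar <- generate_fixture("ar1", list(n = 1e5, phi = 0.9), seed = s)
    statistical_inefficiency(ar$value)
  }, numeric(1)))
  expect_equal(g_hat, 19, tolerance = 0.15)
  ar <- generate_fixture("ar1", list(n = 100, phi = 0.9), seed = 2)
  expect_equal(attr(ar, "truth")$g, 19)
  expect_error(generate_fixture("ar1", list(phi = 1.2), seed = 1), "phi")
  dw <- generate_fixture("dual_well_replicates", list(n = 200), seed = 3)
  expect_identical(attr(dw, "truth")$expected_flag, "severe")
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  generate_fixture("iid", list(n = 50), seed = 4, file = f)
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.csv(f)), 50)
  unlink(f)
})

test_that("reference ladder exchange between identical Hamiltonians always accepts", {
  cfg <- run_config(model = harmonic_model(2, 2), total_steps = 5e3,
                    seed = 13)
  rep <- run_reference_ti(cfg, n_windows = 5, with_exchange = TRUE)
  expect_true(all(abs(rep$exchange_log$delta_u) < 1e-12))
  expect_true(all(rep$exchange_log$accepted))
})
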