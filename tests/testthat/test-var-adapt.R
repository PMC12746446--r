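test_that("Welford tracker matches batch recomputation", {
  tr <- variance_tracker(3)
  tr <- tracker_update(tr, 1, 5)
  expect_equal(tracker_mean(tr)[1], 5)
  expect_equal(tracker_variance(tr)[1], 0)
  tr <- tracker_update(tr, 2, c(1, 2, 3))
  expect_equal(tracker_mean(tr)[2], 2)
  expect_equal(tracker_variance(tr)[2], 2 / 3)   # population form
  expect_equal(tracker_variance(tr)[3], NA_real_)
  tr2 <- tracker_update(variance_tracker(1), 1, rep(4, 100))
  expect_equal(tracker_variance(tr2)[1], 0)
  # one-pass chunked updates vs a single batch, random data
  set.seed(31)
  x <- rnorm(5000, mean = 3, sd = 2)
  tr3 <- variance_tracker(1)
  for (chunk in split(x, rep(1:50, each = 100)))
    tr3 <- tracker_update(tr3, 1, chunk)
  expect_equal(tracker_mean(tr3)[1], mean(x), tolerance = 1e-10)
  expect_equal(tracker_variance(tr3)[1], sum((x - mean(x))^2) / 5000,
               tolerance = 1e-10)
})

test_that("target probabilities: proportionality, floor rule, edge cases", {
  expect_equal(target_probabilities(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(target_probabilities(c(3, 1)), c(0.75, 0.25))
  # floor lifts starved windows, then renormalises
  expect_equal(target_probabilities(c(98, 1, 1)),
               c(0.98, 0.098, 0.098) / 1.176)
  # scale invariance
  set.seed(9)
  v <- rexp(20)
  expect_equal(target_probabilities(v), target_probabilities(100 * v))
  # all-zero variances: uniform
  expect_equal(target_probabilities(rep(0, 5)), rep(0.2, 5))
  # untrusted windows inherit the mean trusted variance
  tr <- variance_tracker(3)
  tr <- tracker_update(tr, 1, rnorm(100, sd = 2))
  tr <- tracker_update(tr, 2, rnorm(100, sd = 2))
  tr <- tracker_update(tr, 3, c(0, 100))   # only 2 samples: untrusted
  p <- target_probabilities(tr, min_samples = 10)
  v12 <- tracker_variance(tr)[1:2]
  expect_equal(p, target_probabilities(c(v12, mean(v12))))
})

test_that("variance weighting of jump probabilities", {
  expect_equal(apply_var_weight(c(0, 0.5, 0.5), rep(1 / 3, 3), 1),
               c(0, 0.5, 0.5))
  # worked case: base [0.5, 0.5] over candidates with targets [0.3, 0.1],
  # current target 0.6 -> [0.75, 0.25]
  expect_equal(apply_var_weight(c(0.5, 0.5, 0), c(0.3, 0.1, 0.6), 3),
               c(0.75, 0.25, 0))
  # zero base probability stays zero
  w <- apply_var_weight(c(0.7, 0, 0.3), c(0.2, 0.5, 0.3), 1)
  expect_equal(w[2], 0)
  expect_equal(sum(w), 1)
  expect_error(apply_var_weight(c(0.5, 0.5), c(1, 0), 2), "floor")
})

test_that("propagated TI variance follows the printed error propagation", {
  expect_equal(ti_variance(0.1, 5, 2), 0.1 / 5 * 2)
  expect_equal(ti_variance(c(0.5, 0.5), c(10, 10), c(2, 2)), 0.2)
  v1 <- ti_variance(c(0.2, 0.8), c(4, 16), c(1, 3))
  expect_equal(ti_variance(c(0.2, 0.8), 2 * c(4, 16), c(1, 3)), v1 / 2)
  expect_error(ti_variance(c(0.5, 0.5), c(5, 0), c(1, 1)), "2")
  # squared-interval variant
  expect_equal(ti_variance(c(0.5, 0.5), c(10, 10), c(2, 2), delta_power = 2),
               0.1)
})

test_that("allocation rules: worked splits and rounding invariants", {
  dl <- rep(0.25, 4)
  expect_equal(neyman_allocation(rep(1, 4), dl, 100), rep(25L, 4))
  # the variance-proportional rule reproduces the [80, 20] split
  expect_equal(neyman_allocation(c(4, 1), rep(0.5, 2), 100,
                                 rule = "variance"), c(80L, 20L))
  # the Eq-10 minimiser allocates by sigma, not sigma^2
  expect_equal(neyman_allocation(c(4, 1), rep(0.5, 2), 99), c(66L, 33L))
  a <- neyman_allocation(rep(1, 3), rep(1 / 3, 3), 100)
  expect_identical(sum(a), 100L)
  expect_lte(max(a) - min(a), 1L)
  # every window gets at least one sample even with a zero variance
  a2 <- neyman_allocation(c(0, 5, 5), rep(1 / 3, 3), 30)
  expect_identical(sum(a2), 30L)
  expect_true(all(a2 >= 1L))
  expect_equal(neyman_allocation(rep(0, 4), rep(0.25, 4), 100), rep(25L, 4))
})

test_that("optimal allocation dominates uniform; variance rule equalises contributions", {
  set.seed(77)
  for (dp in c(1, 2)) {
    for (rep_i in 1:300) {
      n <- sample(3:12, 1)
      v <- rexp(n) + 0.01
      dl <- rep(1 / n, n)
      total <- n * sample(20:100, 1)
      opt <- neyman_allocation(v, dl, total, rule = "neyman",
                               delta_power = dp)
      uni <- rep(total / n, n)
      expect_lte(ti_variance(dl, opt, v, delta_power = dp),
                 ti_variance(dl, uni, v, delta_power = dp) + 1e-12)
    }
    # strict improvement for heterogeneous variances (continuous allocation)
    v <- c(4, 1, 1)
    dl <- rep(1 / 3, 3)
    nopt <- sqrt(dl^dp * v)
    nopt <- 300 * nopt / sum(nopt)
    expect_lt(ti_variance(dl, nopt, v, delta_power = dp),
              ti_variance(dl, rep(100, 3), v, delta_power = dp))
    # homogeneous variances: equality
    expect_equal(ti_variance(dl, neyman_allocation(rep(2, 3), dl, 300,
                                                   delta_power = dp),
                             rep(2, 3), delta_power = dp),
                 ti_variance(dl, rep(100, 3), rep(2, 3), delta_power = dp))
  }
  # the variance-proportional rule equalises dl * sigma^2 / N (continuous)
  v <- c(8, 2, 4, 1)
  dl <- rep(0.25, 4)
  cont <- dl * v / sum(dl * v) * 1e6
  contrib <- dl * v / cont
  expect_lt(diff(range(contrib)) / mean(contrib), 1e-12)
  # and its integer version matches up to rounding
  alloc <- neyman_allocation(v, dl, 1500, rule = "variance")
  expect_lt(diff(range(dl * v / alloc)) / mean(dl * v / alloc), 0.05)
})
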