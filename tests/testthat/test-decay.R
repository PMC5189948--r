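test_that("time course construction validates its invariants", {
  expect_error(decay_timecourse(c(10, 20), c(1, 1)), "first time point")
  expect_error(decay_timecourse(c(0, 10, 5), c(1, 1, 1)), "strictly increasing")
  expect_error(decay_timecourse(c(0, 10), matrix(c(0, 1, 5, 2), 2)),
               "replicate 1 has non-positive intensity at time 0")
  expect_error(decay_timecourse(c(0, 10, 20), c(1, 1)), "one row per time point")
})

test_that("normalization divides each replicate by its own time-0 value", {
  tc <- decay_timecourse(c(0, 10, 20), c(100, 50, 25))
  norm <- normalize_timecourse(tc)
  expect_equal(unname(norm$intensities[, 1]), c(1, 0.5, 0.25))

  two <- decay_timecourse(c(0, 10), cbind(c(100, 50), c(200, 100)))
  norm2 <- normalize_timecourse(two)
  expect_equal(unname(norm2$intensities[, 1]), unname(norm2$intensities[, 2]))

  # zero at t > 0 is floored to 1e-6 of t0 and flagged, not dropped
  fl <- normalize_timecourse(decay_timecourse(c(0, 10, 20), c(80, 0, 20)))
  expect_equal(unname(fl$intensities[, 1]), c(1, 1e-6, 0.25))
  expect_equal(fl$n_floored, 1L)
})

test_that("replicate averaging gives pointwise mean and sample sd", {
  tc <- normalize_timecourse(
    decay_timecourse(c(0, 10), cbind(c(1, 0.4), c(1, 0.6)) * 100))
  avg <- average_replicates(tc)
  expect_equal(avg$mean, c(1, 0.5))
  expect_equal(avg$sd, c(0, sd(c(0.4, 0.6))))

  single <- normalize_timecourse(decay_timecourse(c(0, 10), c(10, 5)))
  expect_warning(avg1 <- average_replicates(single), "single replicate")
  expect_equal(avg1$mean, c(1, 0.5))
  expect_equal(avg1$sd, c(0, 0))

  triple <- normalize_timecourse(
    decay_timecourse(c(0, 10), cbind(c(4, 2), c(4, 2), c(4, 2))))
  expect_equal(average_replicates(triple)$sd, c(0, 0))

  expect_error(average_replicates(decay_timecourse(c(0, 10), c(4, 2))),
               "normalize")
})

test_that("log-linear fit recovers exact exponential decay constants", {
  t <- seq(0, 60, by = 10)
  halving <- fit_half_life(decay_timecourse(t, 100 * 0.5^(t / 10)))
  expect_equal(halving$t_half, 10.0, tolerance = 1e-10)
  expect_equal(halving$r_squared, 1, tolerance = 1e-10)

  # the unstressed regime: ~26 min half-life
  slow <- fit_half_life(decay_timecourse(t, exp(-log(2) * t / 26)))
  expect_equal(slow$t_half, 26.0, tolerance = 1e-8)
  expect_equal(slow$k, log(2) / 26, tolerance = 1e-8)
})

test_that("non-decaying series is flagged stable with infinite half-life", {
  fit <- fit_half_life(decay_timecourse(c(0, 10, 20, 30), rep(5, 4)))
  expect_identical(fit$t_half, Inf)
  expect_identical(fit$k, 0)
  expect_true("stable" %in% fit$flags)
  expect_error(fit_half_life(c(0, 10), c(1, 0.5)), "3 time points")
})

test_that("half-life is invariant to replicate scale and consistent across time units", {
  t <- seq(0, 60, by = 10)
  raw <- cbind(100 * exp(-log(2) * t / 13), 250 * exp(-log(2) * t / 13))
  base <- fit_half_life(decay_timecourse(t, raw))
  scaled <- fit_half_life(decay_timecourse(t, raw %*% diag(c(7.3, 0.02))))
  expect_equal(scaled$t_half, base$t_half, tolerance = 1e-10)

  hours <- fit_half_life(decay_timecourse(t / 60, raw))
  expect_equal(hours$k, base$k * 60, tolerance = 1e-8)
  expect_equal(hours$t_half * 60, base$t_half, tolerance = 1e-8)
})

test_that("noiseless fits preserve the ordering of true half-lives", {
  t <- seq(0, 60, by = 10)
  est <- vapply(c(5, 10, 20, 40), function(th)
    fit_half_life(decay_timecourse(t, exp(-log(2) * t / th)))$t_half,
    numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("per-replicate fitting reports one half-life per replicate", {
  tc <- simulate_decay(t_half = 13, noise_cv = 0.05, n_replicates = 3, seed = 21)
  fit <- fit_half_life(tc, per_replicate = TRUE)
  expect_equal(nrow(fit$per_replicate), 3)
  expect_true(all(abs(fit$per_replicate$t_half - 13) / 13 < 0.3))
})

test_that("halflife_fit behaves like a fitted model object", {
  t <- seq(0, 60, by = 10)
  tc <- decay_timecourse(t, cbind(100 * exp(-log(2) * t / 26),
                                  90 * exp(-log(2) * t / 26)))
  fit <- fit_half_life(tc)
  expect_named(coef(fit), c("log_intercept", "decay_rate_k", "t_half"))
  expect_equal(unname(predict(fit, 0)), 1, tolerance = 1e-8)
  expect_equal(unname(predict(fit, 26)), 0.5, tolerance = 1e-8)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
  expect_output(print(fit), "t1/2")
  expect_output(print(summary(fit)), "mean_fraction")

  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))

  sims <- simulate(fit, nsim = 2, seed = 8)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "decay_timecourse")
  expect_identical(sims[[1]]$times, fit$times)
})
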