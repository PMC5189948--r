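test_that("generators are bit-reproducible under a fixed seed", {
  p1 <- simulate_regulon_pair(n_genes = 300, n_up_shared = 30, n_down_shared = 20,
                              n_up_specific = 10, n_down_specific = 10, seed = 5)
  p2 <- simulate_regulon_pair(n_genes = 300, n_up_shared = 30, n_down_shared = 20,
                              n_up_specific = 10, n_down_specific = 10, seed = 5)
  expect_identical(p1, p2)
  p3 <- simulate_regulon_pair(n_genes = 300, n_up_shared = 30, n_down_shared = 20,
                              n_up_specific = 10, n_down_specific = 10, seed = 6)
  expect_false(identical(p1[[1]]$fc, p3[[1]]$fc))

  expect_identical(simulate_decay(seed = 2), simulate_decay(seed = 2))
  expect_identical(simulate_ct_table(c(a = 2), seed = 3),
                   simulate_ct_table(c(a = 2), seed = 3))
  expect_error(simulate_decay(), "seed")
})

test_that("a pure-null genome yields no regulated genes at the 2-fold cutoffs", {
  pair <- simulate_regulon_pair(n_genes = 4000, n_up_shared = 0, n_down_shared = 0,
                                n_up_specific = 0, n_down_specific = 0,
                                null_log2fc_sd = 0.1, seed = 9)
  sets <- classify_directional_sets(pair[[1]])
  expect_length(sets$up, 0)
  expect_length(sets$down, 0)
})

test_that("planted shared regulons are detected with very large z-scores", {
  for (s in c(1, 17)) {
    pair <- simulate_regulon_pair(seed = s) # defaults: 400/280 shared genes
    cmp <- compare_conditions(pair[[1]], pair[[2]], method = "analytic")
    expect_gt(cmp$up$z, 5)
    expect_gt(cmp$down$z, 5)
  }
})

test_that("simulated pairs are exchangeable under the analytic score", {
  pair <- simulate_regulon_pair(seed = 31)
  ab <- compare_conditions(pair[[1]], pair[[2]], method = "analytic")
  ba <- compare_conditions(pair[[2]], pair[[1]], method = "analytic")
  expect_equal(ab$up$z, ba$up$z)
  expect_equal(ab$down$z, ba$down$z)
})

test_that("noiseless simulated decay round-trips through the estimator exactly", {
  tc <- simulate_decay(t_half = 10, times = seq(0, 60, 10), noise_cv = 0,
                       seed = 1)
  expect_equal(fit_half_life(tc)$t_half, 10.0, tolerance = 1e-10)
})

test_that("simulated decay noise is multiplicative with mean one", {
  tc <- simulate_decay(t_half = 26, times = c(0, 10), n_replicates = 2000,
                       noise_cv = 0.1, seed = 4)
  eps0 <- tc$intensities[1, ] # true value at t=0 is 1, so this is the noise
  expect_equal(mean(eps0), 1, tolerance = 0.01)
  expect_equal(sd(eps0), 0.1, tolerance = 0.06)
})

test_that("fast decay under sparse sampling is flagged low-confidence", {
  # t1/2 = 2 min sampled every 10 min: most of the curve sits below the
  # detection floor, which is why such proteins need a dense schedule
  tc <- simulate_decay(t_half = 2, times = seq(0, 60, 10), noise_cv = 0,
                       seed = 1)
  fit <- fit_half_life(tc)
  expect_true("low_confidence" %in% fit$flags)
  dense <- simulate_decay(t_half = 2, times = c(0, 3, 6, 9, 12, 20, 30),
                          noise_cv = 0, seed = 1)
  expect_false("low_confidence" %in% fit_half_life(dense)$flags)
})

test_that("Ct simulation round-trips true ratios through the ddCt formula", {
  for (r in c(1, 0.125, 4)) {
    tab <- simulate_ct_table(c(tg = r), ct_noise_sd = 0, seed = 2)
    res <- quantify_expression(tab, "reference", "control")
    expect_equal(res$value, r, tolerance = 1e-10)
  }
})

test_that("noisy Ct estimates concentrate around the true fold change", {
  ests <- vapply(1:500, function(s) {
    tab <- simulate_ct_table(c(tg = 4), ct_noise_sd = 0.2, seed = 1000 + s)
    quantify_expression(tab, "reference", "control")$value
  }, numeric(1))
  gm <- exp(mean(log(ests)))
  expect_gt(gm, 3.5)
  expect_lt(gm, 4.6)
})

test_that("the whole synthetic pipeline runs end to end", {
  out <- tempfile(fileext = ".tsv")
  pair <- simulate_regulon_pair(seed = 12)
  cmp <- compare_conditions(pair[[1]], pair[[2]], n_mc = 2000, seed = 13)
  write_overlap_report(cmp, out)
  back <- utils::read.table(out, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 2)
  expect_gt(min(back$z), 5)
})
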