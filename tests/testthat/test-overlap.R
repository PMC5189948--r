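test_that("analytic z-score matches hand-evaluated hypergeometric moments", {
  res <- analytic_overlap_z(5, 8, 20, 4)
  expect_equal(res$null_mean, 2.0)
  expect_equal(res$null_sd, 0.97333, tolerance = 1e-4)
  expect_equal(res$z, 2.0548, tolerance = 1e-4)
  expect_identical(res$method, "analytic")
})

test_that("analytic moments equal exhaustive pmf enumeration", {
  for (case in list(c(20, 5, 8), c(15, 7, 7), c(30, 1, 29), c(12, 6, 3))) {
    N <- case[1]; n1 <- case[2]; n2 <- case[3]
    en <- enum_hyper_moments(N, n1, n2)
    expect_equal(sum(en$p), 1, tolerance = 1e-12)
    res <- analytic_overlap_z(n1, n2, N, min(n1, n2))
    expect_equal(res$null_mean, en$mean, tolerance = 1e-12)
    expect_equal(res$null_sd, en$sd, tolerance = 1e-12)
  }
})

test_that("degenerate nulls are flagged instead of producing numeric z", {
  empty <- analytic_overlap_z(0, 7, 20, 0)
  expect_true(empty$degenerate)
  expect_true(is.na(empty$z))
  expect_equal(empty$null_mean, 0)

  saturated <- analytic_overlap_z(20, 20, 20, 20)
  expect_true(saturated$degenerate)
  expect_true(is.na(saturated$z))
  expect_equal(saturated$null_mean, 20)

  u <- make_universe(10)
  mc_sat <- mc_overlap_z(u, u, u, n_mc = 100, seed = 1)
  expect_true(mc_sat$degenerate)
  expect_true(is.na(mc_sat$z))
})

test_that("analytic z is symmetric in the two set sizes", {
  set.seed(3)
  for (i in 1:25) {
    N <- sample(10:500, 1)
    n1 <- sample.int(N, 1); n2 <- sample.int(N, 1)
    k <- sample(0:min(n1, n2), 1)
    a <- analytic_overlap_z(n1, n2, N, k)
    b <- analytic_overlap_z(n2, n1, N, k)
    expect_equal(a$z, b$z)
    expect_equal(a$null_sd, b$null_sd)
  }
})

test_that("Monte-Carlo null is seeded, reproducible and leaves the RNG alone", {
  u <- make_universe(200)
  a <- u[1:30]; b <- u[20:70]
  r1 <- mc_overlap_z(a, b, u, n_mc = 500, seed = 11)
  r2 <- mc_overlap_z(a, b, u, n_mc = 500, seed = 11)
  expect_identical(r1[c("null_mean", "null_sd", "z")],
                   r2[c("null_mean", "null_sd", "z")])
  r3 <- mc_overlap_z(a, b, u, n_mc = 500, seed = 12)
  expect_false(identical(r1$null_mean, r3$null_mean))

  set.seed(99); before <- .Random.seed
  invisible(mc_overlap_z(a, b, u, n_mc = 200, seed = 5))
  expect_identical(before, .Random.seed)

  expect_error(mc_overlap_z(a, b, u, n_mc = 500), "seed")
  expect_error(mc_overlap_z(c(a, "not_in_universe"), b, u, n_mc = 10, seed = 1),
               "subset")
  expect_error(mc_overlap_z(a, b, u, n_mc = 1, seed = 1), "n_mc")
})

test_that("a set compared with itself scores above the random expectation", {
  u <- make_universe(120)
  res <- mc_overlap_z(u[1:25], u[1:25], u, n_mc = 2000, seed = 4)
  expect_equal(res$k_observed, 25L)
  expect_gt(res$z, 0)
})

test_that("Monte-Carlo null mean converges to n1*n2/N across seeds", {
  N <- 200; n1 <- 30; n2 <- 50; n_mc <- 10000
  u <- make_universe(N)
  analytic <- analytic_overlap_z(n1, n2, N, 10)
  se_mean <- analytic$null_sd / sqrt(n_mc)
  for (s in 1:20) {
    res <- mc_overlap_z(u[1:n1], u[1:n2], u, n_mc = n_mc, seed = s)
    expect_lt(abs(res$null_mean - analytic$null_mean), 4 * se_mean)
  }
})

test_that("compare_conditions uses the shared universe and both directions", {
  fc1 <- make_fc(100, up_idx = 1:10, down_idx = 11:18, label = "A")
  # second table measured on a subset of genes, overlapping regulation
  fc2 <- fold_change_table(fc1$fc[21:100], "B")
  fc2$fc[sprintf("g%05d", c(1:5, 30:34))] <- 4   # g1..g5 outside fc2's genes? no: assign adds
  fc2 <- fold_change_table(fc2$fc, "B")

  cmp <- compare_conditions(fc1, fc2, n_mc = 500, seed = 2)
  expect_s3_class(cmp$up, "overlap_z")
  expect_identical(cmp$up$direction, "up")
  expect_identical(cmp$down$direction, "down")
  # intersection universe: genes in both tables only
  expect_equal(cmp$up$N, length(intersect(names(fc1$fc), names(fc2$fc))))

  cmp_union <- compare_conditions(fc1, fc2, n_mc = 500, seed = 2,
                                  universe = "union")
  expect_equal(cmp_union$up$N, length(union(names(fc1$fc), names(fc2$fc))))

  # self-comparison: full overlap, positive z
  self <- compare_conditions(fc1, fc1, n_mc = 500, seed = 3)
  expect_equal(self$up$k_observed, self$up$n1)
  expect_equal(self$down$k_observed, self$down$n2)
  expect_gt(self$up$z, 0)
  expect_gt(self$down$z, 0)

  # analytic method needs no seed and is deterministic
  an1 <- compare_conditions(fc1, fc2, method = "analytic")
  an2 <- compare_conditions(fc1, fc2, method = "analytic")
  expect_identical(as.data.frame(an1), as.data.frame(an2))
})

test_that("overlap results flatten to the 13 documented report columns", {
  df <- as.data.frame(analytic_overlap_z(5, 8, 20, 4, set1_label = "A",
                                         set2_label = "B", direction = "up"))
  expect_identical(names(df),
    c("set1_label", "set2_label", "direction", "n1", "n2", "N", "k_observed",
      "null_mean", "null_sd", "z", "n_mc", "seed", "method"))
})
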