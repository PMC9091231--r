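test_that("bootstrap BIC intervals collapse correctly in degenerate cases", {
  B0 <- cbind(m1 = rep(100, 8), m2 = rep(100, 8))
  ci0 <- bootstrap_bic_ci(B0, c("m1", "m2"), n_boot = 500, seed = 1)
  expect_equal(unname(ci0[c("lower", "upper")]), c(0, 0))

  # constant per-subject difference d: no resampling variance, CI = [n d, n d]
  d <- 3.5
  B1 <- cbind(m1 = rep(100, 10) + d, m2 = rep(100, 10))
  ci1 <- bootstrap_bic_ci(B1, c("m1", "m2"), n_boot = 500, seed = 1)
  expect_equal(unname(ci1[c("lower", "upper", "observed")]),
               c(10 * d, 10 * d, 10 * d))
  expect_error(bootstrap_bic_ci(B1[1, , drop = FALSE], c(1, 2)), "two subjects")
})

test_that("identical evidences split the posterior and protect the exceedance", {
  L <- matrix(-50, nrow = 12, ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  res <- rfx_bms(L, n_draws = 1e5, seed = 3)
  expect_equal(unname(res$expected_p), c(0.5, 0.5), tolerance = 1e-6)
  # no evidence for frequency differences: the omnibus risk favours the
  # equal-frequency hypothesis and pulls the protected exceedance to uniform
  expect_gt(res$bor, 0.5)
  expect_equal(unname(res$pxp), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(res$xp), 1)
})

test_that("overwhelming evidence concentrates posterior and exceedance", {
  set.seed(11)
  L <- matrix(stats::rnorm(50 * 3, -100, 1), 50, 3,
              dimnames = list(NULL, c("win", "lose1", "lose2")))
  L[, "win"] <- L[, "win"] + 10
  res <- rfx_bms(L, n_draws = 1e5, seed = 4)
  expect_gt(res$expected_p[["win"]], 0.95)
  expect_gt(res$pxp[["win"]], 0.99)
  expect_lt(res$bor, 1e-6)
})

test_that("the Dirichlet posterior conserves total concentration", {
  set.seed(2)
  L <- matrix(stats::rnorm(20 * 4, -80, 3), 20, 4)
  res <- rfx_bms(L, n_draws = 1e4, seed = 5)
  expect_equal(sum(res$alpha), 4 * 1 + 20, tolerance = 1e-6)
  expect_equal(sum(res$expected_p), 1, tolerance = 1e-12)
  expect_equal(rowSums(res$assignment), rep(1, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("relabelling models permutes the selection outputs", {
  set.seed(6)
  L <- matrix(stats::rnorm(30 * 3, -60, 2), 30, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  perm <- c(3, 1, 2)
  r1 <- rfx_bms(L, n_draws = 2e5, seed = 8)
  r2 <- rfx_bms(L[, perm], n_draws = 2e5, seed = 8)
  expect_equal(unname(r2$expected_p), unname(r1$expected_p[perm]),
               tolerance = 1e-6)
  expect_equal(unname(r2$xp), unname(r1$xp[perm]), tolerance = 0.01)
  expect_equal(r2$bor, r1$bor, tolerance = 1e-6)
  expect_error(rfx_bms(L[, 1, drop = FALSE]), "two models")
})

test_that("compare_models assembles sums, intervals and BMS coherently", {
  set.seed(13)
  n <- 15
  B <- cbind(uncertainty = stats::rnorm(n, 200, 5),
             count = stats::rnorm(n, 260, 5))
  cmp <- compare_models(B, n_boot = 2000, n_draws = 1e4, seed = 2)
  expect_equal(unname(cmp$bic_sum), unname(colSums(B)))
  expect_true(cmp$pairwise$significant[1])
  expect_lt(cmp$pairwise$upper[1], 0)
  expect_gt(cmp$bms$expected_p[["uncertainty"]], 0.9)
})
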