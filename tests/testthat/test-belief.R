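test_that("belief mean and uncertainty match their closed forms", {
  expect_equal(belief_mean(belief_state(1, 1)), 0.5)
  expect_equal(belief_mean(belief_state(2, 5)), 2 / 7)
  expect_equal(belief_uncertainty(belief_state(1, 1)), sqrt(1 / 12))
  expect_equal(round(belief_uncertainty(belief_state(1, 1)), 3), 0.289)
  expect_equal(belief_uncertainty(belief_state(2, 2)), sqrt(4 / (16 * 5)))
  expect_error(belief_state(0, 1), "positive")
  expect_error(belief_state(1, -2), "positive")
  expect_error(belief_mean(list(alpha = 1, beta = 1)), "belief_state")
})

test_that("moments agree with adaptive numeric integration over the (alpha, beta) grid", {
  # moments via the survival function: E[r^m] = int m t^(m-1) (1 - F(t)) dt,
  # whose integrand stays bounded even when the density diverges at 0 or 1
  vals <- c(0.1, 0.5, 1, 2, 7.3, 20, 50)
  for (a in vals) for (b in vals) {
    num_mean <- stats::integrate(function(t) 1 - stats::pbeta(t, a, b),
                                 0, 1, rel.tol = 1e-11)$value
    num_m2 <- stats::integrate(function(t) 2 * t * (1 - stats::pbeta(t, a, b)),
                               0, 1, rel.tol = 1e-11)$value
    bs <- belief_state(a, b)
    expect_lt(abs(belief_mean(bs) - num_mean), 1e-6)
    expect_lt(abs(belief_uncertainty(bs) - sqrt(num_m2 - num_mean^2)), 1e-6)
  }
})

test_that("uniform-prior uncertainty agrees with a Monte-Carlo oracle", {
  set.seed(421)
  draws <- stats::rbeta(1e6, 1, 1)
  expect_lt(abs(belief_uncertainty(belief_state(1, 1)) - stats::sd(draws)), 1e-3)
})

test_that("updating is conjugate, additive and order-invariant", {
  b <- belief_state(1, 1)
  b2 <- belief_update(b, 1, 4)
  expect_equal(c(b2$alpha, b2$beta), c(2, 5))
  ident <- belief_update(b, 0, 0)
  expect_equal(c(ident$alpha, ident$beta), c(1, 1))
  expect_error(belief_update(b, -1, 0), "non-negative")

  # two-stage update equals one-stage with summed counts
  two <- belief_update(belief_update(b, 2, 1), 1, 1)
  one <- belief_update(b, 3, 2)
  expect_equal(c(two$alpha, two$beta), c(one$alpha, one$beta))

  # every permutation of 3 greens and 2 reds ends in the same state
  perms <- unique(combinat_perms(c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  finals <- lapply(perms, function(p) {
    s <- b
    for (o in p) s <- belief_update(s, as.integer(o), as.integer(!o))
    c(s$alpha, s$beta)
  })
  expect_true(all(vapply(finals, identical, logical(1), finals[[1]])))
})

test_that("every posterior reachable from the uniform prior is less uncertain than it", {
  # exhaustive over all posterior states with up to 25 outcomes
  u0 <- beta_sd(1, 1)
  for (np in 0:25) for (nn in 0:(25 - np)) {
    if (np + nn > 0) expect_lt(beta_sd(1 + np, 1 + nn), u0)
  }
  # but the decrease is not monotone along every path: a lone green after
  # a run of reds widens the posterior again
  expect_gt(beta_sd(2, 11), beta_sd(1, 11))
})

test_that("disconfirming evidence can increase uncertainty under a sharp prior", {
  before <- belief_uncertainty(belief_state(0.2, 8))
  after <- belief_uncertainty(belief_update(belief_state(0.2, 8), 1, 0))
  expect_gt(after, before)
})
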