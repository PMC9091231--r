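test_that("uncertainty-model sampling probability follows the softmax of (U - k)/tau", {
  # midpoint: tolerance equal to the current posterior sd gives p = 0.5
  u0 <- belief_uncertainty(belief_state(1, 1))
  pars <- uncertainty_params(1, 1, k = u0, tau = 0.05)
  expect_equal(p_sample_uncertainty(pars, 0, 0), 0.5)

  # hand-evaluated logistic at the uniform-prior start
  pars2 <- uncertainty_params(1, 1, k = 0.1, tau = 0.05)
  by_hand <- 1 / (1 + exp(-(sqrt(1 / 12) - 0.1) / 0.05))
  expect_equal(p_sample_uncertainty(pars2, 0, 0), by_hand, tolerance = 1e-12)

  # step-function limit: tiny noise with uncertainty above tolerance
  pars3 <- uncertainty_params(1, 1, k = 0.1, tau = 1e-6)
  expect_gt(p_sample_uncertainty(pars3, 0, 0), 1 - 1e-12)

  # a full grid has no sampling decision
  expect_error(p_sample_uncertainty(pars2, 13, 12), "all tiles")
})

test_that("threshold and count policies respond to their own state variables only", {
  thr <- threshold_params(theta = 4, tau = 0.5)
  expect_equal(p_sample_threshold(thr, 5, 1), 0.5)  # |5 - 1| = theta
  cnt <- count_params(n_target = 10, tau = 0.5)
  expect_equal(p_sample_count(cnt, 10), 0.5)
  # outcome composition is irrelevant at a fixed number of samples
  P <- istg:::sample_prob_grid("count", cnt, task_config())
  expect_equal(P[6, 1], P[1, 6])  # (5 green, 0 red) vs (0 green, 5 red)
  expect_equal(P[4, 3], P[2, 5])
  # near-deterministic counter with target 25 exhausts the grid
  cnt2 <- count_params(25, tau = 1e-4)
  tr <- simulate_subject("count", cnt2, seed = 5)
  expect_true(all(tr$n_samples == 25))
})

test_that("stop-point probabilities over one grid sum to one for every model", {
  cfg <- task_config()
  grid <- generate_grid(0.6, 25, seed = 42)
  trials <- stop_point_trials(grid)
  models <- list(
    uncertainty = unc_pars(1.4, 0.8, 0.09, 0.012),
    samplecost = samplecost_params(0.15, 0.4),
    threshold = threshold_params(5, 0.7),
    count = count_params(12, 0.8))
  for (m in names(models)) {
    total <- sum(vapply(seq_len(nrow(trials)), function(i) {
      exp(trial_loglik(m, models[[m]], trials[i, ], cfg))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("a trial with no samples contributes a single stop term", {
  pars <- unc_pars(1, 1, 0.1, 0.05)
  ll <- trial_loglik("uncertainty", pars, make_trial(""), task_config())
  expect_equal(ll, log(1 - p_sample_uncertainty(pars, 0, 0)))
})

test_that("sample-cost planner equals brute-force expectimax on a toy grid", {
  cfg3 <- task_config(grid_size = 3)
  for (cost in c(0, 0.3, 2)) {
    dp <- samplecost_dp(cost, tau = 0.5, cfg3)
    for (np in 0:3) for (nn in 0:(3 - np)) {
      expect_equal(dp$value[np + 1, nn + 1],
                   expectimax_value(np, nn, 3, cost), tolerance = 1e-12)
    }
  }
})

test_that("sample-cost planner limits behave normatively", {
  cfg <- task_config()
  # free information: sampling weakly dominates at the uninformed start
  free <- samplecost_dp(0, tau = 1e-4, cfg)
  expect_gt(free$p_sample[1, 1], 0.49)
  # prohibitive cost: stop immediately
  dear <- samplecost_dp(5, tau = 1e-4, cfg)
  expect_lt(dear$p_sample[1, 1], 1e-6)
})

test_that("likelihood depends on the traversed state path, not outcome totals", {
  pars <- unc_pars(4, 0.5, 0.12, 0.02)
  cfg <- task_config()
  ll_gr <- trial_loglik("uncertainty", pars, make_trial("GR"), cfg)
  ll_rg <- trial_loglik("uncertainty", pars, make_trial("RG"), cfg)
  expect_false(isTRUE(all.equal(ll_gr, ll_rg)))
})

test_that("simulation is reproducible and shows the inverted-U over conditions", {
  pars <- unc_pars(1, 1, 0.09, 0.01)
  a <- simulate_subject("uncertainty", pars, seed = 123)
  b <- simulate_subject("uncertainty", pars, seed = 123)
  expect_identical(a, b)

  mean_n <- tapply(a$n_samples, a$r, mean)
  # inconsistent outcomes (r near 0.5) sustain uncertainty -> more samples
  expect_gt(mean(mean_n[c("0.4", "0.6")]), mean(mean_n[c("0", "1")]))
})

test_that("tolerance at the uniform-prior bound stops sampling immediately", {
  pars <- uncertainty_params(1, 1, k = 0.289, tau = 0.02)
  tr <- simulate_subject("uncertainty", pars, seed = 9)
  expect_gte(mean(tr$n_samples == 0), 0.5)
})

test_that("wider priors at equal mean lead to more sampling", {
  narrow <- unc_pars(5, 5, 0.09, 0.01)
  wide <- unc_pars(1, 1, 0.09, 0.01)
  n_narrow <- mean(simulate_subject("uncertainty", narrow, seed = 31)$n_samples)
  n_wide <- mean(simulate_subject("uncertainty", wide, seed = 31)$n_samples)
  expect_gt(n_wide, n_narrow)
})

test_that("per-state probabilities are strictly inside (0,1) for finite noise", {
  cfg <- task_config()
  models <- list(
    uncertainty = unc_pars(2, 3, 0.1, 0.3),
    samplecost = samplecost_params(0.5, 0.9),
    threshold = threshold_params(3, 0.9),
    count = count_params(8, 0.9))
  for (m in names(models)) {
    P <- istg:::sample_prob_grid(m, models[[m]], cfg)
    vals <- P[!is.na(P)]
    expect_true(all(vals > 0 & vals < 1))
  }
})
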