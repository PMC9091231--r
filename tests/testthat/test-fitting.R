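test_that("BIC formula and ordering", {
  expect_equal(bic(0, 4, exp(1)), 4)
  expect_equal(bic(100, 4, 1000), 4 * log(1000) + 200)
  # with equal parameter counts and sample sizes, BIC orders like nll
  nlls <- c(50, 42, 61)
  expect_equal(order(vapply(nlls, bic, numeric(1), n_params = 2,
                            n_decisions = 300)), order(nlls))
  expect_error(bic(10, 2, 0), ">= 1")
})

test_that("a near-deterministic counting subject is identified exactly", {
  pars <- count_params(10, tau = 0.05)
  trials <- simulate_subject("count", pars, seed = 2)
  fit <- fit_subject(trials, "count", n_starts = 10, seed = 1)
  expect_lt(abs(fit$par[["n_target"]] - 10), 0.5)
})

test_that("duplicating every trial doubles the likelihood but not the estimates", {
  pars <- unc_pars(1.2, 1.5, 0.08, 0.012)
  trials <- simulate_subject("uncertainty", pars, seed = 4)
  doubled <- rbind(trials, transform(trials, trial = trial + 60L))
  f1 <- fit_subject(trials, "uncertainty", n_starts = 10, seed = 3)
  f2 <- fit_subject(doubled, "uncertainty", n_starts = 10, seed = 3)
  expect_equal(f2$nll, 2 * f1$nll, tolerance = 1e-4)
  expect_equal(f2$par, f1$par, tolerance = 1e-2)
  expect_equal(f2$n_decisions, 2L * f1$n_decisions)
})

test_that("estimates respect the parameter box and restarts only help", {
  pars <- unc_pars(1, 2, 0.07, 0.015)
  trials <- simulate_subject("uncertainty", pars, seed = 8)
  b <- param_bounds("uncertainty")
  f5 <- fit_subject(trials, "uncertainty", n_starts = 5, seed = 21)
  f15 <- fit_subject(trials, "uncertainty", n_starts = 15, seed = 21)
  for (f in list(f5, f15)) {
    expect_true(all(f$par >= b$lower - 1e-12))
    expect_true(all(f$par <= b$upper + 1e-12))
  }
  # starting points are nested, so more restarts never lose ground
  expect_lte(f15$nll, f5$nll + 1e-9)
})

test_that("split-half refits are deterministic and identical on identical halves", {
  pars <- unc_pars(1.3, 1.1, 0.09, 0.012)
  half <- simulate_subject("uncertainty", pars, task_config(trials_per_condition = 5),
                           seed = 14)
  mirrored <- rbind(half, transform(half, trial = trial + 30L))
  halves <- split_half_refit(mirrored, n_starts = 8, seed = 5)
  expect_equal(halves$first$par, halves$second$par)
  expect_equal(halves$first$nll, halves$second$nll)
  expect_error(split_half_refit(half[1, ]), "two trials")
})

test_that("cohort fitting returns one row per subject and model", {
  trials <- rbind(
    simulate_subject("uncertainty", unc_pars(), subject_id = "a", age = 12, seed = 1),
    simulate_subject("uncertainty", unc_pars(), subject_id = "b", age = 20, seed = 2))
  fits <- fit_cohort(trials, models = c("uncertainty", "count"),
                     n_starts = 5, seed = 9)
  expect_equal(nrow(fits), 4L)
  expect_setequal(fits$model, c("uncertainty", "count"))
  expect_true(all(is.na(fits$n_target[fits$model == "uncertainty"])))
  expect_true(all(!is.na(fits$alpha0[fits$model == "uncertainty"])))
  B <- bic_matrix_from_fits(fits)
  expect_equal(dim(B), c(2L, 2L))
})
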