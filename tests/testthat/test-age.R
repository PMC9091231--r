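test_that("derived metrics are the prior's mean and sd plus the raw k and tau", {
  fits <- data.frame(subject_id = c("a", "b"), age = c(12, 20),
                     model = "uncertainty",
                     alpha0 = c(1, 3), beta0 = c(1, 1),
                     k = c(0.1, 0.2), tau = c(0.01, 0.02))
  met <- derive_metrics(fits)
  expect_equal(met$prior_belief, c(0.5, 0.75))
  expect_equal(round(met$prior_uncertainty[1], 3), 0.289)
  expect_equal(met$prior_uncertainty[2], sqrt(3 / (16 * 5)))
  expect_equal(met$k, fits$k)
  # row order of the fit table is irrelevant
  met_rev <- derive_metrics(fits[2:1, ])
  expect_equal(met_rev[met_rev$subject_id == "a", -1],
               met[met$subject_id == "a", -1], ignore_attr = TRUE)
  expect_error(derive_metrics(transform(fits, model = "count")), "no Uncertainty")
})

test_that("a noiseless linear metric yields the slope and a null quadratic", {
  age <- seq(10, 24, length.out = 40)
  y <- 0.02 * age + 1
  reg <- robust_age_regression(y, age)
  z_slope <- 0.02 * stats::sd(age)  # slope per z-scored-age unit
  expect_equal(reg$estimate[reg$term == "age_linear"], z_slope,
               tolerance = 1e-8)
  expect_lt(abs(reg$estimate[reg$term == "age_quadratic"]), 1e-8)
  expect_error(robust_age_regression(y[1:5], age[1:5]), "10 subjects")
})

test_that("gross outliers disturb the robust fit less than least squares", {
  set.seed(77)
  n <- 60
  age <- stats::runif(n, 10, 24)
  z <- (age - mean(age)) / stats::sd(age)
  y <- 0.5 + 0.1 * z + stats::rnorm(n, 0, 0.02)
  dirty <- y
  out <- sample(n, n * 0.2)
  dirty[out] <- dirty[out] + sample(c(-1, 1), length(out), TRUE) * 2
  rob <- robust_age_regression(dirty, age)
  ols <- stats::lm(dirty ~ z + I(z^2))
  rob_err <- abs(rob$estimate[rob$term == "age_linear"] - 0.1)
  ols_err <- abs(stats::coef(ols)[["z"]] - 0.1)
  expect_lt(rob_err, ols_err)
})

test_that("Holm correction reproduces the step-down bookkeeping", {
  all_null <- holm_correct(rep(1, 8))
  expect_false(any(all_null$significant))

  one_small <- holm_correct(c(0.001, rep(1, 7)))
  expect_equal(one_small$significant, c(TRUE, rep(FALSE, 7)))

  # a raw p = 0.032 among eight tests with three smaller hits is not
  # significant after the step-down correction
  p8 <- c(0.032, 0.134, 0.0005, 0.002, 0.0008, 0.589, 0.574, 0.040)
  res <- holm_correct(p8)
  expect_false(res$significant[1])
  expect_false(res$significant[8])
  expect_true(all(res$significant[c(3, 4, 5)]))
})

test_that("split-half tests behave on constructed data", {
  n <- 20
  first <- data.frame(alpha0 = seq(0.5, 3, length.out = n),
                      beta0 = seq(2, 0.8, length.out = n))
  ages <- seq(10, 24, length.out = n)

  same <- split_half_tests(first, first, ages)
  expect_equal(same$median_diff, c(0, 0))
  expect_equal(same$wilcoxon_p, c(1, 1))

  # differences decreasing monotonically in age give Spearman rho = -1
  second <- first
  second$alpha0 <- first$alpha0 - rev(seq_len(n)) * 0.01
  res <- split_half_tests(first, second, ages)
  expect_equal(res$spearman_rho[res$parameter == "alpha0"], -1)
})

test_that("trend table flags the designed pattern on an idealized cohort", {
  # metrics built directly from the generator's trends with tiny noise:
  # checks the regression/correction plumbing, not the fitting stage
  set.seed(31)
  n <- 60
  age <- stats::runif(n, 10, 24)
  z <- (age - mean(age)) / stats::sd(age)
  metrics <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)), age = age,
    prior_belief = 0.5 + stats::rnorm(n, 0, 0.05),
    prior_uncertainty = 0.2 + 0.03 * z - 0.02 * z^2 + stats::rnorm(n, 0, 0.01),
    k = 0.09 + 0.012 * z + stats::rnorm(n, 0, 0.008),
    tau = 0.01 + stats::rnorm(n, 0, 0.003))
  tt <- age_trend_table(metrics)
  s <- trend_signs(tt)
  expect_equal(unname(s["prior_uncertainty.age_linear"]), "+")
  expect_equal(unname(s["prior_uncertainty.age_quadratic"]), "-")
  expect_equal(unname(s["k.age_linear"]), "+")
  expect_equal(unname(s["prior_belief.age_linear"]), "0")
  expect_equal(unname(s["tau.age_linear"]), "0")
  expect_true(matches_reference_pattern(tt))
})
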