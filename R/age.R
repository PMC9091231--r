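# Model-derived metrics and their developmental analysis.
#
# Four per-subject metrics come out of the Uncertainty-model fits: prior
# belief (mean of the fitted beta prior), prior belief uncertainty (its
# sd), uncertainty tolerance k, and decision noise tau. Each metric is
# regressed on linear and quadratic z-scored age with a robust
# (Huber M-estimation) linear model; the 4 metrics x 2 age terms = 8
# p-values are Holm-corrected as one family. Split-half stability of the
# fitted prior is checked on the alpha0 / beta0 estimates directly.

#' Derive prior-belief metrics from Uncertainty-model fits
#'
#' @param fits Data.frame from [fit_cohort()]; only rows with
#'   `model == "uncertainty"` are used (an error if none).
#' @return Data.frame per subject: `age`, `prior_belief` (mean of the
#'   fitted beta prior), `prior_uncertainty` (its standard deviation,
#'   bounded above by 0.289), `k`, `tau`.
#' @export
derive_metrics <- function(fits) {
  fits <- fits[fits$model == "uncertainty", , drop = FALSE]
  if (nrow(fits) == 0) stop("no Uncertainty-model fits found")
  data.frame(
    subject_id = fits$subject_id,
    age = fits$age,
    prior_belief = beta_mean_ab(fits$alpha0, fits$beta0),
    prior_uncertainty = beta_sd_ab(fits$alpha0, fits$beta0),
    k = fits$k,
    tau = fits$tau,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Robust regression of a metric on linear and quadratic age
#'
#' Huber M-estimation (tuning constant 1.345, 95% Gaussian efficiency) of
#' `metric ~ z + z^2` where z is z-scored age. P-values use the asymptotic
#' normal theory of the M-estimator (t statistics on n - 3 df).
#'
#' @param y Metric values, one per subject.
#' @param age Ages in years.
#' @return Data.frame with rows `(Intercept)`, `age_linear`,
#'   `age_quadratic`: `estimate`, `se`, `t`, `p`.
#' @export
robust_age_regression <- function(y, age) {
  if (length(y) < 10) stop("at least 10 subjects are required")
  z <- (age - mean(age)) / stats::sd(age)
  dat <- data.frame(y = y, z = z, z2 = z^2)
  fit <- MASS::rlm(y ~ z + z2, data = dat, psi = MASS::psi.huber,
                   k = 1.345, maxit = 100)
  cf <- summary(fit)$coefficients
  p <- 2 * stats::pt(-abs(cf[, "t value"]), df = length(y) - 3)
  data.frame(term = c("(Intercept)", "age_linear", "age_quadratic"),
             estimate = cf[, "Value"], se = cf[, "Std. Error"],
             t = cf[, "t value"], p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Holm (step-down Bonferroni) correction
#'
#' @param p Vector of raw p-values (the 8-test family is 4 metrics x
#'   linear/quadratic age effects).
#' @param alpha Family-wise error rate.
#' @return Data.frame: `p`, `p_holm` (adjusted), `significant`.
#' @export
holm_correct <- function(p, alpha = 0.05) {
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(p = p, p_holm = adj, significant = adj < alpha)
}

#' Age-trend analysis of all four model-derived metrics
#'
#' Runs [robust_age_regression()] for prior belief, prior uncertainty, k
#' and tau, and Holm-corrects the 8 age-effect p-values as one family.
#'
#' @param metrics Data.frame from [derive_metrics()].
#' @param alpha Family-wise error rate.
#' @return Data.frame with one row per metric x age term: estimates,
#'   raw and Holm-adjusted p-values, significance decisions.
#' @export
age_trend_table <- function(metrics, alpha = 0.05) {
  metric_names <- c("prior_belief", "prior_uncertainty", "k", "tau")
  rows <- do.call(rbind, lapply(metric_names, function(mn) {
    reg <- robust_age_regression(metrics[[mn]], metrics$age)
    reg <- reg[reg$term != "(Intercept)", , drop = FALSE]
    cbind(metric = mn, reg)
  }))
  corr <- holm_correct(rows$p, alpha = alpha)
  rows$p_holm <- corr$p_holm
  rows$significant <- corr$significant
  rownames(rows) <- NULL
  rows
}

#' Sign pattern of the age-trend table
#'
#' Compact summary used by trend-recovery studies: for each metric x age
#' term, `"+"` or `"-"` when Holm-significant, `"0"` otherwise.
#'
#' @param trend_table Output of [age_trend_table()].
#' @return Named character vector, e.g. `prior_uncertainty.age_linear`.
#' @export
trend_signs <- function(trend_table) {
  s <- ifelse(!trend_table$significant, "0",
              ifelse(trend_table$estimate > 0, "+", "-"))
  names(s) <- paste(trend_table$metric, trend_table$term, sep = ".")
  s
}

#' Split-half stability tests of the fitted prior
#'
#' Paired two-sided Wilcoxon signed-rank tests on the first- versus
#' second-half alpha0 and beta0 estimates (exact for n <= 25, normal
#' approximation with continuity correction otherwise), plus Spearman rank
#' correlations of the per-subject half-difference with age.
#'
#' @param first,second Data.frames with per-subject `alpha0`, `beta0`
#'   estimates from the two half-session refits (same subject order).
#' @param ages Ages in years, same order.
#' @return Data.frame with one row per parameter: Wilcoxon statistic and
#'   p, median difference, Spearman rho and p.
#'
#' @details The Spearman p-value is computed by Monte-Carlo permutation of
#'   the ages (deterministic internal stream) rather than the asymptotic t
#'   approximation: half-session refits regularly produce tied or
#'   boundary-valued estimates, under which the approximation is
#'   anti-conservative, while the permutation reference is exactly
#'   calibrated regardless of ties.
#' @export
split_half_tests <- function(first, second, ages) {
  n <- nrow(first)
  stopifnot(nrow(second) == n, length(ages) == n)
  do.call(rbind, lapply(c("alpha0", "beta0"), function(par) {
    d <- first[[par]] - second[[par]]
    if (all(d == 0)) {
      # degenerate: no paired difference anywhere, nothing to test
      w <- list(statistic = 0, p.value = 1)
      rho <- NA_real_
      sp <- 1
    } else {
      w <- suppressWarnings(
        stats::wilcox.test(first[[par]], second[[par]], paired = TRUE,
                           exact = n <= 25, correct = TRUE))
      rho <- suppressWarnings(stats::cor(d, ages, method = "spearman"))
      sp <- spearman_perm_p(d, ages)
    }
    data.frame(parameter = par, wilcoxon_v = unname(w$statistic),
               wilcoxon_p = w$p.value, median_diff = stats::median(d),
               spearman_rho = rho, spearman_p = sp,
               stringsAsFactors = FALSE)
  }))
}

# two-sided permutation p for a Spearman correlation; the permutation
# stream is seeded internally and the caller's RNG state is restored
spearman_perm_p <- function(d, ages, n_perm = 1999L) {
  obs <- abs(suppressWarnings(stats::cor(d, ages, method = "spearman")))
  if (is.na(obs)) return(NA_real_)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(770031L)
  perm <- replicate(n_perm, abs(suppressWarnings(
    stats::cor(d, sample(ages), method = "spearman"))))
  (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
}
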