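# Synthetic age-structured cohort.
#
# The generator stands in for the study's participants (n = 157, ages
# 10-24): each simulated subject gets Uncertainty-model parameters drawn
# from age-trend functions plus between-subject noise, and a full
# 60-trial session simulated from those parameters. The default trends
# emulate the developmental pattern the human data showed: prior belief
# uncertainty rising steeply through early-to-mid adolescence and then
# flattening (positive linear, negative quadratic effect of z-scored age),
# uncertainty tolerance rising linearly, prior belief and decision noise
# flat.

#' Moments of a beta distribution
#'
#' @param alpha,beta Beta parameters.
#' @return Named numeric: `mean`, `sd`.
#' @export
beta_moments <- function(alpha, beta) {
  c(mean = beta_mean_ab(alpha, beta), sd = beta_sd_ab(alpha, beta))
}

#' Beta parameters from mean and standard deviation
#'
#' Inverts the moment map: `alpha = m * (m (1 - m) / s^2 - 1)`,
#' `beta = (1 - m) * (m (1 - m) / s^2 - 1)`. Only valid when
#' `s^2 < m (1 - m)` (every beta distribution's variance is below the
#' Bernoulli variance of its mean); infeasible pairs are rejected.
#'
#' @param m Target mean in (0, 1).
#' @param s Target standard deviation.
#' @return Named numeric: `alpha`, `beta`.
#' @export
beta_from_moments <- function(m, s) {
  if (m <= 0 || m >= 1) stop("'m' must lie strictly inside (0, 1)")
  if (s <= 0) stop("'s' must be positive")
  if (s^2 >= m * (1 - m)) {
    stop(sprintf(paste("infeasible (mean, sd) pair: need s^2 < m(1-m);",
                       "got s^2 = %.4g >= %.4g"), s^2, m * (1 - m)))
  }
  nu <- m * (1 - m) / s^2 - 1
  c(alpha = m * nu, beta = (1 - m) * nu)
}

# truncated-normal draws by inverse-cdf (vectorised)
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  q <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  pmin(pmax(q, lower), upper)  # guard against p rounding to 0/1
}

#' Specification of a synthetic cohort
#'
#' Age trends are quadratic polynomials in z-scored age,
#' `intercept + linear * z + quadratic * z^2`, one per generative quantity:
#' prior belief (beta-prior mean), prior belief uncertainty (beta-prior
#' sd), uncertainty tolerance k and decision noise tau. Between-subject
#' noise is truncated normal within each quantity's feasible range.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Ages are drawn uniformly over this range (years).
#' @param trends Named list of `c(intercept, linear, quadratic)` vectors
#'   for `prior_belief`, `prior_uncertainty`, `k`, `tau`.
#' @param noise_sd Named numeric of between-subject noise sds.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 157L,
                        age_range = c(10, 24),
                        trends = list(
                          prior_belief = c(0.50, 0, 0),
                          prior_uncertainty = c(0.230, 0.028, -0.022),
                          k = c(0.090, 0.012, 0),
                          tau = c(0.010, 0, 0)),
                        noise_sd = c(prior_belief = 0.06,
                                     prior_uncertainty = 0.010,
                                     k = 0.008,
                                     tau = 0.003),
                        seed = 1L) {
  need <- c("prior_belief", "prior_uncertainty", "k", "tau")
  stopifnot(all(need %in% names(trends)), all(need %in% names(noise_sd)),
            n_subjects >= 2, diff(age_range) > 0)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 trends = trends, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

trend_value <- function(coefs, z) coefs[1] + coefs[2] * z + coefs[3] * z^2

#' Generate a synthetic cohort
#'
#' Draws per-subject generative parameters from the age trends, maps the
#' (prior mean, prior sd) targets back to (alpha0, beta0) by moment
#' inversion, and simulates each subject's full session under the
#' Uncertainty model.
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [task_config()].
#' @return List with `subjects` (subject_id, age, generative parameters and
#'   their derived prior-belief metrics) and `trials` (all sessions,
#'   trial-level CSV layout).
#' @export
generate_cohort <- function(spec = cohort_spec(), cfg = task_config()) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  z <- (age - mean(age)) / stats::sd(age)

  m <- rtnorm(n, trend_value(spec$trends$prior_belief, z),
              spec$noise_sd["prior_belief"], 0.05, 0.95)
  # feasible sd: below the uniform-prior bound and the moment region, above
  # the most concentrated prior the fitting box can represent
  s_hi <- pmin(0.285, 0.98 * sqrt(m * (1 - m)))
  s <- rtnorm(n, trend_value(spec$trends$prior_uncertainty, z),
              spec$noise_sd["prior_uncertainty"], 0.05, s_hi)
  tau <- rtnorm(n, trend_value(spec$trends$tau, z),
                spec$noise_sd["tau"], 0.005, 0.018)
  # tolerance must sit clearly below the prior uncertainty, or the subject
  # never reveals a tile and produces no modellable behaviour
  k_hi <- pmax(0.012, pmin(0.28, s - 2.5 * tau))
  k <- rtnorm(n, trend_value(spec$trends$k, z),
              spec$noise_sd["k"], 0.01, k_hi)

  ab <- t(mapply(beta_from_moments, m, s))
  subjects <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)), age = age,
    alpha0 = ab[, "alpha"], beta0 = ab[, "beta"], k = k, tau = tau,
    prior_belief = m, prior_uncertainty = s, stringsAsFactors = FALSE)

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- uncertainty_params(subjects$alpha0[i], subjects$beta0[i],
                               subjects$k[i], subjects$tau[i])
    trials[[i]] <- simulate_subject("uncertainty", pars, cfg,
                                    subject_id = subjects$subject_id[i],
                                    age = subjects$age[i],
                                    seed = derive_seed(spec$seed, i, 997L))
  }
  list(subjects = subjects, trials = do.call(rbind, trials))
}
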