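# Beta-Bernoulli belief representation.
#
# A subject's belief about a trustee's reciprocation probability r is a
# beta distribution Beta(r; alpha, beta). alpha counts (pseudo-)observations
# of trustworthy behaviour, beta of untrustworthy behaviour. Both are
# continuous positive reals: the prior pseudo-counts alpha0, beta0 are free
# parameters of the Uncertainty model and need not be integers.

# Floor applied inside closed-form computations so that optimizer probes at
# parameter-box boundaries can never divide by zero.
.BELIEF_EPS <- 1e-6

#' Construct a beta belief state
#'
#' A belief state is a beta distribution over the reciprocation probability
#' of a trustee, parameterised by pseudo-counts of trustworthy (`alpha`) and
#' untrustworthy (`beta`) observations.
#'
#' @param alpha Positive real; pseudo-count of trustworthy observations.
#' @param beta Positive real; pseudo-count of untrustworthy observations.
#' @return An object of class `belief_state`.
#' @examples
#' b <- belief_state(1, 1)          # uniform prior
#' belief_mean(b)                   # 0.5
#' belief_uncertainty(b)            # 0.289 (upper bound)
#' @export
belief_state <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      length(alpha) != 1L || length(beta) != 1L ||
      !is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("'alpha' and 'beta' must be single positive finite numbers")
  }
  structure(list(alpha = alpha, beta = beta), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("Beta belief state: alpha = %.4g, beta = %.4g\n", x$alpha, x$beta))
  cat(sprintf("  mean = %.4f, uncertainty (sd) = %.4f\n",
              belief_mean(x), belief_uncertainty(x)))
  invisible(x)
}

.check_belief <- function(b) {
  if (!inherits(b, "belief_state")) stop("expected a 'belief_state' object")
  b
}

# Vectorised internals used in likelihood hot paths (no class dispatch).
beta_mean_ab <- function(alpha, beta) {
  alpha <- pmax(alpha, .BELIEF_EPS)
  beta <- pmax(beta, .BELIEF_EPS)
  alpha / (alpha + beta)
}

beta_sd_ab <- function(alpha, beta) {
  alpha <- pmax(alpha, .BELIEF_EPS)
  beta <- pmax(beta, .BELIEF_EPS)
  s <- alpha + beta
  sqrt(alpha * beta / (s * s * (s + 1)))
}

#' Mean of a belief state
#'
#' The marginal probability of reciprocation under the belief: integrating
#' the Bernoulli success probability over the beta density gives
#' `alpha / (alpha + beta)`, the mean of the beta distribution.
#'
#' @param b A [belief_state()].
#' @return The marginal reciprocation probability, in (0, 1).
#' @export
belief_mean <- function(b) {
  .check_belief(b)
  beta_mean_ab(b$alpha, b$beta)
}

#' Uncertainty (standard deviation) of a belief state
#'
#' Belief uncertainty is the standard deviation of the beta distribution,
#' `sqrt(alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1)))`. For the
#' uniform prior (1, 1) it equals `sqrt(1/12) = 0.289` (3 d.p.), which upper
#' bounds the uncertainty of any belief reachable from a uniform prior.
#'
#' @param b A [belief_state()].
#' @return The standard deviation, in (0, 0.5).
#' @export
belief_uncertainty <- function(b) {
  .check_belief(b)
  beta_sd_ab(b$alpha, b$beta)
}

#' Update a belief state with observed outcomes
#'
#' Conjugate beta-Bernoulli update: observing `n_pos` trustworthy and
#' `n_neg` untrustworthy outcomes turns Beta(alpha, beta) into
#' Beta(alpha + n_pos, beta + n_neg). The posterior depends only on the
#' outcome counts, never on the order in which tiles were revealed.
#'
#' @param b A [belief_state()].
#' @param n_pos Non-negative count of trustworthy (green) observations.
#' @param n_neg Non-negative count of untrustworthy (red) observations.
#' @return The updated `belief_state`.
#' @export
belief_update <- function(b, n_pos, n_neg) {
  .check_belief(b)
  if (length(n_pos) != 1L || length(n_neg) != 1L ||
      !is.finite(n_pos) || !is.finite(n_neg) || n_pos < 0 || n_neg < 0) {
    stop("'n_pos' and 'n_neg' must be single non-negative counts")
  }
  belief_state(b$alpha + n_pos, b$beta + n_neg)
}
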