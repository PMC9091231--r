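# Sampling-policy models.
#
# Four models of when a participant stops revealing tiles:
#
#   * uncertainty — Bayesian belief distribution over r; the probability of
#     drawing another sample is a softmax of how far the posterior
#     uncertainty (beta sd) still exceeds the subject's uncertainty
#     tolerance k:  p(sample) = 1 / (1 + exp(-(U(alpha, beta) - k) / tau)).
#     Free parameters: alpha0, beta0, k, tau.
#   * samplecost — normative: finite-horizon dynamic programme over states
#     (n_pos, n_neg) with a token cost per sample; choice is a softmax of
#     the action-value difference. Free parameters: cost, tau.
#   * threshold — heuristic, no belief distribution: sample until the
#     absolute difference between green and red counts reaches a subjective
#     threshold theta. Free parameters: theta, tau.
#   * count — sample a fixed target number of tiles regardless of their
#     outcomes. Free parameters: n_target, tau.
#
# All models share the state space (n_pos, n_neg) with n_pos + n_neg < 25
# and emit a per-state probability of sampling; a trial's likelihood is the
# product of one Bernoulli term per sample/stop decision.

#' The four sampling-policy model identifiers
#' @export
MODELS <- c("uncertainty", "samplecost", "threshold", "count")

# Probability clamp keeping log-likelihoods finite at extreme parameters.
.P_CLAMP <- 1e-12

.clamp_p <- function(p) pmin(pmax(p, .P_CLAMP), 1 - .P_CLAMP)

# ---- parameter containers ---------------------------------------------------

.PARAM_NAMES <- list(uncertainty = c("alpha0", "beta0", "k", "tau"),
                     samplecost = c("cost", "tau"),
                     threshold = c("theta", "tau"),
                     count = c("n_target", "tau"))

.new_params <- function(model, values) {
  canon <- .PARAM_NAMES[[model]]
  if (is.null(canon)) stop("unknown model '", model, "'")
  if (length(values) != length(canon)) {
    stop(model, " model takes parameters ", paste(canon, collapse = ", "))
  }
  values <- if (is.null(names(values))) stats::setNames(values, canon)
            else values[canon]
  if (any(is.na(unlist(values)))) {
    stop("parameter names must be ", paste(canon, collapse = ", "))
  }
  structure(as.list(values), class = "istg_params", model = model)
}

#' @export
print.istg_params <- function(x, ...) {
  cat(sprintf("%s model parameters:\n", attr(x, "model")))
  v <- unlist(x)
  cat(paste(sprintf("  %s = %.5g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Parameters of the Uncertainty model
#'
#' @param alpha0,beta0 Prior pseudo-counts of the beta belief over r.
#' @param k Uncertainty tolerance: the posterior-sd level at which the
#'   probability of sampling again drops through one half. Bounded above by
#'   the uniform-prior uncertainty 0.289.
#' @param tau Decision noise (softmax temperature on the uncertainty scale).
#' @return An `istg_params` object.
#' @export
uncertainty_params <- function(alpha0, beta0, k, tau) {
  stopifnot(alpha0 > 0, beta0 > 0, k > 0, tau > 0)
  if (k > 0.289) {  # uniform-prior uncertainty, the declared upper bound
    stop("'k' exceeds the uniform-prior uncertainty bound 0.289")
  }
  .new_params("uncertainty", c(alpha0 = alpha0, beta0 = beta0, k = k, tau = tau))
}

#' Parameters of the Sample Cost model
#'
#' @param cost Token cost per sample (>= 0).
#' @param tau Decision noise on the action-value (token) scale.
#' @return An `istg_params` object.
#' @export
samplecost_params <- function(cost, tau) {
  stopifnot(cost >= 0, tau > 0)
  .new_params("samplecost", c(cost = cost, tau = tau))
}

#' Parameters of the Threshold model
#'
#' @param theta Subjective evidence threshold on |n_pos - n_neg|.
#' @param tau Decision noise on the count scale.
#' @return An `istg_params` object.
#' @export
threshold_params <- function(theta, tau) {
  stopifnot(theta >= 0, tau > 0)
  .new_params("threshold", c(theta = theta, tau = tau))
}

#' Parameters of the Count model
#'
#' @param n_target Target number of samples, in [0, grid size].
#' @param tau Decision noise on the count scale.
#' @return An `istg_params` object.
#' @export
count_params <- function(n_target, tau) {
  stopifnot(n_target >= 0, tau > 0)
  .new_params("count", c(n_target = n_target, tau = tau))
}

params_model <- function(params) attr(params, "model")

params_vector <- function(params) unlist(params)

params_from_vector <- function(model, v) .new_params(model, v)

# ---- per-state sampling probabilities --------------------------------------

# (size+1) x (size+1) matrix P with P[np + 1, nn + 1] = p(sample | state);
# entries for terminal states (np + nn >= size) are NA. One matrix per
# parameter vector makes trial likelihoods pure table lookups.
sample_prob_grid <- function(model, params, cfg = task_config()) {
  size <- cfg$grid_size
  np <- matrix(0:size, size + 1L, size + 1L)
  nn <- t(np)
  P <- switch(model,
    uncertainty = {
      U <- beta_sd_ab(params$alpha0 + np, params$beta0 + nn)
      stats::plogis((U - params$k) / params$tau)
    },
    threshold = stats::plogis((params$theta - abs(np - nn)) / params$tau),
    count = stats::plogis((params$n_target - (np + nn)) / params$tau),
    samplecost = samplecost_dp(params$cost, params$tau, cfg)$p_sample,
    stop("unknown model '", model, "'")
  )
  P[np + nn >= size] <- NA_real_
  P
}

#' State values and sampling policy of the Sample Cost model
#'
#' Finite-horizon dynamic programme over states (n_pos, n_neg). Terminal
#' states (all tiles revealed) are worth the better of investing
#' (expected return `12 * belief_mean`) and keeping the endowment (6).
#' Earlier states compare stopping with paying `cost` for one more sample
#' whose outcome is green with the posterior-predictive probability
#' `belief_mean`; the state value is the max of the two action values and
#' the sampling probability a softmax of their difference. The belief is
#' anchored at the uniform prior (1, 1): the model is normative given the
#' observed tile counts.
#'
#' @param cost Token cost per sample.
#' @param tau Softmax temperature on the token scale.
#' @param cfg A [task_config()].
#' @param prior Beta prior pseudo-counts used by the planner.
#' @return List with matrices `value` and `p_sample` indexed
#'   `[n_pos + 1, n_neg + 1]` (p_sample is NA at terminal states).
#' @export
samplecost_dp <- function(cost, tau, cfg = task_config(), prior = c(1, 1)) {
  size <- cfg$grid_size
  a0 <- prior[1]; b0 <- prior[2]
  invest_gain <- cfg$endowment * cfg$multiplier * cfg$split_fraction
  V <- matrix(NA_real_, size + 1L, size + 1L)
  P <- matrix(NA_real_, size + 1L, size + 1L)
  # terminal diagonal: n_pos + n_neg == size
  np <- 0:size
  m <- (a0 + np) / (a0 + b0 + size)
  V[cbind(np + 1L, size - np + 1L)] <- pmax(invest_gain * m, cfg$endowment)
  for (n in (size - 1L):0L) {
    np <- 0:n
    nn <- n - np
    m <- (a0 + np) / (a0 + b0 + n)
    q_stop <- pmax(invest_gain * m, cfg$endowment)
    v_green <- V[cbind(np + 2L, nn + 1L)]
    v_red <- V[cbind(np + 1L, nn + 2L)]
    q_sample <- -cost + m * v_green + (1 - m) * v_red
    idx <- cbind(np + 1L, nn + 1L)
    P[idx] <- stats::plogis((q_sample - q_stop) / tau)
    V[idx] <- pmax(q_stop, q_sample)
  }
  list(value = V, p_sample = P)
}

#' Per-state sampling probability of the Uncertainty model
#'
#' Evaluates `1 / (1 + exp(-(U(alpha0 + n_pos, beta0 + n_neg) - k) / tau))`
#' where U is the beta-posterior standard deviation: the further the
#' posterior uncertainty still sits above the tolerance k, the more likely
#' another sample.
#'
#' @param params [uncertainty_params()].
#' @param n_pos,n_neg Revealed green / red counts (vectorised).
#' @param grid_size Total tiles; a state with all tiles revealed has no
#'   sample decision and is rejected.
#' @return Probability of sampling again, in (0, 1).
#' @export
p_sample_uncertainty <- function(params, n_pos, n_neg, grid_size = 25L) {
  if (any(n_pos + n_neg >= grid_size)) {
    stop("no sampling decision exists once all tiles are revealed")
  }
  U <- beta_sd_ab(params$alpha0 + n_pos, params$beta0 + n_neg)
  stats::plogis((U - params$k) / params$tau)
}

#' Per-state sampling probability of the Threshold model
#'
#' @inheritParams p_sample_uncertainty
#' @param params [threshold_params()].
#' @return Probability of sampling again while the absolute green-red count
#'   difference is still below the subjective threshold.
#' @export
p_sample_threshold <- function(params, n_pos, n_neg, grid_size = 25L) {
  if (any(n_pos + n_neg >= grid_size)) {
    stop("no sampling decision exists once all tiles are revealed")
  }
  stats::plogis((params$theta - abs(n_pos - n_neg)) / params$tau)
}

#' Per-state sampling probability of the Count model
#'
#' Depends only on how many tiles have been revealed, never on their
#' outcomes.
#'
#' @param params [count_params()].
#' @param n_sampled Number of tiles revealed so far (vectorised).
#' @param grid_size Total tiles.
#' @return Probability of sampling again.
#' @export
p_sample_count <- function(params, n_sampled, grid_size = 25L) {
  if (any(n_sampled >= grid_size)) {
    stop("no sampling decision exists once all tiles are revealed")
  }
  stats::plogis((params$n_target - n_sampled) / params$tau)
}

#' Per-state sampling probability of the Sample Cost model
#'
#' @inheritParams p_sample_uncertainty
#' @param params [samplecost_params()].
#' @param cfg A [task_config()] providing payoffs and horizon.
#' @return Probability of sampling again under the normative planner.
#' @export
p_sample_samplecost <- function(params, n_pos, n_neg, cfg = task_config()) {
  if (any(n_pos + n_neg >= cfg$grid_size)) {
    stop("no sampling decision exists once all tiles are revealed")
  }
  P <- samplecost_dp(params$cost, params$tau, cfg)$p_sample
  P[cbind(n_pos + 1L, n_neg + 1L)]
}

# ---- trial likelihood -------------------------------------------------------

# Pre-encode a trial table into linear indices of the (size+1)^2 state grid:
# one index per observed "sample" decision (the state *before* the tile was
# turned) and one per observed "stop" decision (absent when the grid was
# exhausted, where no choice remains).
encode_decisions <- function(trials, size = 25L) {
  n_trials <- nrow(trials)
  sample_idx <- vector("list", n_trials)
  stop_idx <- integer(0)
  for (i in seq_len(n_trials)) {
    o <- string_to_outcomes(trials$outcomes[i])
    n <- length(o)
    if (n > 0L) {
      np_before <- c(0L, cumsum(o))[seq_len(n)]
      nn_before <- (0:(n - 1L)) - np_before
      sample_idx[[i]] <- np_before + (size + 1L) * nn_before + 1L
    }
    if (n < size) {
      np <- sum(o)
      stop_idx <- c(stop_idx, np + (size + 1L) * (n - np) + 1L)
    }
  }
  list(sample_idx = unlist(sample_idx), stop_idx = stop_idx,
       n_decisions = length(unlist(sample_idx)) + length(stop_idx))
}

nll_from_grid <- function(P, enc) {
  ps <- .clamp_p(P[enc$sample_idx])
  pq <- .clamp_p(1 - P[enc$stop_idx])
  -(sum(log(ps)) + sum(log(pq)))
}

#' Log-likelihood of one trial under a sampling model
#'
#' The trial contributes one Bernoulli term per decision: `log p(sample)`
#' at each of the `n_samples` pre-sample states, plus `log(1 - p(sample))`
#' at the stopping state when the subject stopped before exhausting the
#' grid. A fully revealed grid has no final stop term because no choice
#' remains.
#'
#' @param model One of `"uncertainty"`, `"samplecost"`, `"threshold"`,
#'   `"count"`.
#' @param params Matching parameter object.
#' @param trial One-row trial data.frame (see [validate_trials()]).
#' @param cfg A [task_config()].
#' @return The trial log-likelihood (a non-positive number).
#' @export
trial_loglik <- function(model, params, trial, cfg = task_config()) {
  P <- sample_prob_grid(model, params, cfg)
  enc <- encode_decisions(trial, size = cfg$grid_size)
  -nll_from_grid(P, enc)
}

# Negative log-likelihood closure over a subject's trials; parameters enter
# as the bare numeric vector the optimizer works on.
make_nll <- function(model, trials, cfg = task_config()) {
  enc <- encode_decisions(trials, size = cfg$grid_size)
  force(model); force(cfg)
  fn <- function(par) {
    params <- params_from_vector(model, par)
    P <- sample_prob_grid(model, params, cfg)
    nll_from_grid(P, enc)
  }
  attr(fn, "n_decisions") <- enc$n_decisions
  fn
}

# ---- simulation -------------------------------------------------------------

#' Simulate one subject's session
#'
#' Generates a full session: grids per condition, a walk of the model's
#' sample/stop policy over each grid, and an invest decision. The invest
#' rule (used for synthetic data only; it enters no model's likelihood) is
#' a softmax over expected payoff of investing (`12 *` posterior mean of
#' the belief at stopping, uniform prior for the non-Bayesian models)
#' versus keeping the endowment.
#'
#' @param model Model id.
#' @param params Matching parameter object.
#' @param cfg A [task_config()].
#' @param subject_id Identifier written into the trial table.
#' @param age Age in years written into the trial table.
#' @param seed Optional integer seed; fixed seed gives identical records.
#' @param invest_noise Softmax temperature (token scale) of the invest rule.
#' @return Trial data.frame, one row per trustee.
#' @export
simulate_subject <- function(model, params, cfg = task_config(),
                             subject_id = "s1", age = NA_real_, seed = NULL,
                             invest_noise = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  size <- cfg$grid_size
  P <- sample_prob_grid(model, params, cfg)
  conds <- sample(rep(cfg$conditions, cfg$trials_per_condition))
  n_trials <- length(conds)
  invest_gain <- cfg$endowment * cfg$multiplier * cfg$split_fraction
  if (model == "uncertainty") {
    a0 <- params$alpha0; b0 <- params$beta0
  } else {
    a0 <- 1; b0 <- 1
  }
  out <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    grid <- generate_grid(conds[t], size, exact_counts = cfg$exact_counts)
    np <- 0L; nn <- 0L; n <- 0L
    while (n < size) {
      if (stats::runif(1) >= P[np + 1L, nn + 1L]) break
      if (grid[n + 1L]) np <- np + 1L else nn <- nn + 1L
      n <- n + 1L
    }
    m_post <- (a0 + np) / (a0 + b0 + n)
    p_invest <- stats::plogis((invest_gain * m_post - cfg$endowment) / invest_noise)
    out[[t]] <- data.frame(
      subject_id = subject_id, age = age, trial = t, r = conds[t],
      outcomes = outcomes_to_string(grid[seq_len(n)]),
      n_samples = n, invested = stats::runif(1) < p_invest,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
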