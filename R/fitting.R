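# Per-subject maximum-likelihood estimation.
#
# Each model is fitted to one subject's trials by minimising the summed
# negative log-likelihood of that subject's sample/stop decisions over a
# bounded parameter box, restarting a bounded quasi-Newton optimizer
# (L-BFGS-B, finite-difference gradients) from a seeded Latin-hypercube of
# starting points. Models are compared per subject by BIC.

#' Parameter bounds per model
#'
#' The box the optimizer searches. alpha0 and beta0 cover priors from
#' near-dogmatic to very diffuse; k cannot exceed the uniform-prior
#' uncertainty 0.289; tau is kept above 1e-4 so the softmax stays
#' numerically stable; cost cannot exceed the endowment.
#'
#' @param model Model id.
#' @return List with named numeric vectors `lower` and `upper`.
#' @export
param_bounds <- function(model) {
  switch(model,
    uncertainty = list(
      lower = c(alpha0 = 0.01, beta0 = 0.01, k = 0.001, tau = 1e-4),
      upper = c(alpha0 = 50, beta0 = 50, k = 0.289, tau = 1)),
    samplecost = list(
      lower = c(cost = 0, tau = 1e-4),
      upper = c(cost = 6, tau = 1)),
    threshold = list(
      lower = c(theta = 0, tau = 1e-4),
      upper = c(theta = 25, tau = 1)),
    count = list(
      lower = c(n_target = 0, tau = 1e-4),
      upper = c(n_target = 25, tau = 1)),
    stop("unknown model '", model, "'")
  )
}

# Positive scale parameters are optimized on the log scale: it conditions
# the finite-difference gradients far better when, say, tau ~ 0.01 lives in
# a [1e-4, 1] box, and makes the Latin-hypercube starting points cover the
# small-value end of the box.
.LOG_SCALE_PARS <- c("alpha0", "beta0", "k", "tau")

transform_bounds <- function(model) {
  b <- param_bounds(model)
  log_scale <- names(b$lower) %in% .LOG_SCALE_PARS
  list(lower = ifelse(log_scale, log(b$lower), b$lower),
       upper = ifelse(log_scale, log(b$upper), b$upper),
       log_scale = log_scale, names = names(b$lower))
}

to_natural <- function(par_t, log_scale) {
  ifelse(log_scale, exp(par_t), par_t)
}

# Latin-hypercube starting points, drawn in blocks of 5 with per-block
# derived seeds: the first n starts are a prefix of the first n' > n
# starts, so increasing n_starts can only improve the best optimum found.
start_points <- function(model, n_starts, seed = NULL) {
  tb <- transform_bounds(model)
  d <- length(tb$lower)
  n_blocks <- ceiling(n_starts / 5)
  u <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    if (!is.null(seed)) set.seed(derive_seed(seed, b, 53L))
    lhs::randomLHS(5L, d)
  }))[seq_len(n_starts), , drop = FALSE]
  starts <- sweep(sweep(u, 2, tb$upper - tb$lower, `*`), 2, tb$lower, `+`)
  colnames(starts) <- tb$names
  starts
}

#' Bayesian Information Criterion
#'
#' `BIC = n_params * log(n_decisions) + 2 * nll`. The sample size is the
#' number of observed sample/stop decisions (the unit of observation of
#' the likelihood), not the number of trials.
#'
#' @param nll Minimised negative log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_decisions Number of decisions entering the likelihood.
#' @return The BIC score (lower is better).
#' @export
bic <- function(nll, n_params, n_decisions) {
  if (n_decisions < 1) stop("'n_decisions' must be >= 1")
  n_params * log(n_decisions) + 2 * nll
}

#' Fit one model to one subject by multistart maximum likelihood
#'
#' Minimises the summed negative log-likelihood of the subject's
#' sample/stop decisions with L-BFGS-B from `n_starts` Latin-hypercube
#' starting points.
#'
#' @param trials Trial data.frame of a single subject.
#' @param model Model id (see `MODELS`).
#' @param cfg A [task_config()].
#' @param n_starts Number of optimizer restarts.
#' @param seed Integer seed controlling the starting points.
#' @return An object of class `istg_fit`: best parameters, `nll`, `bic`,
#'   `n_decisions`, and restart diagnostics. If every restart fails the
#'   error is propagated rather than silently returning a bogus fit.
#' @export
fit_subject <- function(trials, model, cfg = task_config(),
                        n_starts = 100L, seed = NULL) {
  trials <- validate_trials(trials, grid_size = cfg$grid_size)
  if (nrow(trials) < 1) stop("at least one trial is required")
  nll_fn <- make_nll(model, trials, cfg)
  b <- param_bounds(model)
  tb <- transform_bounds(model)
  nll_t <- function(par_t) nll_fn(to_natural(par_t, tb$log_scale))
  starts <- start_points(model, n_starts, seed = seed)
  best <- NULL
  n_conv <- 0L
  best_start <- NA_integer_
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[s, ], nll_t, method = "L-BFGS-B",
                   lower = tb$lower, upper = tb$upper,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_start <- s
    }
  }
  if (is.null(best)) {
    stop("no optimizer start converged to a finite likelihood for model '",
         model, "'")
  }
  par <- to_natural(pmin(pmax(best$par, tb$lower), tb$upper), tb$log_scale)
  par <- pmin(pmax(par, b$lower), b$upper)
  names(par) <- tb$names
  n_dec <- attr(nll_fn, "n_decisions")
  structure(list(
    subject_id = trials$subject_id[1],
    model = model,
    params = params_from_vector(model, par),
    par = par,
    nll = best$value,
    bic = bic(best$value, length(par), n_dec),
    n_decisions = n_dec,
    n_starts = n_starts,
    n_converged = n_conv,
    best_start = best_start
  ), class = "istg_fit")
}

#' @export
print.istg_fit <- function(x, ...) {
  cat(sprintf("ISTG fit: subject %s, %s model\n", x$subject_id, x$model))
  cat(paste(sprintf("  %s = %.5g", names(x$par), x$par), collapse = "\n"), "\n")
  cat(sprintf("  nll = %.3f, BIC = %.3f (%d decisions, %d/%d starts converged)\n",
              x$nll, x$bic, x$n_decisions, x$n_converged, x$n_starts))
  invisible(x)
}

fit_row <- function(fit, age = NA_real_) {
  row <- data.frame(subject_id = fit$subject_id, age = age, model = fit$model,
                    alpha0 = NA_real_, beta0 = NA_real_, k = NA_real_,
                    tau = NA_real_, cost = NA_real_, theta = NA_real_,
                    n_target = NA_real_,
                    nll = fit$nll, bic = fit$bic,
                    n_decisions = fit$n_decisions,
                    n_converged = fit$n_converged,
                    stringsAsFactors = FALSE)
  row[names(fit$par)] <- as.list(unname(fit$par))
  row
}

# Bounded derived seed (R integers are 32-bit).
derive_seed <- function(seed, i, j = 0L) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 7919 * i + 104729 * j) %% 2147483647)
}

#' Fit models to every subject of a cohort
#'
#' @param trials Trial data.frame for all subjects (column `subject_id`
#'   partitions it).
#' @param models Character vector of model ids to fit.
#' @param cfg A [task_config()].
#' @param n_starts Optimizer restarts per subject and model.
#' @param seed Base seed; each subject x model gets a derived seed.
#' @param verbose Print one line per subject.
#' @return Data.frame with one row per subject x model: parameter columns
#'   (NA where a parameter does not belong to the model), `nll`, `bic`,
#'   `n_decisions`, `n_converged`.
#' @export
fit_cohort <- function(trials, models = MODELS, cfg = task_config(),
                       n_starts = 100L, seed = NULL, verbose = FALSE) {
  trials <- validate_trials(trials, grid_size = cfg$grid_size)
  ids <- unique(trials$subject_id)
  rows <- vector("list", length(ids) * length(models))
  n <- 0L
  for (i in seq_along(ids)) {
    sub <- trials[trials$subject_id == ids[i], , drop = FALSE]
    age <- sub$age[1]
    for (j in seq_along(models)) {
      fit <- fit_subject(sub, models[j], cfg, n_starts = n_starts,
                         seed = derive_seed(seed, i, j))
      n <- n + 1L
      rows[[n]] <- fit_row(fit, age = age)
    }
    if (verbose) message(sprintf("fitted subject %s (%d/%d)", ids[i], i, length(ids)))
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Refit a model to the first and second half of a session
#'
#' Splits a subject's trials by presentation order into a first and second
#' half and fits each half separately. Downstream stability tests compare
#' the two halves' alpha0 and beta0 estimates directly, because different
#' (alpha0, beta0) pairs can encode the same prior mean.
#'
#' @param trials Trial data.frame of one subject, ordered by `trial`.
#' @param model Model id (default the Uncertainty model).
#' @param cfg A [task_config()].
#' @param n_starts Optimizer restarts per half.
#' @param seed Base seed.
#' @return List with `istg_fit` elements `first` and `second`.
#' @export
split_half_refit <- function(trials, model = "uncertainty",
                             cfg = task_config(), n_starts = 25L,
                             seed = NULL) {
  if (nrow(trials) < 2) stop("at least two trials are required to split")
  trials <- trials[order(trials$trial), , drop = FALSE]
  cut <- floor(nrow(trials) / 2)
  # same derived seed for both halves: identical half-sessions then yield
  # identical fits, so any difference reflects the data, not the restarts
  list(
    first = fit_subject(trials[seq_len(cut), , drop = FALSE], model, cfg,
                        n_starts = n_starts, seed = derive_seed(seed, 1L)),
    second = fit_subject(trials[(cut + 1):nrow(trials), , drop = FALSE],
                         model, cfg, n_starts = n_starts,
                         seed = derive_seed(seed, 1L))
  )
}
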