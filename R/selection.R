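# Group-level model comparison.
#
# Two complementary views: (1) frequentist — the summed per-subject BIC
# difference between model pairs, with a bootstrap confidence interval over
# subjects; (2) random-effects Bayesian model selection (BMS), which treats
# the generating model as a random effect across subjects and returns
# expected posterior model probabilities, exceedance probabilities and
# protected exceedance probabilities.

#' Bootstrap confidence interval of a summed BIC difference
#'
#' Subjects (not trials) are resampled with replacement; each bootstrap
#' replicate sums the per-subject BIC difference for the model pair. A
#' difference is conventionally called not significant when the interval
#' contains zero.
#'
#' @param bic_matrix Numeric matrix, subjects x models (named columns
#'   recommended).
#' @param pair Length-2 vector of column indices or names: the interval is
#'   for `sum(BIC[, pair[1]] - BIC[, pair[2]])`; negative values favour the
#'   first model.
#' @param n_boot Bootstrap iterations.
#' @param seed Optional seed.
#' @param level Confidence level.
#' @return Named numeric: `lower`, `upper`, `observed` (the observed summed
#'   difference).
#' @export
bootstrap_bic_ci <- function(bic_matrix, pair, n_boot = 1e5, seed = NULL,
                             level = 0.95) {
  bic_matrix <- as.matrix(bic_matrix)
  if (nrow(bic_matrix) < 2) stop("at least two subjects are required")
  d <- bic_matrix[, pair[1]] - bic_matrix[, pair[2]]
  n <- length(d)
  if (!is.null(seed)) set.seed(seed)
  sums <- numeric(n_boot)
  # chunked so n_boot = 1e5 never allocates a huge index matrix at once
  chunk <- max(1L, floor(2e6 / n))
  done <- 0L
  while (done < n_boot) {
    m <- min(chunk, n_boot - done)
    idx <- sample.int(n, n * m, replace = TRUE)
    sums[done + seq_len(m)] <- colSums(matrix(d[idx], nrow = n))
    done <- done + m
  }
  q <- stats::quantile(sums, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lower = q[1], upper = q[2], observed = sum(d))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over per-subject model evidences. Model
#' identity is a random effect: each subject's data may come from a
#' different model, with unknown population frequencies given a Dirichlet
#' prior. Returns the expected posterior model probabilities, exceedance
#' probabilities (probability a model is the most frequent, by Dirichlet
#' Monte Carlo), the Bayes omnibus risk (posterior probability that all
#' model frequencies are equal) and protected exceedance probabilities,
#' which shrink the exceedance probabilities towards uniform by the omnibus
#' risk.
#'
#' @param log_evidence Numeric matrix, subjects x models, of per-subject
#'   log model evidences. When only BIC is available use `-BIC / 2`.
#' @param prior_alpha Dirichlet prior concentration per model.
#' @param n_draws Monte-Carlo draws for the exceedance probabilities.
#' @param seed Optional seed for the Monte-Carlo step.
#' @param tol,max_iter Convergence control of the variational iteration.
#' @return List of class `istg_bms`: `alpha` (posterior Dirichlet
#'   concentrations), `expected_p` (posterior model probabilities),
#'   `assignment` (subjects x models posterior membership), `xp`, `bor`,
#'   `pxp`.
#' @export
rfx_bms <- function(log_evidence, prior_alpha = 1, n_draws = 1e6,
                    seed = NULL, tol = 1e-8, max_iter = 1000L) {
  L <- as.matrix(log_evidence)
  if (ncol(L) < 2) stop("model selection needs at least two models")
  if (any(!is.finite(L))) stop("log evidences must be finite")
  n <- nrow(L); K <- ncol(L)
  a0 <- rep(prior_alpha, K)
  alpha <- a0 + n / K
  for (it in seq_len(max_iter)) {
    w <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1, max)
    g <- exp(w)
    g <- g / rowSums(g)
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  expected_p <- alpha / sum(alpha)

  # exceedance probability: P(r_k > r_j for all j) under Dirichlet(alpha)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                  n_draws, K)
  xp <- tabulate(max.col(draws, ties.method = "first"), nbins = K) / n_draws

  # Bayes omnibus risk: P(H0: equal frequencies | data) against the RFX
  # alternative, via the two free energies.
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  F1 <- sum(g * L) +
    sum(sweep(g, 2, elog_r, `*`)) -
    sum(g[g > 0] * log(g[g > 0])) +
    (lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * elog_r)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elog_r))
  F0 <- sum(apply(L - log(K), 1, .logsumexp))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- (1 - bor) * xp + bor / K

  names(expected_p) <- names(xp) <- names(pxp) <- names(alpha) <- colnames(L)
  structure(list(alpha = alpha, expected_p = expected_p, assignment = g,
                 xp = xp, bor = bor, pxp = pxp, n_subjects = n,
                 iterations = it),
            class = "istg_bms")
}

#' @export
print.istg_bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  tab <- rbind(`posterior p` = x$expected_p, `exceedance p` = x$xp,
               `protected xp` = x$pxp)
  print(round(tab, 4))
  cat(sprintf("Bayes omnibus risk = %.4g (%d subjects)\n", x$bor, x$n_subjects))
  invisible(x)
}

#' Full group-level model comparison
#'
#' Summed BICs, pairwise bootstrap CIs of summed BIC differences, and
#' random-effects BMS on `-BIC / 2` model evidences.
#'
#' @param fits Data.frame from [fit_cohort()] (columns `subject_id`,
#'   `model`, `bic`), or a subjects x models BIC matrix.
#' @param n_boot Bootstrap iterations per model pair.
#' @param n_draws Monte-Carlo draws for exceedance probabilities.
#' @param seed Optional seed.
#' @return List of class `istg_comparison`: `bic_sum`, `bic_mean`,
#'   `pairwise` (data.frame of intervals), `bms`.
#' @export
compare_models <- function(fits, n_boot = 1e5, n_draws = 1e6, seed = NULL) {
  if (is.data.frame(fits) && all(c("subject_id", "model", "bic") %in% names(fits))) {
    B <- bic_matrix_from_fits(fits)
  } else {
    B <- as.matrix(fits)
  }
  models <- colnames(B)
  pairs <- utils::combn(models, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    ci <- bootstrap_bic_ci(B, p, n_boot = n_boot,
                           seed = derive_seed(seed, i))
    data.frame(model_a = p[1], model_b = p[2],
               diff = ci["observed"], lower = ci["lower"], upper = ci["upper"],
               significant = !(ci["lower"] <= 0 && ci["upper"] >= 0),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  bms <- rfx_bms(-B / 2, n_draws = n_draws,
                 seed = derive_seed(seed, 0L, 1L))
  structure(list(bic_sum = colSums(B), bic_mean = colMeans(B),
                 pairwise = pw, bms = bms, n_subjects = nrow(B)),
            class = "istg_comparison")
}

#' @export
print.istg_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d subjects\n\nSummed BIC:\n", x$n_subjects))
  print(round(x$bic_sum, 1))
  cat("\nPairwise summed BIC differences (bootstrap 95% CI):\n")
  print(transform(x$pairwise, diff = round(diff, 1), lower = round(lower, 1),
                  upper = round(upper, 1)))
  cat("\n")
  print(x$bms)
  invisible(x)
}

#' Reshape a fit table into a subjects x models BIC matrix
#'
#' @param fits Data.frame from [fit_cohort()].
#' @return Numeric matrix, rows = subjects, columns = models.
#' @export
bic_matrix_from_fits <- function(fits) {
  ids <- unique(fits$subject_id)
  models <- unique(fits$model)
  B <- matrix(NA_real_, length(ids), length(models),
              dimnames = list(ids, models))
  B[cbind(match(fits$subject_id, ids), match(fits$model, models))] <- fits$bic
  if (any(is.na(B))) stop("missing subject x model BIC entries")
  B
}
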