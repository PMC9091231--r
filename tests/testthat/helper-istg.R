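# Shared fixtures, all built in code.

# one-row trial table from an outcome string
make_trial <- function(outcomes, r = 0.5, subject_id = "t1", trial = 1L,
                       invested = TRUE, age = NA_real_) {
  data.frame(subject_id = subject_id, age = age, trial = trial, r = r,
             outcomes = outcomes, n_samples = nchar(outcomes),
             invested = invested, stringsAsFactors = FALSE)
}

# trial table enumerating every possible stopping point of one hidden grid
stop_point_trials <- function(grid) {
  size <- length(grid)
  do.call(rbind, lapply(0:size, function(s) {
    make_trial(paste(ifelse(grid[seq_len(s)], "G", "R"), collapse = ""),
               trial = s + 1L)
  }))
}

# default parameter objects used across tests
unc_pars <- function(alpha0 = 1, beta0 = 1, k = 0.1, tau = 0.02) {
  uncertainty_params(alpha0, beta0, k, tau)
}

# direct closed form used in enumeration checks
beta_sd <- function(a, b) sqrt(a * b / ((a + b)^2 * (a + b + 1)))

# all permutations of a vector (tiny n only)
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# brute-force expectimax oracle for the sample-cost planner on a tiny grid:
# plain recursion over (n_pos, n_neg), independent of the DP implementation
expectimax_value <- function(n_pos, n_neg, size, cost, cfg_endow = 6,
                             invest_gain = 12, a0 = 1, b0 = 1) {
  m <- (a0 + n_pos) / (a0 + b0 + n_pos + n_neg)
  q_stop <- max(invest_gain * m, cfg_endow)
  if (n_pos + n_neg == size) return(q_stop)
  q_sample <- -cost +
    m * expectimax_value(n_pos + 1, n_neg, size, cost, cfg_endow, invest_gain) +
    (1 - m) * expectimax_value(n_pos, n_neg + 1, size, cost, cfg_endow, invest_gain)
  max(q_stop, q_sample)
}
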