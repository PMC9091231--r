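# The ISTG environment: task configuration, grid generation, payoffs, and
# the trial-level CSV dialect shared by the simulator and the fitting code.
#
# In the ISTG the participant (investor) may reveal up to 25 tiles of a 5x5
# grid showing a trustee's reciprocation history (green = reciprocated,
# red = defected) before deciding whether to invest 6 tokens. Investing
# multiplies the endowment by 4; a reciprocating trustee returns half of
# the 24 tokens (12), a defecting trustee keeps all of them (0). Not
# investing keeps the endowment (6).

#' Task configuration for the Information Sampling Trust Game
#'
#' @param grid_size Number of tiles per trustee grid (5 x 5 = 25).
#' @param conditions Generative reciprocation probabilities; one grid per
#'   trial is drawn from one condition.
#' @param trials_per_condition Trials per condition (6 x 10 = 60 trials).
#' @param endowment Tokens the investor starts each trial with.
#' @param multiplier Factor applied to an invested endowment.
#' @param split_fraction Fraction of the multiplied amount a reciprocating
#'   trustee returns.
#' @param exact_counts If `TRUE`, each grid contains exactly
#'   `round(grid_size * r)` green tiles in random positions instead of
#'   i.i.d. Bernoulli(r) draws (sensitivity-check variant).
#' @return A list of class `istg_config`.
#' @export
task_config <- function(grid_size = 25L,
                        conditions = seq(0, 1, by = 0.2),
                        trials_per_condition = 10L,
                        endowment = 6,
                        multiplier = 4,
                        split_fraction = 0.5,
                        exact_counts = FALSE) {
  if (any(conditions < 0 | conditions > 1)) {
    stop("all reciprocation probabilities must lie in [0, 1]")
  }
  if (grid_size < 1) stop("'grid_size' must be a positive count")
  structure(list(grid_size = as.integer(grid_size),
                 conditions = as.numeric(conditions),
                 trials_per_condition = as.integer(trials_per_condition),
                 endowment = endowment,
                 multiplier = multiplier,
                 split_fraction = split_fraction,
                 exact_counts = exact_counts),
            class = "istg_config")
}

#' Generate one hidden trustee grid
#'
#' Tile outcomes are i.i.d. Bernoulli(r) draws (`TRUE` = green/trustworthy),
#' or exactly `round(size * r)` greens in random order when
#' `exact_counts = TRUE`. Tile position carries no information, so only the
#' ordered outcome sequence is kept.
#'
#' @param r Reciprocation probability in [0, 1].
#' @param size Number of tiles.
#' @param exact_counts Fixed green count instead of i.i.d. draws.
#' @param seed Optional integer seed for reproducibility.
#' @return Logical vector of length `size`: the hidden outcomes in the
#'   order they would be revealed.
#' @export
generate_grid <- function(r, size = 25L, exact_counts = FALSE, seed = NULL) {
  if (length(r) != 1L || !is.finite(r) || r < 0 || r > 1) {
    stop("'r' must be a single probability in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  if (exact_counts) {
    n_green <- round(size * r)
    sample(c(rep(TRUE, n_green), rep(FALSE, size - n_green)))
  } else {
    stats::runif(size) < r
  }
}

#' Investor payoff
#'
#' @param invested Did the investor invest the endowment?
#' @param reciprocated Did the trustee reciprocate? Ignored when not
#'   invested.
#' @param cfg A [task_config()].
#' @return Investor payoff in tokens: keep the endowment (6) when not
#'   investing; half the multiplied endowment (12) when trust is
#'   reciprocated; nothing (0) when it is betrayed.
#' @export
payoff <- function(invested, reciprocated, cfg = task_config()) {
  ifelse(!invested, cfg$endowment,
         ifelse(reciprocated,
                cfg$endowment * cfg$multiplier * cfg$split_fraction, 0))
}

# ---- trial-level table ------------------------------------------------------

# Canonical trial table columns. `outcomes` encodes the revealed sequence as
# a string of G (green) / R (red), e.g. "GGRGR"; empty when no tile was
# turned. This is also the layout external datasets are mapped to.
.TRIAL_COLS <- c("subject_id", "age", "trial", "r", "outcomes",
                 "n_samples", "invested")

outcomes_to_string <- function(x) paste(ifelse(x, "G", "R"), collapse = "")

string_to_outcomes <- function(s) {
  if (is.na(s) || !nzchar(s)) return(logical(0))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("G", "R"))) stop("outcome strings may only contain 'G' and 'R'")
  ch == "G"
}

#' Validate a trial table
#'
#' Checks the trial-level data.frame produced by the simulator or read from
#' disk: required columns, outcome strings consistent with `n_samples`,
#' sample counts within the grid, probabilities in range.
#'
#' @param trials A data.frame of trials.
#' @param grid_size Maximum number of samples per trial.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_trials <- function(trials, grid_size = 25L) {
  missing_cols <- setdiff(.TRIAL_COLS, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(trials$r < 0 | trials$r > 1)) stop("'r' outside [0, 1]")
  if (any(trials$n_samples < 0 | trials$n_samples > grid_size)) {
    stop("'n_samples' outside [0, ", grid_size, "]")
  }
  lens <- nchar(ifelse(is.na(trials$outcomes), "", trials$outcomes))
  if (any(lens != trials$n_samples)) {
    stop("outcome string lengths do not match 'n_samples'")
  }
  if (!all(grepl("^[GR]*$", trials$outcomes) | is.na(trials$outcomes))) {
    stop("outcome strings may only contain 'G' and 'R'")
  }
  if (!is.logical(trials$invested)) {
    if (all(trials$invested %in% c(0, 1))) {
      trials$invested <- as.logical(trials$invested)
    } else stop("'invested' must be logical (or 0/1)")
  }
  trials
}

#' Write a trial table to CSV
#'
#' @param trials Trial data.frame (see [validate_trials()]).
#' @param path Output file path.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  utils::write.csv(trials[, .TRIAL_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path CSV written by [write_trials()] (or external data mapped to
#'   the same layout).
#' @param grid_size Grid size used for validation.
#' @return Validated trial data.frame.
#' @export
read_trials <- function(path, grid_size = 25L) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(outcomes = "character"))
  trials$outcomes[is.na(trials$outcomes)] <- ""
  validate_trials(trials, grid_size = grid_size)
}
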