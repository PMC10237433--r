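#' The four cue conditions of the orthogonalized go/no-go task
#'
#' The task crosses required action (go / no-go) with outcome valence
#' (win reward / avoid punishment), giving four cue conditions. Cue ids are
#' a fixed bijection onto labels: 1 = go-to-win (reward), 2 = go-to-avoid
#' (punishment), 3 = no-go-to-win (reward), 4 = no-go-to-avoid (punishment).
#'
#' @return A data frame with one row per condition and columns `id`,
#'   `label`, `domain` (`"reward"` or `"punishment"`) and `correct_action`
#'   (`"go"` or `"nogo"`).
#' @examples
#' cue_conditions()
#' @export
cue_conditions <- function() {
  data.frame(
    id = 1:4,
    label = c("go_to_win", "go_to_avoid", "nogo_to_win", "nogo_to_avoid"),
    domain = c("reward", "punishment", "reward", "punishment"),
    correct_action = c("go", "go", "nogo", "nogo"),
    stringsAsFactors = FALSE
  )
}

#' @rdname cue_conditions
#' @param cue integer vector of cue ids in 1..4.
#' @return `cue_domain()` returns `"reward"` or `"punishment"` per cue;
#'   `cue_correct_action()` returns 1 (go) or 0 (no-go) per cue.
#' @export
cue_domain <- function(cue) {
  c("reward", "punishment")[1L + (cue %in% c(2L, 4L))]
}

#' @rdname cue_conditions
#' @export
cue_correct_action <- function(cue) {
  as.integer(cue %in% c(1L, 2L))
}

#' Task design parameters
#'
#' The standard session has 45 trials of each of the four conditions (180
#' trials total) and a 0.7 action-outcome contingency: the optimal response
#' yields the beneficial outcome (reward +1, or neutral 0 under threat of
#' punishment) with probability 0.7, the non-beneficial outcome otherwise;
#' probabilities reverse for the suboptimal response.
#'
#' @param n_trials_per_condition trials per condition (default 45).
#' @param contingency probability of the beneficial outcome given the
#'   optimal response; must lie strictly inside (0, 1) unless `1` or `0` is
#'   wanted for degenerate debugging designs, which are allowed.
#' @return An object of class `task_design`.
#' @export
task_design <- function(n_trials_per_condition = 45, contingency = 0.7) {
  stopifnot(n_trials_per_condition >= 1, contingency >= 0, contingency <= 1)
  structure(
    list(n_trials_per_condition = as.integer(n_trials_per_condition),
         contingency = contingency,
         n_trials = 4L * as.integer(n_trials_per_condition)),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat("Orthogonalized go/no-go task design\n")
  cat("  trials:", x$n_trials, "(", x$n_trials_per_condition,
      "per condition )\n")
  cat("  contingency:", x$contingency, "\n")
  invisible(x)
}

#' Generate a cue schedule
#'
#' Produces a uniformly shuffled cue sequence containing each condition
#' exactly `n_trials_per_condition` times.
#'
#' @param design a [task_design].
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used (so schedules embedded in larger simulations stay reproducible
#'   from one top-level seed).
#' @return Integer vector of cue ids, length `design$n_trials`.
#' @export
make_schedule <- function(design = task_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep(1:4, each = design$n_trials_per_condition))
}

#' Sample feedback for one trial
#'
#' Implements the probabilistic action-outcome contingency. Reward-domain
#' cues yield feedback in \{0, +1\}; punishment-domain cues in \{-1, 0\}.
#' The beneficial outcome (+1, or 0 under punishment) occurs with
#' probability `contingency` when the emitted action is the cue's correct
#' action, and with probability `1 - contingency` otherwise.
#'
#' @param cue cue id (1..4); vectorized.
#' @param action emitted action, 1 = go, 0 = no-go; vectorized.
#' @param design a [task_design].
#' @return Integer feedback in \{-1, 0, +1\}, drawn from the current RNG
#'   stream (seed with `set.seed()` upstream).
#' @export
sample_feedback <- function(cue, action, design = task_design()) {
  stopifnot(all(cue %in% 1:4), all(action %in% 0:1))
  n <- max(length(cue), length(action))
  cue <- rep_len(cue, n); action <- rep_len(action, n)
  correct <- action == cue_correct_action(cue)
  p_beneficial <- ifelse(correct, design$contingency, 1 - design$contingency)
  beneficial <- runif(n) < p_beneficial
  reward <- cue_domain(cue) == "reward"
  out <- integer(n)
  out[reward] <- ifelse(beneficial[reward], 1L, 0L)
  out[!reward] <- ifelse(beneficial[!reward], 0L, -1L)
  out
}
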