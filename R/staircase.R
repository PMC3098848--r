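# Transformed two-up/one-down adaptive staircase on noise-dot count.
#
# "Up" means more noise dots (harder). After two consecutive correct
# responses the level moves up; after any error it moves down. The rule
# converges on the level where P(two consecutive correct) = 1/2, i.e.
# P(correct) = sqrt(1/2) ~ 0.707.

#' Staircase configuration
#'
#' Defaults encode the masked-detection procedure: start at 20 noise dots,
#' steps of 6 dots for the first 12 reversals and 3 dots thereafter, stop at
#' 16 reversals, threshold = mean of the last 6 reversal levels.
#'
#' @param start_level initial noise-dot count.
#' @param big_step,small_step step sizes before/after the switch.
#' @param step_change_after_reversals reversal count at which the step
#'   drops from `big_step` to `small_step`.
#' @param stop_after_reversals reversal count terminating the run.
#' @param threshold_last_k number of final reversals averaged for the
#'   threshold.
#' @param min_level floor for the level (cannot go below 0 noise dots).
#' @param max_trials safety cap on trial count.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(start_level = 20L, big_step = 6L, small_step = 3L,
                             step_change_after_reversals = 12L,
                             stop_after_reversals = 16L,
                             threshold_last_k = 6L,
                             min_level = 0L, max_trials = 400L) {
  stopifnot(start_level >= 0, big_step > 0, small_step > 0,
            step_change_after_reversals > 0, stop_after_reversals > 0,
            threshold_last_k > 0, min_level >= 0, max_trials > 0,
            threshold_last_k <= stop_after_reversals)
  structure(list(start_level = as.integer(start_level),
                 big_step = as.integer(big_step),
                 small_step = as.integer(small_step),
                 step_change_after_reversals = as.integer(step_change_after_reversals),
                 stop_after_reversals = as.integer(stop_after_reversals),
                 threshold_last_k = as.integer(threshold_last_k),
                 min_level = as.integer(min_level),
                 max_trials = as.integer(max_trials)),
            class = "staircase_config")
}

#' Create a fresh staircase state
#'
#' @param cfg a [staircase_config()].
#' @return an object of class `staircase` holding the current level,
#'   consecutive-correct counter, last movement direction, reversal ledger
#'   and trial index.
#' @export
staircase_new <- function(cfg = staircase_config()) {
  stopifnot(inherits(cfg, "staircase_config"))
  structure(list(cfg = cfg, level = cfg$start_level,
                 consecutive_correct = 0L, last_direction = "none",
                 reversal_levels = integer(0), trial_index = 0L,
                 finished = FALSE),
            class = "staircase")
}

#' Update a staircase with one trial's outcome
#'
#' Implements the transformed two-up/one-down rule. A reversal is recorded
#' at the level of the trial on which the movement direction changed (the
#' local extremum). The step size consults the reversal ledger after any
#' reversal on the current trial is recorded, so the size switch takes
#' effect on the movement that completes the 12th reversal. The
#' consecutive-correct counter resets on every level movement.
#'
#' @param state a [staircase_new()] state (not finished).
#' @param correct logical: was the response correct?
#' @return the updated `staircase` state.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase"), is.logical(correct), length(correct) == 1L)
  if (state$finished) stop("staircase already finished")
  cfg <- state$cfg
  state$trial_index <- state$trial_index + 1L

  move <- NULL
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) move <- "up"
  } else {
    state$consecutive_correct <- 0L
    move <- "down"
  }

  if (!is.null(move)) {
    if (state$last_direction != "none" && move != state$last_direction)
      state$reversal_levels <- c(state$reversal_levels, state$level)
    step <- if (length(state$reversal_levels) >= cfg$step_change_after_reversals)
      cfg$small_step else cfg$big_step
    state$level <- if (move == "up") state$level + step
      else max(cfg$min_level, state$level - step)
    state$last_direction <- move
    state$consecutive_correct <- 0L
  }

  if (length(state$reversal_levels) >= cfg$stop_after_reversals ||
      state$trial_index >= cfg$max_trials)
    state$finished <- TRUE
  state
}

#' Threshold estimate from a finished staircase
#'
#' @param state a finished `staircase` with at least `threshold_last_k`
#'   reversals.
#' @return arithmetic mean of the last `threshold_last_k` reversal levels.
#' @export
staircase_threshold <- function(state) {
  stopifnot(inherits(state, "staircase"))
  k <- state$cfg$threshold_last_k
  if (length(state$reversal_levels) < k)
    stop(sprintf("cannot estimate threshold: %d reversals recorded, %d required",
                 length(state$reversal_levels), k))
  mean(utils::tail(state$reversal_levels, k))
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf("<staircase: trial %d, level %d, %d reversals%s>\n",
              x$trial_index, x$level, length(x$reversal_levels),
              if (x$finished) ", finished" else ""))
  invisible(x)
}
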