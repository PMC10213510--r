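#' Initialize a 2-down/1-up adaptive track
#'
#' One of the two interleaved tracks of a block. Early-onset tracks start at
#' a gap deviation of 1.0 (a 100% gap decrease, i.e. no gap) bounded in
#' `[0, 1]`; late-onset tracks start at 1.5 bounded in `[0, 2]`. The step is
#' half the current gap deviation until the track's second reversal and a
#' quarter of it thereafter.
#'
#' @param direction `"early"` or `"late"`.
#' @param level Initial gap deviation; defaults to 1.0 (early) / 1.5 (late).
#' @param bounds Length-2 limits; defaults `[0, 1]` (early) / `[0, 2]` (late).
#' @return An object of class `"track_state"`.
#' @export
track_state <- function(direction = c("early", "late"),
                        level = NULL, bounds = NULL) {
  direction <- match.arg(direction)
  if (is.null(level)) level <- if (direction == "early") 1.0 else 1.5
  if (is.null(bounds)) bounds <- if (direction == "early") c(0, 1) else c(0, 2)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2],
            level >= bounds[1], level <= bounds[2])
  structure(list(direction = direction, level = level,
                 consecutive_correct = 0L, reversals = numeric(0),
                 last_move = "none", lower_bound = bounds[1],
                 upper_bound = bounds[2], step_phase = "coarse"),
            class = "track_state")
}

#' Advance a track by one response
#'
#' Implements the 2-down/1-up rule: two consecutive correct responses lower
#' the gap deviation by one step and reset the counter; any incorrect
#' response raises it by one step. The step is computed from the level
#' before the move — half of it in the coarse phase, a quarter after the
#' second reversal — and the result is clipped to the track bounds. A change
#' in the direction of movement of the level records the pre-move level as a
#' reversal. When the level sits at a bound and the clipped move leaves it
#' unchanged, the value simply repeats: no movement is booked and no
#' spurious reversal can be generated until the level actually changes in
#' the opposite direction.
#'
#' @param state A [track_state()].
#' @param correct Logical: was the response correct?
#' @return The updated `"track_state"`.
#' @export
update_track <- function(state, correct) {
  stopifnot(inherits(state, "track_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  move <- 0L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct == 2L) {
      move <- -1L
      state$consecutive_correct <- 0L
    }
  } else {
    state$consecutive_correct <- 0L
    move <- 1L
  }
  if (move != 0L) {
    pre <- state$level
    step <- pre * (if (state$step_phase == "coarse") 0.5 else 0.25)
    new_level <- min(max(pre + move * step, state$lower_bound),
                     state$upper_bound)
    if (new_level != pre) {
      dir_label <- if (move > 0L) "up" else "down"
      if (state$last_move != "none" && state$last_move != dir_label) {
        state$reversals <- c(state$reversals, pre)
        if (length(state$reversals) == 2L) state$step_phase <- "fine"
      }
      state$last_move <- dir_label
      state$level <- new_level
    }
  }
  state
}

#' Run one 40-trial block of interleaved tracks
#'
#' Presents an equal number of early- and late-onset trials in uniformly
#' shuffled order. Each trial takes its gap deviation from its track's
#' current level; the simulated observer answers correctly with probability
#' `p_correct(profile, rhythm_condition, direction, level)` and the track is
#' updated with the 2-down/1-up rule.
#'
#' @param profile An [observer_profile()].
#' @param rhythm_condition `"unaltered"`, `"low_rate"` or `"high_rate"`.
#' @param n_trials Trials in the block (even, default 40; half per track).
#' @param tracks Optional named list `list(early =, late =)` of initial
#'   [track_state()]s; fresh default tracks if omitted.
#' @return A list of class `"block_result"`: final `tracks`, per-track
#'   `thresholds` (see [estimate_threshold()]), and a per-trial `log`
#'   data.frame with columns `trial`, `direction`, `level`, `p`, `correct`,
#'   `level_after`.
#' @export
run_block <- function(profile, rhythm_condition, n_trials = 40, tracks = NULL) {
  rhythm_condition <- match.arg(rhythm_condition, rhythm_conditions)
  if (is.null(tracks))
    tracks <- list(early = track_state("early"), late = track_state("late"))
  order <- block_trial_order(n_trials)
  log <- data.frame(trial = seq_len(n_trials), direction = order,
                    level = NA_real_, p = NA_real_, correct = NA,
                    level_after = NA_real_)
  for (i in seq_len(n_trials)) {
    dir <- order[i]
    lvl <- tracks[[dir]]$level
    p <- p_correct(profile, rhythm_condition, dir, lvl)
    correct <- stats::runif(1) < p
    tracks[[dir]] <- update_track(tracks[[dir]], correct)
    log$level[i] <- lvl
    log$p[i] <- p
    log$correct[i] <- correct
    log$level_after[i] <- tracks[[dir]]$level
  }
  thresholds <- lapply(tracks, estimate_threshold)
  structure(list(tracks = tracks, thresholds = thresholds, log = log),
            class = "block_result")
}

#' Reversal-based threshold estimate for one track
#'
#' The block threshold is the mean gap deviation of the track's last four
#' reversals. Tracks with fewer than four reversals yield an invalid block
#' (`NA` threshold, `valid = FALSE`); such blocks are excluded from the
#' subject's three-block mean.
#'
#' @param track A [track_state()] after a block, or a numeric vector of
#'   reversal levels.
#' @param n_reversals_used Number of trailing reversals averaged (default 4).
#' @return List with `threshold`, `n_reversals`, `valid`.
#' @export
estimate_threshold <- function(track, n_reversals_used = 4) {
  rev_levels <- if (inherits(track, "track_state")) track$reversals
                else as.numeric(track)
  k <- length(rev_levels)
  if (k < n_reversals_used)
    return(list(threshold = NA_real_, n_reversals = k, valid = FALSE))
  list(threshold = mean(utils::tail(rev_levels, n_reversals_used)),
       n_reversals = k, valid = TRUE)
}

#' Subject threshold for one condition x direction cell
#'
#' Mean of the valid block thresholds across the three blocks of a rhythm
#' condition.
#'
#' @param block_thresholds Numeric vector of per-block thresholds (may
#'   contain `NA` for invalid blocks).
#' @return List with `mean_threshold`, `block_thresholds`, `n_valid`.
#' @export
condition_threshold <- function(block_thresholds) {
  valid <- !is.na(block_thresholds)
  list(mean_threshold = if (any(valid)) mean(block_thresholds[valid]) else NA_real_,
       block_thresholds = block_thresholds,
       n_valid = sum(valid))
}
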