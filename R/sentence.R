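#' Sentence timeline template
#'
#' Abstract timeline of a CRM-style sentence ("Ready Charlie go to white six
#' now"): an early region that can be rhythm-warped, a reference gap of
#' duration T (the "white six" words, silent in comparison intervals), and a
#' final word whose onset the listener judges. Default T values are the
#' durations of the "white six" portion for the two talkers: 1661 ms (male)
#' and 1603 ms (female).
#'
#' @param speaker `"male"` or `"female"`.
#' @param early_ms Duration of the early region ("Ready Charlie go to"), ms.
#' @param gap_ms Reference gap duration T, ms; defaults to the speaker's
#'   standard value.
#' @param final_word_ms Duration of the final word ("now"), ms.
#' @return An object of class `"sentence_template"`.
#' @export
sentence_template <- function(speaker = c("male", "female"),
                              early_ms = 1200,
                              gap_ms = NULL,
                              final_word_ms = 350) {
  speaker <- match.arg(speaker)
  if (is.null(gap_ms)) gap_ms <- if (speaker == "male") 1661 else 1603
  stopifnot(early_ms > 0, gap_ms > 0, final_word_ms > 0)
  structure(list(speaker = speaker, early_ms = early_ms, gap_ms = gap_ms,
                 final_word_ms = final_word_ms),
            class = "sentence_template")
}

#' @export
print.sentence_template <- function(x, ...) {
  cat(sprintf("<sentence_template> %s: early %g ms | gap T %g ms | final %g ms\n",
              x$speaker, x$early_ms, x$gap_ms, x$final_word_ms))
  invisible(x)
}

rhythm_conditions <- c("unaltered", "low_rate", "high_rate")
shift_directions <- c("early", "late")

delta_bound <- function(direction) if (direction == "early") 1 else 2

#' Altered gap duration for a temporal shift
#'
#' Gap duration of the temporally altered comparison: `T * (1 - delta)` for
#' an early final-word onset (shortened gap) or `T * (1 + delta)` for a late
#' onset (lengthened gap), where `delta` is the gap deviation as a
#' proportion of T. The deviation is bounded in `[0, 1]` for early shifts
#' (the gap cannot be negative) and `[0, 2]` for late shifts.
#'
#' @param template A [sentence_template()].
#' @param direction `"early"` or `"late"`.
#' @param delta_frac Gap deviation `delta T / T`, within the direction's bound.
#' @return Altered gap duration in ms.
#' @export
#' @examples
#' altered_gap_ms(sentence_template("male"), "early", 1)  # 0: no gap at all
altered_gap_ms <- function(template, direction, delta_frac) {
  stopifnot(inherits(template, "sentence_template"))
  direction <- match.arg(direction, shift_directions)
  if (delta_frac < 0 || delta_frac > delta_bound(direction))
    stop("delta_frac ", delta_frac, " outside [0, ", delta_bound(direction),
         "] for ", direction, " shifts")
  if (direction == "early") template$gap_ms * (1 - delta_frac)
  else template$gap_ms * (1 + delta_frac)
}

#' Assemble one three-interval trial
#'
#' Draws the randomized components of a trial: which of the two comparison
#' intervals carries the altered gap (uniform), the two inter-stimulus
#' intervals (uniform in 400-800 ms, blocking timing cues across intervals),
#' and the modulator's initial phase (uniform over the eight allowed values).
#' In altered-rhythm conditions the same phase — hence the same warp
#' schedule — applies to the early region of the reference and of both
#' comparisons within the trial.
#'
#' @param template A [sentence_template()].
#' @param rhythm_condition `"unaltered"`, `"low_rate"` (1 modulator cycle) or
#'   `"high_rate"` (3 cycles).
#' @param direction `"early"` or `"late"` final-word onset shift.
#' @param delta_frac Gap deviation of the altered comparison.
#' @param depth Modulation depth for altered conditions (default 0.75).
#' @param frame_ms Warp frame duration, ms.
#' @param isi_range ISI jitter range in ms.
#' @return An object of class `"trial_spec"`: condition labels, `delta_frac`,
#'   `altered_position` (1 or 2), `isi_ms` (length 2), `modulator_phase`,
#'   `schedule` (the shared warp schedule for the early region), `speaker`.
#' @export
make_trial <- function(template, rhythm_condition, direction, delta_frac,
                       depth = 0.75, frame_ms = 50, isi_range = c(400, 800)) {
  stopifnot(inherits(template, "sentence_template"))
  rhythm_condition <- match.arg(rhythm_condition, rhythm_conditions)
  direction <- match.arg(direction, shift_directions)
  if (delta_frac < 0 || delta_frac > delta_bound(direction))
    stop("delta_frac out of range for direction ", direction)
  phase <- sample(modulator_phases(), 1L)
  mod <- switch(rhythm_condition,
                unaltered = modulator(0, 1, 0),
                low_rate  = modulator(depth, 1, phase),
                high_rate = modulator(depth, 3, phase))
  structure(list(
    rhythm_condition = rhythm_condition,
    direction = direction,
    delta_frac = delta_frac,
    altered_position = sample(1:2, 1L),
    isi_ms = stats::runif(2, isi_range[1], isi_range[2]),
    modulator_phase = if (rhythm_condition == "unaltered") 0 else phase,
    schedule = build_frame_schedule(template$early_ms, mod, frame_ms),
    speaker = template$speaker
  ), class = "trial_spec")
}

#' Render a trial as three audio intervals
#'
#' Builds the reference interval (early region, audible gap-word stand-in,
#' final word) and the two comparison intervals (early region, silent gap of
#' correct or altered duration, final word) from a synthetic audio source.
#' The early region of all three intervals is warped with the trial's shared
#' schedule.
#'
#' @param trial A [make_trial()] result.
#' @param template The matching [sentence_template()].
#' @param sample_rate Sampling rate in Hz (>= 8000 for sample-exact gap
#'   arithmetic at the precision asserted by the tests).
#' @param synth Function `(dur_ms, sample_rate) -> samples` producing
#'   word-like audio; defaults to [am_noise_word()].
#' @return List with elements `reference`, `comparison1`, `comparison2`
#'   (numeric sample vectors) and `altered_position`.
#' @export
render_trial_audio <- function(trial, template, sample_rate = 16000,
                               synth = am_noise_word) {
  stopifnot(inherits(trial, "trial_spec"), inherits(template, "sentence_template"))
  if (trial$speaker != template$speaker)
    stop("trial and template speakers differ")
  sr_ms <- sample_rate / 1000
  early_raw <- synth(template$early_ms, sample_rate)
  if (length(early_raw) != round(template$early_ms * sr_ms))
    stop("synth returned ", length(early_raw), " samples for the early region; ",
         "expected ", round(template$early_ms * sr_ms))
  final <- synth(template$final_word_ms, sample_rate)
  if (length(final) != round(template$final_word_ms * sr_ms))
    stop("synth duration mismatch for the final word")
  early <- warp_waveform(early_raw, sample_rate, trial$schedule)

  silence <- function(ms) numeric(round(ms * sr_ms))
  gap_alt <- altered_gap_ms(template, trial$direction, trial$delta_frac)
  correct <- c(early, silence(template$gap_ms), final)
  altered <- c(early, silence(gap_alt), final)
  reference <- c(early, synth(template$gap_ms, sample_rate), final)
  if (trial$altered_position == 1L)
    list(reference = reference, comparison1 = altered, comparison2 = correct,
         altered_position = 1L)
  else
    list(reference = reference, comparison1 = correct, comparison2 = altered,
         altered_position = 2L)
}

#' Balanced trial order for one block
#'
#' A block holds an equal number of early- and late-onset trials (20 + 20 by
#' default) in uniformly shuffled order, preventing identification of the
#' altered interval from total sentence duration statistics.
#'
#' @param n_trials Trials per block (even; default 40).
#' @return Character vector of directions, a uniform shuffle of half
#'   `"early"`, half `"late"`.
#' @export
block_trial_order <- function(n_trials = 40) {
  stopifnot(n_trials %% 2 == 0)
  sample(rep(shift_directions, each = n_trials / 2))
}
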