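#' Sinusoidal duration modulator
#'
#' Parameters of the sinusoidal frame-duration modulator used to alter the
#' rhythm of the early portion of a sentence. The new duration of each 50-ms
#' frame relative to its original duration is `1 + m sin(2 pi f t + phi)`
#' where `m` is the modulation depth, `f` the number of whole modulator
#' cycles across the warped region, `phi` the initial phase, and `t` the
#' frame's normalized position within the region.
#'
#' @param depth Modulation depth `m`, a fraction in `[0, 1]`. 0 leaves every
#'   frame unchanged; 1 compresses frames to 0 ms at the modulator trough and
#'   doubles them at the peak.
#' @param cycles Number of whole modulator cycles across the warped region
#'   (positive integer; 1 = low-rate alteration, 3 = high-rate).
#' @param phase Initial phase `phi` in radians, in `[0, 2*pi)`. The
#'   experiment draws it from the eight values `k*pi/4`, `k = 0..7`
#'   (see [modulator_phases()]).
#' @return An object of class `"modulator"`.
#' @seealso [frame_duration_ratio()], [build_frame_schedule()]
#' @export
#' @examples
#' modulator(depth = 0.75, cycles = 1, phase = pi / 4)
modulator <- function(depth, cycles, phase = 0) {
  stopifnot(is.numeric(depth), length(depth) == 1L, is.finite(depth),
            is.numeric(cycles), length(cycles) == 1L, is.finite(cycles),
            is.numeric(phase), length(phase) == 1L, is.finite(phase))
  if (depth < 0 || depth > 1)
    stop("modulation depth must lie in [0, 1], got ", depth)
  if (cycles < 1 || cycles != round(cycles))
    stop("cycles must be a positive integer, got ", cycles)
  phase <- phase %% (2 * pi)
  structure(list(depth = depth, cycles = as.integer(cycles), phase = phase),
            class = "modulator")
}

#' @export
print.modulator <- function(x, ...) {
  cat(sprintf("<modulator> depth=%.3g cycles=%d phase=%.4g rad\n",
              x$depth, x$cycles, x$phase))
  invisible(x)
}

#' The eight allowed initial phases
#'
#' The initial modulator phase is drawn with equal probability from
#' `0, pi/4, ..., 7*pi/4`.
#'
#' @return Numeric vector of length 8 (radians).
#' @export
modulator_phases <- function() (0:7) * pi / 4

#' Frame duration ratio at a normalized position
#'
#' Evaluates the sinusoidal modulator: the ratio of the new frame duration to
#' the original frame duration at normalized position `t_norm` within the
#' warped region.
#'
#' @param mod A [modulator()].
#' @param t_norm Normalized position(s) in `[0, 1)`; frames are evaluated at
#'   their centers.
#' @return Ratio(s) in `[1 - depth, 1 + depth]`.
#' @export
#' @examples
#' m <- modulator(depth = 1, cycles = 1, phase = 0)
#' # trough of the sinusoid: frame compressed to 0 ms
#' frame_duration_ratio(m, 0.75) * 50
frame_duration_ratio <- function(mod, t_norm) {
  stopifnot(inherits(mod, "modulator"), is.numeric(t_norm))
  if (any(t_norm < 0 | t_norm >= 1))
    stop("t_norm must lie in [0, 1)")
  1 + mod$depth * sin(2 * pi * mod$cycles * t_norm + mod$phase)
}

#' Build a warped frame schedule for a region
#'
#' Splits a region into consecutive frames of `frame_ms` (original duration),
#' evaluates the modulator at each frame center, and applies a uniform
#' residual correction so that the summed new durations equal the original
#' region of warped frames exactly. Any frame driven below zero by the
#' correction is clipped to 0 ms and the deficit redistributed
#' proportionally over the remaining frames.
#'
#' Only `floor(region_ms / frame_ms)` frames are warped; a remainder shorter
#' than one frame is passed through unwarped (reported as `remainder_ms`).
#'
#' @param region_ms Duration of the region to warp, in ms. Must be at least
#'   one frame long.
#' @param mod A [modulator()].
#' @param frame_ms Original frame duration in ms (default 50).
#' @return An object of class `"frame_schedule"` with fields
#'   `original_frame_ms`, `n_frames`, `new_durations_ms`, `remainder_ms`.
#' @export
#' @examples
#' sch <- build_frame_schedule(1000, modulator(0.75, 1, 0))
#' sum(sch$new_durations_ms)  # 1000: total duration is conserved
build_frame_schedule <- function(region_ms, mod, frame_ms = 50) {
  stopifnot(is.numeric(region_ms), length(region_ms) == 1L,
            is.numeric(frame_ms), length(frame_ms) == 1L, frame_ms > 0,
            inherits(mod, "modulator"))
  if (region_ms < frame_ms)
    stop("region (", region_ms, " ms) is shorter than one frame (",
         frame_ms, " ms)")
  n <- floor(region_ms / frame_ms)
  t_centers <- (seq_len(n) - 0.5) / n
  durs <- frame_ms * frame_duration_ratio(mod, t_centers)
  # discrete sampling of the sinusoid need not sum to zero deviation;
  # subtract the mean deviation so the warped total matches n * frame_ms
  durs <- durs - (mean(durs) - frame_ms)
  # clip-and-redistribute if the correction pushed any frame negative
  while (any(durs < 0)) {
    deficit <- -sum(durs[durs < 0])
    durs[durs < 0] <- 0
    pos <- durs > 0
    durs[pos] <- durs[pos] - deficit * durs[pos] / sum(durs[pos])
  }
  structure(list(original_frame_ms = frame_ms,
                 n_frames = as.integer(n),
                 new_durations_ms = durs,
                 remainder_ms = region_ms - n * frame_ms),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d frames x %g ms (+%.3g ms passthrough), total %.6g ms\n",
    x$n_frames, x$original_frame_ms, x$remainder_ms,
    sum(x$new_durations_ms) + x$remainder_ms))
  invisible(x)
}

#' Identity schedule (unaltered rhythm)
#'
#' Convenience constructor for the unaltered condition: every frame keeps its
#' original duration.
#'
#' @inheritParams build_frame_schedule
#' @return A `"frame_schedule"` with all durations equal to `frame_ms`.
#' @export
identity_schedule <- function(region_ms, frame_ms = 50) {
  build_frame_schedule(region_ms, modulator(0, 1, 0), frame_ms)
}
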