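#' Parametric simulated listener
#'
#' A generative observer for the two-interval temporal-shift task, encoding
#' the dynamic-attending interpretation of the paradigm in three parameters:
#' a baseline temporal-expectancy imprecision (`sigma_base`, the SD of the
#' internal estimate of the correct final-word onset, as a fraction of the
#' reference gap T), a multiplicative inflation of that imprecision when the
#' preceding speech rhythm is altered (`rhythm_penalty`, disrupted
#' entrainment weakens the expectancy), and an early/late `asymmetry` (ratio
#' of late-shift to early-shift sigma; above 1 reproduces the heightened
#' sensitivity to unexpectedly early onsets typical of young listeners,
#' 1 gives the direction-indifferent pattern typical of older listeners).
#'
#' Defaults for each group are calibrated so that analytic 70.7%-correct
#' points land near the observed group cell means (young early about 0.30,
#' late about 0.53; unaltered about 0.37 vs altered about 0.45 overall).
#'
#' @param group `"young"` or `"older"`.
#' @param sigma_base Expectancy SD as a fraction of T (> 0).
#' @param rhythm_penalty Multiplicative sigma inflation in altered-rhythm
#'   conditions (>= 1).
#' @param asymmetry Ratio sigma_late / sigma_early (> 0).
#' @param lapse Lapse rate in `[0, 0.1]`: probability of an uninformed
#'   random response regardless of the stimulus.
#' @param battery_scores Optional named list of simulated covariates
#'   (`GAP` percent correct, `SC` tapping-variability slope, `RD` d-prime,
#'   `WM` composite).
#' @param subject_id Optional identifier.
#' @return An object of class `"observer_profile"`.
#' @export
observer_profile <- function(group = c("young", "older"),
                             sigma_base = NULL, rhythm_penalty = 1.22,
                             asymmetry = NULL, lapse = 0.02,
                             battery_scores = NULL, subject_id = NA_character_) {
  group <- match.arg(group)
  if (is.null(sigma_base)) sigma_base <- if (group == "young") 0.34 else 0.49
  if (is.null(asymmetry)) asymmetry <- if (group == "young") 1.75 else 1.0
  stopifnot(sigma_base > 0, rhythm_penalty >= 1, asymmetry > 0,
            lapse >= 0, lapse <= 0.1)
  structure(list(group = group, sigma_base = sigma_base,
                 rhythm_penalty = rhythm_penalty, asymmetry = asymmetry,
                 lapse = lapse, battery_scores = battery_scores,
                 subject_id = subject_id),
            class = "observer_profile")
}

#' @export
print.observer_profile <- function(x, ...) {
  cat(sprintf(
    "<observer_profile> %s%s: sigma=%.3g penalty=%.3g asymmetry=%.3g lapse=%.3g\n",
    x$group, if (is.na(x$subject_id)) "" else paste0(" ", x$subject_id),
    x$sigma_base, x$rhythm_penalty, x$asymmetry, x$lapse))
  invisible(x)
}

observer_sigma <- function(profile, rhythm_condition, direction) {
  profile$sigma_base *
    (if (rhythm_condition == "unaltered") 1 else profile$rhythm_penalty) *
    (if (direction == "late") profile$asymmetry else 1)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfinv <- function(y) stats::qnorm((y + 1) / 2) / sqrt(2)

#' Probability of a correct response
#'
#' Two-interval forced-choice psychometric function of the simulated
#' observer. The internal signal-to-noise of a gap deviation `delta` is
#' `d' = delta / sigma` with `sigma = sigma_base x rhythm_penalty (if
#' altered) x asymmetry (if late)`; the probability correct is the
#' lapse-mixed Gaussian 2AFC function
#' `p = 0.5 + (0.5 - lapse/2) * erf(d'/2)`,
#' i.e. chance at `delta = 0`, monotone increasing, asymptote `1 - lapse/2`.
#'
#' @param profile An [observer_profile()].
#' @param rhythm_condition `"unaltered"`, `"low_rate"` or `"high_rate"`.
#' @param direction `"early"` or `"late"`.
#' @param delta_frac Gap deviation(s) `delta T / T`, >= 0.
#' @return Probability (vectorized over `delta_frac`).
#' @export
p_correct <- function(profile, rhythm_condition, direction, delta_frac) {
  stopifnot(inherits(profile, "observer_profile"), all(delta_frac >= 0))
  rhythm_condition <- match.arg(rhythm_condition, rhythm_conditions)
  direction <- match.arg(direction, shift_directions)
  sigma <- observer_sigma(profile, rhythm_condition, direction)
  dprime <- delta_frac / sigma
  0.5 + (0.5 - profile$lapse / 2) * erf(dprime / 2)
}

#' Analytic target-performance point of an observer
#'
#' Closed-form inverse of [p_correct()]: the gap deviation at which the
#' observer reaches a target proportion correct. The default target,
#' `sqrt(1/2)` (about 0.707), is the convergence point of a 2-down/1-up
#' staircase, so this is the analytic threshold a converged track estimates.
#'
#' @inheritParams p_correct
#' @param p_target Target proportion correct in `(0.5, 1 - lapse/2)`.
#' @return The gap deviation `delta T / T` at which `p_correct` equals
#'   `p_target`.
#' @export
analytic_threshold <- function(profile, rhythm_condition, direction,
                               p_target = sqrt(0.5)) {
  stopifnot(inherits(profile, "observer_profile"))
  q <- (p_target - 0.5) / (0.5 - profile$lapse / 2)
  if (q <= 0 || q >= 1)
    stop("p_target unreachable for lapse ", profile$lapse)
  sigma <- observer_sigma(profile,
                          match.arg(rhythm_condition, rhythm_conditions),
                          match.arg(direction, shift_directions))
  sigma * 2 * erfinv(q)
}

#' Choose sigma_base so a cell's 70.7% point lands at a target
#'
#' Convenience inverse used to place an observer's analytic threshold at a
#' chosen gap deviation (for convergence checks and calibration).
#'
#' @param threshold Desired 70.7%-correct gap deviation for the cell.
#' @param rhythm_condition,direction Cell in which the threshold is placed.
#' @param rhythm_penalty,asymmetry,lapse Remaining observer parameters.
#' @return The `sigma_base` giving that analytic threshold.
#' @export
sigma_for_threshold <- function(threshold, rhythm_condition = "unaltered",
                                direction = "early", rhythm_penalty = 1.22,
                                asymmetry = 1, lapse = 0,
                                p_target = sqrt(0.5)) {
  probe <- observer_profile("young", sigma_base = 1,
                            rhythm_penalty = rhythm_penalty,
                            asymmetry = asymmetry, lapse = lapse)
  threshold / analytic_threshold(probe, rhythm_condition, direction, p_target)
}

#' Cohort specification
#'
#' Sampling plan for a simulated cohort: group sizes (defaults 11 young, 10
#' older, as in the study), the group-default observer profiles, log-normal
#' between-subject spreads for the psychophysical parameters, and the
#' loadings that tie the simulated test-battery covariates to the underlying
#' parameters. RD (rhythm discrimination d-prime) loads on the early/late
#' asymmetry; GAP, S&C and WM load on the baseline imprecision, so that
#' simulated cohorts reproduce the observed dissociation: RD tracks the
#' late-early difference while the other three track overall thresholds.
#'
#' @param n_young,n_older Group sizes (>= 1).
#' @param young,older Group-default [observer_profile()]s.
#' @param sd_log_sigma,sd_log_asym,sd_log_penalty Between-subject SDs on the
#'   log scale (>= 0) for `sigma_base`, `asymmetry`, `rhythm_penalty`.
#' @param battery_loading Named vector of correlation loadings in `[0, 1)`
#'   for `GAP`, `SC`, `RD`, `WM`.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_young = 11, n_older = 10,
                        young = observer_profile("young"),
                        older = observer_profile("older"),
                        sd_log_sigma = 0.35, sd_log_asym = 0.40,
                        sd_log_penalty = 0.10,
                        battery_loading = c(GAP = 0.7, SC = 0.7,
                                            RD = 0.75, WM = 0.8)) {
  stopifnot(n_young >= 1, n_older >= 1,
            inherits(young, "observer_profile"),
            inherits(older, "observer_profile"))
  sds <- c(sd_log_sigma, sd_log_asym, sd_log_penalty)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("between-subject SDs must be finite and non-negative")
  if (!all(c("GAP", "SC", "RD", "WM") %in% names(battery_loading)))
    stop("battery_loading must name GAP, SC, RD, WM")
  if (any(battery_loading < 0 | battery_loading >= 1))
    stop("battery loadings must lie in [0, 1)")
  structure(list(n_young = n_young, n_older = n_older,
                 young = young, older = older,
                 sd_log_sigma = sd_log_sigma, sd_log_asym = sd_log_asym,
                 sd_log_penalty = sd_log_penalty,
                 battery_loading = battery_loading),
            class = "cohort_spec")
}

# natural-unit scales of the simulated battery scores
battery_scales <- list(
  GAP = list(center = 75, scale = 8),    # percent correct
  SC  = list(center = 1.0, scale = 0.25),# tapping-variability slope
  RD  = list(center = 1.5, scale = 0.6), # d-prime
  WM  = list(center = 0.5, scale = 0.15) # working-memory composite
)

#' Draw a simulated cohort
#'
#' Samples `n_young + n_older` observer profiles around the group defaults
#' with log-normal between-subject variation, and attaches simulated battery
#' covariates generated as `loading x z + sqrt(1 - loading^2) x noise` in
#' standard units (z is the standardized log-parameter the score loads on),
#' rescaled to natural units.
#'
#' @param spec A [cohort_spec()].
#' @return List of [observer_profile()]s with `battery_scores` filled in.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  # mean-centered log-normal: exp(sd*z - sd^2/2) has expectation 1, so the
  # group mean of each parameter equals its default
  lnorm1 <- function(sd, z) exp(sd * z - sd^2 / 2)
  draw_group <- function(base, n, prefix) {
    lapply(seq_len(n), function(i) {
      z_sigma <- stats::rnorm(1)
      z_asym <- stats::rnorm(1)
      z_pen <- stats::rnorm(1)
      load <- spec$battery_loading
      score <- function(nm, z) {
        s <- battery_scales[[nm]]
        s$center + s$scale *
          (load[[nm]] * z + sqrt(1 - load[[nm]]^2) * stats::rnorm(1))
      }
      observer_profile(
        group = base$group,
        sigma_base = base$sigma_base * lnorm1(spec$sd_log_sigma, z_sigma),
        rhythm_penalty = max(1, base$rhythm_penalty *
                                  lnorm1(spec$sd_log_penalty, z_pen)),
        asymmetry = base$asymmetry * lnorm1(spec$sd_log_asym, z_asym),
        lapse = base$lapse,
        battery_scores = list(GAP = score("GAP", z_sigma),
                              SC = score("SC", z_sigma),
                              RD = score("RD", z_asym),
                              WM = score("WM", z_sigma)),
        subject_id = sprintf("%s%02d", prefix, i))
    })
  }
  c(draw_group(spec$young, spec$n_young, "Y"),
    draw_group(spec$older, spec$n_older, "O"))
}
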