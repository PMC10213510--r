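#' Experiment configuration
#'
#' All constants of the stimulus and procedure with their standard defaults:
#' 50-ms warp frames, 75% modulation depth, 1 (low-rate) or 3 (high-rate)
#' modulator cycles, eight initial phases `k*pi/4`, ISI jitter 400-800 ms,
#' reference gaps of 1661 ms (male talker) and 1603 ms (female), three
#' 40-trial blocks per rhythm condition, initial gap deviations 1.0 (early)
#' and 1.5 (late) with bounds `[0, 1]` and `[0, 2]`, and thresholds from the
#' last four reversals. Every field is validated against its admissible
#' range on construction and on load.
#'
#' @param ... Named overrides of the default fields.
#' @return A validated list of class `"experiment_config"`.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    frame_ms = 50,
    depth = 0.75,
    cycles = list(low_rate = 1L, high_rate = 3L),
    phases = modulator_phases(),
    isi_range = c(400, 800),
    gap_ms = list(male = 1661, female = 1603),
    early_ms = list(male = 1200, female = 1200),
    final_word_ms = 350,
    n_blocks = 3L,
    n_trials_per_block = 40L,
    initial_level = list(early = 1.0, late = 1.5),
    bounds = list(early = c(0, 1), late = c(0, 2)),
    n_reversals_used = 4L,
    seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stop("config field '", field, "': ", msg)
  chk(cfg$frame_ms > 0, "frame_ms", "must be positive")
  chk(cfg$depth >= 0 && cfg$depth <= 1, "depth", "must lie in [0, 1]")
  chk(all(unlist(cfg$cycles) >= 1), "cycles", "must be >= 1")
  chk(all(cfg$phases >= 0 & cfg$phases < 2 * pi), "phases",
      "must lie in [0, 2*pi)")
  chk(length(cfg$isi_range) == 2 && cfg$isi_range[1] <= cfg$isi_range[2] &&
        cfg$isi_range[1] >= 0, "isi_range", "must be a non-negative range")
  chk(all(unlist(cfg$gap_ms) > 0), "gap_ms", "must be positive")
  chk(all(unlist(cfg$early_ms) >= cfg$frame_ms), "early_ms",
      "must be at least one frame")
  chk(cfg$final_word_ms > 0, "final_word_ms", "must be positive")
  chk(cfg$n_blocks >= 1, "n_blocks", "must be >= 1")
  chk(cfg$n_trials_per_block >= 2 && cfg$n_trials_per_block %% 2 == 0,
      "n_trials_per_block", "must be even and >= 2")
  for (d in c("early", "late")) {
    b <- cfg$bounds[[d]]
    chk(length(b) == 2 && b[1] < b[2], "bounds", "must be increasing pairs")
    lv <- cfg$initial_level[[d]]
    chk(lv >= b[1] && lv <= b[2], "initial_level", "must lie within bounds")
  }
  chk(cfg$n_reversals_used >= 1, "n_reversals_used", "must be >= 1")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed",
      "must be an integer")
  structure(cfg, class = "experiment_config")
}

#' Save / load a configuration as YAML
#'
#' Configurations round-trip exactly: `load_config(save_config(cfg, path))`
#' reproduces `cfg`, and loading re-runs the range validation.
#'
#' @param cfg An [experiment_config()].
#' @param path YAML file path.
#' @return `save_config()` the path, invisibly; `load_config()` the config.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$cycles <- lapply(cfg$cycles, as.integer)
  for (f in c("n_blocks", "n_trials_per_block", "n_reversals_used", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  validate_config(cfg)
}

#' Derive a child seed from a master seed
#'
#' Deterministic 31-bit hash of the master seed and a string key, so that
#' per-subject random streams are reproducible regardless of execution
#' order.
#'
#' @param master Integer master seed.
#' @param key Character key (e.g. a subject id).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  h <- as.numeric(master) %% 2147483647
  for (c in utf8ToInt(as.character(key)))
    h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Run one simulated subject through the full procedure
#'
#' The three rhythm conditions are visited in random order; each comprises
#' `n_blocks` blocks of `n_trials_per_block` trials with fresh interleaved
#' tracks per block. Cell thresholds are the means of valid block
#' thresholds (last-`n_reversals_used` reversals).
#'
#' @param profile An [observer_profile()].
#' @param config An [experiment_config()].
#' @return A list of class `"subject_result"`: `subject_id`, `group`,
#'   `thresholds` (named 6-vector), `block_thresholds` (6 x n_blocks
#'   matrix), `late_early`, `rhythm_diff`, `battery_scores`, `condition_order`,
#'   and the per-trial `log` (data.frame across all blocks).
#' @export
run_subject <- function(profile, config = experiment_config()) {
  stopifnot(inherits(profile, "observer_profile"),
            inherits(config, "experiment_config"))
  cond_order <- sample(rhythm_conditions)
  cells <- cell_names()
  block_thr <- matrix(NA_real_, nrow = length(cells), ncol = config$n_blocks,
                      dimnames = list(cells, NULL))
  logs <- list()
  for (cond in cond_order) {
    for (b in seq_len(config$n_blocks)) {
      tracks <- list(
        early = track_state("early", config$initial_level$early,
                            config$bounds$early),
        late = track_state("late", config$initial_level$late,
                           config$bounds$late))
      blk <- run_block(profile, cond, config$n_trials_per_block, tracks)
      for (d in shift_directions) {
        est <- estimate_threshold(blk$tracks[[d]], config$n_reversals_used)
        block_thr[paste(cond, d, sep = "_"), b] <- est$threshold
      }
      blk$log$block <- b
      blk$log$rhythm_condition <- cond
      logs[[length(logs) + 1L]] <- blk$log
    }
  }
  thresholds <- apply(block_thr, 1, function(v) condition_threshold(v)$mean_threshold)
  # a cell can be NA when all of its blocks had < 4 reversals; difference
  # scores are then undefined and the subject is dropped by analyze_cohort
  ds <- if (anyNA(thresholds)) list(late_early = NA_real_, rhythm_diff = NA_real_)
        else difference_scores(thresholds)
  structure(list(subject_id = profile$subject_id, group = profile$group,
                 thresholds = thresholds, block_thresholds = block_thr,
                 late_early = ds$late_early, rhythm_diff = ds$rhythm_diff,
                 battery_scores = profile$battery_scores,
                 condition_order = cond_order,
                 log = do.call(rbind, logs)),
            class = "subject_result")
}

#' Tabulate a simulated cohort's results
#'
#' One row per subject: id, group, the six cell thresholds, the overall mean
#' threshold, both difference scores, and the battery covariates.
#'
#' @param subject_results List of [run_subject()] results.
#' @return A data.frame.
#' @export
cohort_results_table <- function(subject_results) {
  rows <- lapply(subject_results, function(s) {
    bat <- s$battery_scores
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(s$thresholds)),
          data.frame(mean_threshold = mean(s$thresholds),
                     late_early = s$late_early, rhythm_diff = s$rhythm_diff,
                     GAP = if (is.null(bat)) NA_real_ else bat$GAP,
                     SC = if (is.null(bat)) NA_real_ else bat$SC,
                     RD = if (is.null(bat)) NA_real_ else bat$RD,
                     WM = if (is.null(bat)) NA_real_ else bat$WM))
  })
  do.call(rbind, rows)
}

#' Group-level analysis of a cohort results table
#'
#' Reproduces the analysis stage: the 2 x 3 x 2 split-plot ANOVA with
#' Greenhouse-Geisser correction, post-hoc paired t tests (rhythm condition
#' contrasts on all subjects; late vs early within each group) with Cohen's
#' d, and the battery correlation table for the older group.
#'
#' Subjects with any missing cell (all blocks invalid in some condition) are
#' excluded listwise; the number dropped is reported as `n_excluded`.
#'
#' @param results A [cohort_results_table()] data.frame.
#' @return List with `anova`, `posthoc` (data.frame), `correlations`
#'   (older-group [battery_correlations()] table), `group_means`,
#'   `n_excluded`.
#' @export
analyze_cohort <- function(results) {
  cells <- cell_names()
  complete <- stats::complete.cases(results[, cells])
  n_excluded <- sum(!complete)
  results <- results[complete, , drop = FALSE]
  Y <- as.matrix(results[, cells])
  anova <- split_plot_anova(Y, results$group)

  cond_mean <- function(cond)
    rowMeans(Y[, paste(cond, shift_directions, sep = "_"), drop = FALSE])
  dir_mean <- function(d, rows = TRUE)
    rowMeans(Y[rows, paste(rhythm_conditions, d, sep = "_"), drop = FALSE])
  ph <- list(
    unaltered_vs_low = paired_t_and_d(cond_mean("unaltered"), cond_mean("low_rate")),
    unaltered_vs_high = paired_t_and_d(cond_mean("unaltered"), cond_mean("high_rate")),
    low_vs_high = paired_t_and_d(cond_mean("low_rate"), cond_mean("high_rate")))
  for (g in unique(results$group)) {
    rows <- results$group == g
    if (sum(rows) >= 3)
      ph[[paste0(g, "_early_vs_late")]] <-
        paired_t_and_d(dir_mean("early", rows), dir_mean("late", rows))
  }
  posthoc <- do.call(rbind, lapply(names(ph), function(nm)
    data.frame(contrast = nm, t = ph[[nm]]$t, df = ph[[nm]]$df,
               p = ph[[nm]]$p, cohens_d = ph[[nm]]$cohens_d)))

  older <- results[results$group == "older", ]
  correlations <- if (nrow(older) >= 3 && !anyNA(older$GAP))
    battery_correlations(older) else NULL

  group_means <- do.call(rbind, lapply(split(results, results$group),
    function(d) colMeans(d[, c(cells, "mean_threshold", "late_early",
                               "rhythm_diff")])))
  list(anova = anova, posthoc = posthoc, correlations = correlations,
       group_means = group_means, n_excluded = n_excluded)
}

#' Run the complete simulated experiment
#'
#' Generates a cohort from the spec, runs every simulated subject through
#' the adaptive procedure (per-subject random streams derived from the
#' master seed, so results do not depend on execution order), and performs
#' the group analysis. If `out_dir` is given, writes `thresholds.csv`,
#' `anova.csv`, `posthoc.csv`, `correlations.csv` and a `manifest.json`
#' recording the seed, config and file inventory.
#'
#' @param config An [experiment_config()]; `config$seed` is the master seed.
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory.
#' @return List with `results` (per-subject table), `analysis`, `subjects`
#'   (full per-subject objects), `config`, and `manifest`.
#' @export
run_full_pipeline <- function(config = experiment_config(),
                              spec = cohort_spec(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"), inherits(spec, "cohort_spec"))
  set.seed(derive_seed(config$seed, "cohort"))
  cohort <- sample_cohort(spec)
  subjects <- lapply(cohort, function(pr) {
    set.seed(derive_seed(config$seed, paste0("subject:", pr$subject_id)))
    run_subject(pr, config)
  })
  results <- cohort_results_table(subjects)
  analysis <- analyze_cohort(results)

  manifest <- list(seed = config$seed,
                   n_subjects = length(subjects),
                   config = unclass(config),
                   files = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(obj, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(obj, p, row.names = FALSE)
      name
    }
    files <- c(w(results, "thresholds.csv"),
               w(as.data.frame(analysis$anova), "anova.csv"),
               w(analysis$posthoc, "posthoc.csv"))
    if (!is.null(analysis$correlations))
      files <- c(files, w(analysis$correlations, "correlations.csv"))
    manifest$files <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, analysis = analysis, subjects = subjects,
       config = config, manifest = manifest)
}
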