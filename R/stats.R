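#' Cell labels of the 3 rhythm x 2 direction design
#'
#' @return Character vector of the six cell names, rhythm varying slowest:
#'   `"unaltered_early"`, `"unaltered_late"`, `"low_rate_early"`, ...
#' @export
cell_names <- function() {
  as.vector(t(outer(rhythm_conditions, shift_directions, paste, sep = "_")))
}

#' Late-early and rhythm difference scores
#'
#' Per-subject summaries of the 6-cell threshold profile:
#' the late-early difference score is the mean of the three late-onset
#' thresholds minus the mean of the three early-onset thresholds (positive =
#' better detection of early onsets); the rhythm difference score is the
#' mean of the four altered-rhythm thresholds minus the mean of the two
#' unaltered thresholds (positive = cost of rhythm alteration).
#'
#' @param thresholds Named numeric vector of the six cell thresholds (names
#'   as in [cell_names()]).
#' @return List with `late_early` and `rhythm_diff`.
#' @export
difference_scores <- function(thresholds) {
  need <- cell_names()
  if (!all(need %in% names(thresholds)) || anyNA(thresholds[need]))
    stop("all six rhythm x direction cells are required")
  x <- thresholds[need]
  late <- grepl("_late$", need)
  unalt <- grepl("^unaltered_", need)
  list(late_early = mean(x[late]) - mean(x[!late]),
       rhythm_diff = mean(x[!unalt]) - mean(x[unalt]))
}

#' Paired t test with Cohen's d
#'
#' Two-sided paired t test on `x - y`, with the paired-samples effect size
#' `d = mean(x - y) / sd(x - y)`. Zero variance of the differences is
#' flagged degenerate rather than reported as an infinite t.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 3`.
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean_diff`, `degenerate`.
#' @export
paired_t_and_d <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, !anyNA(x), !anyNA(y))
  d <- x - y
  if (stats::sd(d) == 0) {
    # identical vectors: a well-defined null result; any other constant
    # difference has an undefined (infinite) t and is flagged degenerate
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1, cohens_d = 0,
                  mean_diff = 0, degenerate = TRUE))
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                cohens_d = NA_real_, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(d) / stats::sd(d),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Pearson correlation with two-sided p
#'
#' Product-moment correlation; p from the t transform with `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List with `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input to pearson_r")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

# orthonormal contrast matrix ((k-1) x k) for a k-level factor
orthonormal_contrasts <- function(k) {
  C <- t(stats::contr.helmert(k))
  C / sqrt(rowSums(C^2))
}

# pooled within-group covariance of a subjects x cells matrix
pooled_cov <- function(Y, group) {
  group <- as.factor(group)
  pieces <- lapply(levels(group), function(g) {
    Yg <- Y[group == g, , drop = FALSE]
    scale(Yg, center = TRUE, scale = FALSE)
  })
  S <- crossprod(do.call(rbind, pieces))
  S / (nrow(Y) - nlevels(group))
}

# Greenhouse-Geisser epsilon for contrast variables Y %*% t(C)
gg_epsilon <- function(Y, group, C) {
  Sc <- C %*% pooled_cov(Y, group) %*% t(C)
  k1 <- nrow(C)
  sum(diag(Sc))^2 / (k1 * sum(Sc * Sc))
}

#' Split-plot (mixed-measures) ANOVA with Greenhouse-Geisser correction
#'
#' 2 (group, between subjects) x 3 (rhythm) x 2 (direction) analysis of
#' variance on per-subject cell thresholds. Sums of squares, df and F come
#' from the classical univariate decomposition with separate error strata
#' per within-subject factor (via [stats::aov()] with an `Error()` term).
#' Greenhouse-Geisser epsilon is estimated from the pooled within-group
#' covariance of the orthonormalized contrast variables and applied to every
#' within-subject effect with more than one numerator df (the rhythm main
#' effect and the interactions involving rhythm); 1-df effects are
#' uncorrected (epsilon 1). Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within each effect's stratum.
#'
#' @param thresholds Numeric matrix or data.frame, one row per subject, six
#'   columns named as in [cell_names()]. No missing cells are allowed: the
#'   decomposition requires a balanced within-subject design.
#' @param group Factor or character vector of group labels, one per subject,
#'   at least 2 subjects per group.
#' @return An object of class `"anova_result"`: a data.frame with one row
#'   per effect and columns `effect`, `ss`, `df`, `ss_err`, `df_err`, `F`,
#'   `p`, `epsilon`, `df_gg`, `df_err_gg`, `p_gg`, `partial_eta_sq`, plus
#'   attribute `ss_total`.
#' @export
split_plot_anova <- function(thresholds, group) {
  Y <- as.matrix(thresholds)
  if (!all(cell_names() %in% colnames(Y)))
    stop("thresholds must have the six columns ", paste(cell_names(), collapse = ", "))
  Y <- Y[, cell_names(), drop = FALSE]
  if (anyNA(Y)) stop("unbalanced design: missing cells are not supported")
  n <- nrow(Y)
  group <- as.factor(group)
  if (length(group) != n) stop("one group label per subject is required")
  if (any(table(group) < 2)) stop("at least 2 subjects per group are required")

  long <- data.frame(
    subject = factor(rep(seq_len(n), times = 6)),
    group = rep(group, times = 6),
    rhythm = factor(rep(rep(rhythm_conditions, each = 2), each = n),
                    levels = rhythm_conditions),
    direction = factor(rep(rep(shift_directions, times = 3), each = n),
                       levels = shift_directions),
    y = as.vector(Y))
  fit <- stats::aov(
    y ~ group * rhythm * direction + Error(subject / (rhythm * direction)),
    data = long)
  sm <- summary(fit)

  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    err <- terms == "Residuals"
    ss_err <- tab$`Sum Sq`[err]
    df_err <- tab$Df[err]
    for (j in which(!err)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " x ", gsub("group", "group",  terms[j])),
        ss = tab$`Sum Sq`[j], df = tab$Df[j],
        ss_err = ss_err, df_err = df_err,
        F = tab$`F value`[j], p = tab$`Pr(>F)`[j],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)

  # GG epsilon: rhythm stratum uses direction-averaged cells; the
  # rhythm x direction stratum uses the interaction contrasts of all 6 cells
  C3 <- orthonormal_contrasts(3)
  C2 <- orthonormal_contrasts(2)
  Y_rhythm <- cbind((Y[, 1] + Y[, 2]) / 2, (Y[, 3] + Y[, 4]) / 2,
                    (Y[, 5] + Y[, 6]) / 2)
  eps_rhythm <- gg_epsilon(Y_rhythm, group, C3)
  eps_rd <- gg_epsilon(Y, group, kronecker(C3, C2))
  res$epsilon <- 1
  res$epsilon[res$effect %in% c("rhythm", "group x rhythm")] <- eps_rhythm
  res$epsilon[res$effect %in% c("rhythm x direction",
                                "group x rhythm x direction")] <- eps_rd
  res$df_gg <- res$df * res$epsilon
  res$df_err_gg <- res$df_err * res$epsilon
  res$p_gg <- ifelse(is.na(res$F), NA_real_,
                     stats::pf(res$F, res$df_gg, res$df_err_gg,
                               lower.tail = FALSE))
  res$partial_eta_sq <- res$ss / (res$ss + res$ss_err)
  attr(res, "ss_total") <- sum(res$ss) +
    sum(vapply(sm, function(s) {
      tab <- s[[1]]
      tab$`Sum Sq`[trimws(rownames(tab)) == "Residuals"]
    }, numeric(1)))
  class(res) <- c("anova_result", "data.frame")
  res
}

#' @export
print.anova_result <- function(x, digits = 4, ...) {
  cat("Split-plot ANOVA (Greenhouse-Geisser corrected where epsilon < 1)\n")
  print.data.frame(
    cbind(x[, c("effect", "ss", "df")],
          round(x[, c("F", "epsilon", "df_gg", "df_err_gg", "p_gg",
                      "partial_eta_sq")], digits)),
    row.names = FALSE)
  invisible(x)
}

#' Correlations of battery covariates with threshold summaries
#'
#' Builds the correlation table relating the simulated battery scores (GAP,
#' S&C, RD, WM) to three threshold summaries per subject: the overall mean
#' threshold, the late-early difference score and the rhythm difference
#' score.
#'
#' @param results Data frame from [cohort_results_table()] (one row per
#'   subject with cell thresholds, difference scores and battery columns).
#' @return Data frame with one row per battery measure and columns
#'   `measure`, then `r` and `p` for each of the three summaries.
#' @export
battery_correlations <- function(results) {
  meas <- c("GAP", "SC", "RD", "WM")
  stopifnot(all(meas %in% names(results)))
  summaries <- list(mean_threshold = results$mean_threshold,
                    late_early = results$late_early,
                    rhythm_diff = results$rhythm_diff)
  out <- data.frame(measure = meas)
  for (s in names(summaries)) {
    rs <- ps <- numeric(length(meas))
    for (i in seq_along(meas)) {
      ct <- pearson_r(results[[meas[i]]], summaries[[s]])
      rs[i] <- ct$r; ps[i] <- ct$p
    }
    out[[paste0("r_", s)]] <- rs
    out[[paste0("p_", s)]] <- ps
  }
  out
}
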