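# Independent oracles coded directly from the definitions, kept free of the
# package's implementation paths.

# direct evaluation of the sinusoidal schedule at frame centers plus uniform
# mean-residual correction and clip/redistribute
oracle_schedule <- function(region_ms, frame_ms, depth, cycles, phase) {
  n <- floor(region_ms / frame_ms)
  tc <- ((seq_len(n) - 1) + 0.5) / n
  d <- frame_ms * (1 + depth * sin(2 * pi * cycles * tc + phase))
  d <- d - (sum(d) - n * frame_ms) / n
  while (any(d < 0)) {
    deficit <- -sum(d[d < 0])
    d[d < 0] <- 0
    d[d > 0] <- d[d > 0] - deficit * d[d > 0] / sum(d[d > 0])
  }
  d
}

# replay of the 2-down/1-up rule for a fixed response sequence
oracle_replay <- function(level0, bounds, responses) {
  level <- level0
  streak <- 0
  halves <- TRUE           # coarse phase: step is half the level
  prev_dir <- NA
  revs <- numeric(0)
  traj <- numeric(0)
  for (ok in responses) {
    traj <- c(traj, level)
    delta <- 0
    if (ok) {
      streak <- streak + 1
      if (streak == 2) { delta <- -1; streak <- 0 }
    } else {
      streak <- 0
      delta <- 1
    }
    if (delta != 0) {
      step <- level * if (halves) 0.5 else 0.25
      nxt <- level + delta * step
      nxt <- max(bounds[1], min(bounds[2], nxt))
      if (nxt != level) {
        if (!is.na(prev_dir) && prev_dir != delta) {
          revs <- c(revs, level)
          if (length(revs) == 2) halves <- FALSE
        }
        prev_dir <- delta
        level <- nxt
      }
    }
  }
  list(levels = traj, final = level, reversals = revs)
}

# paired t, p and Cohen's d from the textbook formulas
oracle_paired_t <- function(x, y) {
  dd <- x - y
  n <- length(dd)
  tval <- mean(dd) / (sd(dd) / sqrt(n))
  list(t = tval, df = n - 1,
       p = 2 * pt(-abs(tval), n - 1),
       cohens_d = mean(dd) / sd(dd))
}

# product-moment correlation and its t-transform p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), n - 2))
}

# split-plot sums of squares from cell/subject means (balanced within-subject
# design; groups may differ in size). Returns SS per effect, per-stratum
# error SS, and the total SS.
oracle_split_plot_ss <- function(Y, group) {
  group <- as.factor(group)
  n <- nrow(Y)
  k <- 3; m <- 2
  R <- cbind((Y[, 1] + Y[, 2]) / 2, (Y[, 3] + Y[, 4]) / 2, (Y[, 5] + Y[, 6]) / 2)
  D <- cbind(rowMeans(Y[, c(1, 3, 5)]), rowMeans(Y[, c(2, 4, 6)]))
  s <- rowMeans(Y)
  grand <- mean(Y)
  ng <- tabulate(group)
  gmean <- tapply(s, group, mean)

  ss_group <- k * m * sum(ng * (gmean - grand)^2)
  ss_sub_err <- k * m * sum((s - gmean[group])^2)

  rbar <- colMeans(R)
  rbar_g <- apply(R, 2, function(col) tapply(col, group, mean))
  ss_rhythm <- m * n * sum((rbar - grand)^2)
  # interaction deviations per group x rhythm cell
  dev_gr <- sweep(sweep(rbar_g, 1, gmean, "-"), 2, rbar, "-") + grand
  ss_g_rhythm <- m * sum(ng * dev_gr^2)
  ss_rhythm_total <- m * sum((R - s)^2)
  ss_rhythm_err <- ss_rhythm_total - ss_rhythm - ss_g_rhythm

  dbar <- colMeans(D)
  dbar_g <- apply(D, 2, function(col) tapply(col, group, mean))
  ss_dir <- k * n * sum((dbar - grand)^2)
  dev_gd <- sweep(sweep(dbar_g, 1, gmean, "-"), 2, dbar, "-") + grand
  ss_g_dir <- k * sum(ng * dev_gd^2)
  ss_dir_total <- k * sum((D - s)^2)
  ss_dir_err <- ss_dir_total - ss_dir - ss_g_dir

  # per-subject interaction residuals w[i, j, l]
  W <- Y
  for (j in 1:k) for (l in 1:m)
    W[, (j - 1) * m + l] <- Y[, (j - 1) * m + l] - R[, j] - D[, l] + s
  wbar <- colMeans(W)
  wbar_g <- apply(W, 2, function(col) tapply(col, group, mean))
  ss_rd <- n * sum(wbar^2)
  dev_grd <- sweep(wbar_g, 2, wbar, "-")
  ss_g_rd <- sum(ng * dev_grd^2)
  ss_rd_total <- sum(W^2)
  ss_rd_err <- ss_rd_total - ss_rd - ss_g_rd

  list(group = ss_group, sub_err = ss_sub_err,
       rhythm = ss_rhythm, g_rhythm = ss_g_rhythm, rhythm_err = ss_rhythm_err,
       direction = ss_dir, g_dir = ss_g_dir, dir_err = ss_dir_err,
       rd = ss_rd, g_rd = ss_g_rd, rd_err = ss_rd_err,
       total = sum((Y - grand)^2))
}

# synthetic cell-threshold matrix with named columns
make_cells <- function(n, fill = 0.4) {
  Y <- matrix(fill, n, 6)
  colnames(Y) <- cell_names()
  Y
}
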