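test_that("difference scores are exact arithmetic on the six cells", {
  flat <- setNames(rep(0.4, 6), cell_names())
  expect_equal(difference_scores(flat), list(late_early = 0, rhythm_diff = 0))

  thr <- setNames(c(0.30, 0.53, 0.30, 0.53, 0.30, 0.53), cell_names())
  expect_equal(difference_scores(thr)$late_early, 0.23)

  thr2 <- setNames(c(0.37, 0.37, 0.45, 0.45, 0.45, 0.45), cell_names())
  expect_equal(difference_scores(thr2)$rhythm_diff, 0.08)

  expect_error(difference_scores(thr[-1]), "six")
  thr[2] <- NA
  expect_error(difference_scores(thr), "six")
})

test_that("paired t and Cohen's d match the definition oracle", {
  set.seed(14)
  x <- rnorm(11, 0.4, 0.2)
  y <- rnorm(11, 0.5, 0.2)
  got <- paired_t_and_d(x, y)
  orc <- oracle_paired_t(x, y)
  expect_equal(got$t, orc$t, tolerance = 1e-12)
  expect_equal(got$p, orc$p, tolerance = 1e-12)
  expect_equal(got$cohens_d, orc$cohens_d, tolerance = 1e-12)
  expect_equal(got$df, 10)
})

test_that("degenerate paired inputs are flagged, identical ones give zero", {
  same <- paired_t_and_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  expect_true(same$degenerate)
  const <- paired_t_and_d(c(1, 2, 3), c(2, 3, 4))
  expect_true(const$degenerate)
  expect_true(is.na(const$t))
})

test_that("pearson r matches the covariance oracle and handles sign", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(15)
  a <- rnorm(9); b <- 0.4 * a + rnorm(9)
  got <- pearson_r(a, b)
  orc <- oracle_pearson(a, b)
  expect_equal(got$r, orc$r, tolerance = 1e-12)
  expect_equal(got$p, orc$p, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "variance")
})

test_that("split-plot SS decomposition matches the means-based oracle", {
  set.seed(16)
  Y <- make_cells(9) + matrix(rnorm(54, sd = 0.15), 9, 6)
  group <- rep(c("young", "older"), c(5, 4))
  res <- split_plot_anova(Y, group)
  orc <- oracle_split_plot_ss(Y, group)
  get_ss <- function(eff) res$ss[res$effect == eff]
  expect_equal(get_ss("group"), orc$group, tolerance = 1e-9)
  expect_equal(get_ss("rhythm"), orc$rhythm, tolerance = 1e-9)
  expect_equal(get_ss("direction"), orc$direction, tolerance = 1e-9)
  expect_equal(get_ss("group x rhythm"), orc$g_rhythm, tolerance = 1e-9)
  expect_equal(get_ss("group x direction"), orc$g_dir, tolerance = 1e-9)
  expect_equal(get_ss("rhythm x direction"), orc$rd, tolerance = 1e-9)
  expect_equal(get_ss("group x rhythm x direction"), orc$g_rd, tolerance = 1e-9)
  expect_equal(res$ss_err[res$effect == "rhythm"], orc$rhythm_err,
               tolerance = 1e-9)
  # SS conservation: strata sum to the total SS
  expect_equal(attr(res, "ss_total"), orc$total, tolerance = 1e-9)
})

test_that("a pure group x direction effect lands only in that interaction", {
  Y <- make_cells(8)
  group <- rep(c("A", "B"), each = 4)
  a <- 0.1
  Y[group == "A", grepl("_early$", colnames(Y))] <- 0.4 + a
  Y[group == "A", grepl("_late$", colnames(Y))] <- 0.4 - a
  Y[group == "B", grepl("_early$", colnames(Y))] <- 0.4 - a
  Y[group == "B", grepl("_late$", colnames(Y))] <- 0.4 + a
  res <- split_plot_anova(Y, group)
  inter <- c("group x rhythm", "group x direction", "rhythm x direction",
             "group x rhythm x direction")
  ss <- setNames(res$ss[match(inter, res$effect)], inter)
  expect_gt(ss["group x direction"], 0)
  expect_equal(unname(ss[c(1, 3, 4)]), rep(0, 3), tolerance = 1e-12)
  expect_equal(res$ss[res$effect == "direction"], 0, tolerance = 1e-12)
  expect_equal(res$ss[res$effect == "group"], 0, tolerance = 1e-12)
})

test_that("constant data yield zero effect SS throughout", {
  Y <- make_cells(6, fill = 0.37)
  res <- split_plot_anova(Y, rep(c("A", "B"), each = 3))
  expect_true(all(res$ss < 1e-20))
  expect_equal(attr(res, "ss_total"), 0, tolerance = 1e-20)
})

test_that("GG epsilon is bounded and agrees with the car oracle", {
  set.seed(17)
  Y <- make_cells(12) + matrix(rnorm(72, sd = 0.1), 12, 6)
  # induce a sphericity violation by correlating two rhythm levels
  Y[, "low_rate_early"] <- Y[, "low_rate_early"] + 0.8 * Y[, "unaltered_early"]
  Y[, "low_rate_late"] <- Y[, "low_rate_late"] + 0.8 * Y[, "unaltered_late"]
  group <- rep(c("young", "older"), each = 6)
  res <- split_plot_anova(Y, group)
  eps_r <- res$epsilon[res$effect == "rhythm"]
  expect_gte(eps_r, 0.5)      # lower bound 1/(k-1) for k = 3
  expect_lte(eps_r, 1)
  expect_lt(eps_r, 0.999)     # the violation must be detected

  skip_if_not_installed("car")
  idata <- expand.grid(direction = factor(c("early", "late")),
                       rhythm = factor(c("unaltered", "low_rate", "high_rate"),
                                       levels = c("unaltered", "low_rate",
                                                  "high_rate")))
  # car expects columns ordered to match idata rows
  Ycar <- Y[, paste(idata$rhythm, idata$direction, sep = "_")]
  # sum-to-zero group coding so car's type-3 within tests are at the grand mean
  mlm <- lm(Ycar ~ group, data = data.frame(group = factor(group)),
            contrasts = list(group = "contr.sum"))
  A <- car::Anova(mlm, idata = idata, idesign = ~ rhythm * direction, type = 3)
  s <- summary(A, multivariate = FALSE)
  gg <- s$pval.adjustments
  expect_equal(unname(gg["rhythm", "GG eps"]), eps_r, tolerance = 1e-6)
  expect_equal(unname(gg["rhythm", "Pr(>F[GG])"]),
               res$p_gg[res$effect == "rhythm"], tolerance = 1e-6)
  expect_equal(unname(gg["rhythm:direction", "GG eps"]),
               res$epsilon[res$effect == "rhythm x direction"],
               tolerance = 1e-6)
  # uncorrected F values agree with car's univariate table
  utab <- s$univariate.tests
  expect_equal(unname(utab["rhythm", "F value"]),
               res$F[res$effect == "rhythm"], tolerance = 1e-8)
  expect_equal(unname(utab["direction", "F value"]),
               res$F[res$effect == "direction"], tolerance = 1e-8)
})

test_that("unbalanced or undersized designs are rejected", {
  Y <- make_cells(5)
  Y[2, 3] <- NA
  expect_error(split_plot_anova(Y, rep(c("A", "B"), c(3, 2))), "unbalanced")
  expect_error(split_plot_anova(make_cells(3), c("A", "A", "B")), "2 subjects")
  expect_error(split_plot_anova(make_cells(4)[, -1], rep(c("A", "B"), 2)),
               "columns")
})

test_that("battery correlation table mirrors the measure x summary layout", {
  set.seed(18)
  n <- 9
  res <- data.frame(mean_threshold = rnorm(n, 0.4, 0.1),
                    late_early = rnorm(n, 0.1, 0.1),
                    rhythm_diff = rnorm(n, 0.05, 0.05))
  res$GAP <- res$mean_threshold * 10 + rnorm(n, 0, 0.2)
  res$SC <- rnorm(n)
  res$RD <- res$late_early * 5 + rnorm(n, 0, 0.1)
  res$WM <- rnorm(n)
  tab <- battery_correlations(res)
  expect_equal(tab$measure, c("GAP", "SC", "RD", "WM"))
  expect_gt(tab$r_mean_threshold[tab$measure == "GAP"], 0.9)
  expect_gt(tab$r_late_early[tab$measure == "RD"], 0.9)
  expect_equal(tab$r_mean_threshold[1],
               pearson_r(res$GAP, res$mean_threshold)$r)
})
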