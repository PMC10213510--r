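#!/usr/bin/env Rscript
# Figures from the simulated cohort: threshold panels per rhythm condition
# and direction (group means + individual subjects) and the per-subject
# difference-score scatter. Requires results/thresholds.csv from
# analysis/01_simulate.R.
#
#   Rscript analysis/04_figures.R

library(rhythmshift)
library(ggplot2)

results <- read.csv("results/thresholds.csv")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

long <- do.call(rbind, lapply(cell_names(), function(cn) {
  parts <- strsplit(cn, "_(?=early|late)", perl = TRUE)[[1]]
  data.frame(subject_id = results$subject_id, group = results$group,
             rhythm = factor(parts[1], levels = c("unaltered", "low_rate",
                                                  "high_rate")),
             direction = parts[2], threshold = results[[cn]])
}))

p1 <- ggplot(long, aes(rhythm, threshold)) +
  geom_point(color = "firebrick", alpha = 0.5, size = 1) +
  stat_summary(fun = mean, geom = "point", color = "navy", size = 2.5) +
  stat_summary(fun = mean, geom = "line", aes(group = 1), color = "navy") +
  stat_summary(fun.data = mean_se, geom = "errorbar", width = 0.15,
               color = "navy") +
  facet_grid(group ~ direction) +
  labs(x = "rhythm condition", y = expression(paste("threshold ", Delta*T/T)),
       title = "Temporal-shift detection thresholds (simulated cohort)") +
  theme_bw()
ggsave("results/figures/thresholds.png", p1, width = 7, height = 5, dpi = 150)

p2 <- ggplot(results, aes(late_early, rhythm_diff, color = group)) +
  geom_hline(yintercept = 0, linetype = 3) +
  geom_vline(xintercept = 0, linetype = 3) +
  geom_point(size = 2.5) +
  scale_color_manual(values = c(young = "royalblue", older = "firebrick")) +
  labs(x = "late - early difference score", y = "rhythm difference score",
       title = "Per-subject difference scores") +
  theme_bw()
ggsave("results/figures/difference_scores.png", p2, width = 6, height = 4.5,
       dpi = 150)

older <- results[results$group == "older", ]
p3 <- ggplot(older, aes(RD, late_early)) +
  geom_point(color = "firebrick", size = 2.5) +
  geom_smooth(method = "lm", se = FALSE, color = "grey40") +
  labs(x = "rhythm discrimination d'", y = "late - early difference score",
       title = "Older group: RD vs direction asymmetry") +
  theme_bw()
ggsave("results/figures/rd_scatter.png", p3, width = 5, height = 4, dpi = 150)

cat("wrote results/figures/{thresholds,difference_scores,rd_scatter}.png\n")
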