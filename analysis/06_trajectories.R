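#!/usr/bin/env Rscript
# Step 6: score trajectories over time.
#
# Fits the mixed-effects model of windowed SOFA on group, window and their
# interaction (random patient intercept vs intercept+slope chosen by AIC),
# tests consecutive-window contrasts within each group, and draws the
# mean-score trajectory figure. Writes results/trajectory_contrasts.csv and
# results/figures/mean_scores.png.

suppressPackageStartupMessages({
  library(wardscores)
  library(data.table)
})

scored <- fread("results/scores.csv")
pairs <- read.csv("results/pairs.csv")
cohort <- read_cohort("results/cohort")
eligible <- build_cohort(cohort)
labels <- data.frame(patient_id = c(pairs$case_id, pairs$control_id),
                     is_case = rep(c(TRUE, FALSE), each = nrow(pairs)))

traj <- trajectory_table(scored[score == "SOFA"], labels, eligible$patients)
fit <- fit_trajectories(traj)
cat(sprintf("random structure by AIC: %s (%.1f vs %.1f)\n",
            fit$random_structure, fit$aic[1], fit$aic[2]))
cat(sprintf("group x window interaction p = %.3g\n", fit$interaction_p))
cat("consecutive-window contrasts (positive = rising toward the index):\n")
print(fit$contrasts, row.names = FALSE, digits = 3)
write.csv(fit$contrasts, "results/trajectory_contrasts.csv",
          row.names = FALSE)

# mean trajectories for all nine systems
lab_dt <- as.data.table(labels)
means <- merge(scored[in_hospital == TRUE], lab_dt, by = "patient_id")[
  , .(mean_total = mean(total)), by = .(score, window, is_case)]
write.csv(means, "results/mean_scores_by_window.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  means$group <- ifelse(means$is_case, "cases", "controls")
  means$window <- factor(means$window, levels = c("W4", "W3", "W2", "W1"),
                         labels = c("48-72", "24-48", "12-24", "0-12"))
  p <- ggplot(means, aes(window, mean_total, colour = group,
                         group = group)) +
    geom_line() + geom_point() +
    facet_wrap(~score, scales = "free_y") +
    labs(x = "hours before index time", y = "mean score",
         colour = NULL) +
    theme_bw()
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  ggsave("results/figures/mean_scores.png", p, width = 9, height = 7,
         dpi = 120)
  cat("wrote results/figures/mean_scores.png\n")
}
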