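#!/usr/bin/env Rscript
# Step 4: time-resolved discrimination.
#
# DeLong AUC for each score in each pre-index window (the Table-2-style
# comparison), paired DeLong tests of the best score against the others in
# the 0-12 h window, and the ad hoc z-test for comparisons across windows
# with unequal subjects. Writes results/auc_by_window.csv and
# results/auc_comparisons.csv.

suppressPackageStartupMessages({
  library(wardscores)
  library(data.table)
})

scored <- fread("results/scores.csv")
pairs <- read.csv("results/pairs.csv")
labels <- data.frame(patient_id = c(pairs$case_id, pairs$control_id),
                     is_case = rep(c(TRUE, FALSE), each = nrow(pairs)))

aucs <- auc_by_window(scored, labels)
write.csv(aucs, "results/auc_by_window.csv", row.names = FALSE)
cat("AUC by score and window:\n")
print(dcast(aucs, score ~ window, value.var = "auc"), digits = 3)

# rank the systems in the 0-12 h window and compare the best to the rest
w1 <- scored[window == "W1" & in_hospital == TRUE]
w1 <- merge(w1, labels, by = "patient_id")
wide <- dcast(w1, patient_id + is_case ~ score, value.var = "total")
best <- aucs[window == "W1"][order(-auc)]$score[1]
cat(sprintf("\nbest 0-12 h discrimination: %s\n", best))
cmp <- rbindlist(lapply(setdiff(score_names(), best), function(nm) {
  t <- delong_paired_test(wide[[best]], wide[[nm]], wide$is_case)
  data.table(reference = best, comparator = nm,
             auc_ref = t$auc_a, auc_cmp = t$auc_b, z = t$z, p = t$p)
}))
write.csv(cmp, "results/auc_comparisons.csv", row.names = FALSE)
print(cmp, digits = 3)

# same-score decay across windows (unequal subjects: ad hoc z with rho 0.5)
a <- aucs[score == best]
z14 <- adhoc_z_unequal(a[window == "W1"]$auc, a[window == "W1"]$variance,
                       a[window == "W4"]$auc, a[window == "W4"]$variance)
cat(sprintf("\n%s 0-12 h vs 48-72 h: z = %.2f, p = %.2g\n",
            best, z14$z, z14$p))
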