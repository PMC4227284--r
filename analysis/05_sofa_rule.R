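#!/usr/bin/env Rscript
# Step 5: SOFA decision rules.
#
# Derives and evaluates the three SOFA model families on the matched
# cohort: the earliest available score, the peak score within 72 h, and the
# two-threshold rule combining the earliest score with its change over time
# (positive if earliest >= theta_base OR delta > theta_delta), each at its
# Youden-optimal threshold(s), with crude and covariate-adjusted odds
# ratios. Repeats the rule evaluation with in-hospital death as the
# endpoint. Writes results/sofa_models.csv.

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

feats <- sofa_model_features(scored[score == "SOFA"])
fcov <- merge(merge(feats, labels, by = "patient_id"),
              eligible$patients[, c("patient_id", "age", "sex",
                                    "severe_sepsis", "pneumonia", "chf")],
              by = "patient_id")
fcov <- as.data.frame(fcov)
covs <- fcov[, c("age", "sex", "severe_sepsis", "pneumonia", "chf")]

y_e <- youden_threshold(fcov$earliest, fcov$is_case)
y_p <- youden_threshold(fcov$peak, fcov$is_case)
y_d <- derive_delta_rule(fcov$earliest, fcov$delta, fcov$is_case)

row <- function(model, desc, perf, pos) {
  adj <- adjusted_or(pos, fcov$is_case, covs, penalized = TRUE)
  cat(sprintf("%-28s sens %4.0f%%  spec %4.0f%%  OR %6.2f  ORadj %6.2f\n",
              desc, 100 * perf$sensitivity, 100 * perf$specificity,
              perf$or_crude, adj$or_adj))
  data.frame(model = model, rule = desc,
             sensitivity = perf$sensitivity, specificity = perf$specificity,
             youden = perf$youden, or_crude = perf$or_crude,
             or_lo = perf$or_ci95[1], or_hi = perf$or_ci95[2],
             or_adj = adj$or_adj, or_adj_lo = adj$ci95[1],
             or_adj_hi = adj$ci95[2])
}

cat("three SOFA model families (deterioration endpoint):\n")
tab <- rbind(
  row("earliest", sprintf("earliest SOFA >= %d", y_e$threshold),
      y_e$performance, fcov$earliest >= y_e$threshold),
  row("peak", sprintf("peak SOFA >= %d", y_p$threshold),
      y_p$performance, fcov$peak >= y_p$threshold),
  row("delta", sprintf("earliest SOFA >= %d or dSOFA > %d",
                       y_d$rule["theta_base"], y_d$rule["theta_delta"]),
      y_d$performance,
      fcov$earliest >= y_d$rule["theta_base"] |
        fcov$delta > y_d$rule["theta_delta"]))
write.csv(tab, "results/sofa_models.csv", row.names = FALSE)

# mortality endpoint: restrict cases to in-hospital deaths
pat <- eligible$patients
died <- pat$patient_id[!is.na(pat$death_time)]
mp <- pairs[pairs$case_id %in% died, ]
msub <- fcov[fcov$patient_id %in% c(mp$case_id, mp$control_id), ]
md <- derive_delta_rule(msub$earliest, msub$delta, msub$is_case)
cat(sprintf(
  "\nmortality endpoint (%d pairs): earliest >= %d or dSOFA > %d -> sens %.0f%%, spec %.0f%%\n",
  nrow(mp), md$rule["theta_base"], md$rule["theta_delta"],
  100 * md$performance$sensitivity, 100 * md$performance$specificity))
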