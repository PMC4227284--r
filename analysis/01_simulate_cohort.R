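#!/usr/bin/env Rscript
# Step 1: simulate the ward cohort.
#
# Generates a study-scale synthetic cohort of infection admissions (5,188
# admissions, ~6% deteriorating, median time from admission to first event
# 32 h, case physiology drifting toward derangement from 48 h before the
# event) and writes it under results/cohort/ as plain-text CSVs plus a JSON
# parameter sidecar. All later steps read from that directory.

suppressPackageStartupMessages(library(wardscores))

seed <- as.integer(Sys.getenv("WARD_SEED", "20100331")) %% 2^31
params <- cohort_params(seed = seed)
cohort <- generate_cohort(params)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

gt <- ground_truth(cohort)
cat(sprintf("simulated %d admissions (seed %d)\n", nrow(cohort$patients),
            seed))
cat(sprintf("  %d patients (%.1f%%) experience a deterioration event\n",
            sum(gt$is_case), 100 * mean(gt$is_case)))
off <- as.numeric(difftime(gt$event_time[gt$is_case],
                           cohort$patients$admission_time[gt$is_case],
                           units = "hours"))
cat(sprintf("  median admission-to-event %.0f h (IQR %.0f-%.0f)\n",
            median(off), quantile(off, 0.25), quantile(off, 0.75)))
cat(sprintf("  %d observation rows written to results/cohort/\n",
            nrow(cohort$observations)))
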