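# End-to-end driver: from a ward cohort to the windowed AUC table, the
# three SOFA models and the trajectory fit. The analysis scripts and the
# acceptance checks are thin wrappers over this.

utils::globalVariables(c(
  ".", "patient_id", "timestamp", "kind", "name", "value", "hb", "window",
  "index_time", "admission_time", "pts", "win_i", "in_hospital", "offset_h",
  "component", "provenance", "is_case", "total", "score", "n_defaulted",
  "auc", "discrimination", "systolic_bp", "diastolic_bp", "time_h"
))

#' Run the nested case-control deterioration analysis on a cohort
#'
#' Applies the inclusion rules, identifies cases and index times, samples
#' admission-date-matched controls by risk-set sampling, computes the nine
#' windowed severity scores for all matched subjects, and evaluates
#' discrimination (AUC per score per window), the three SOFA model families
#' (earliest, peak, and the earliest-or-delta rule, thresholds chosen by
#' Youden index), covariate-adjusted odds ratios, the SOFA trajectory mixed
#' model and the baseline characteristics table.
#'
#' @param cohort A `ward_cohort` from [generate_cohort()] or [read_cohort()].
#' @param seed Seed for control sampling.
#' @param endpoint `"deterioration"` (any qualifying event) or
#'   `"mortality"` (cases restricted to in-hospital deaths, keeping their
#'   matched controls).
#' @param scores Score systems to evaluate.
#' @param spec Window specification.
#' @param carry Imputation carry policy, see [windowed_features()].
#' @return List with elements `exclusions`, `cases`, `pairs`, `scored`,
#'   `labels`, `aucs`, `features` (per-subject SOFA earliest/delta/peak),
#'   `models` (per model family: threshold/rule, performance, adjusted OR),
#'   `trajectory`, `baseline`.
#' @export
run_ncc_analysis <- function(cohort, seed = 1L,
                             endpoint = c("deterioration", "mortality"),
                             scores = score_names(), spec = window_spec(),
                             carry = "nearest") {
  endpoint <- match.arg(endpoint)
  eligible <- build_cohort(cohort)
  cases <- identify_cases(eligible)
  pairs <- sample_controls(cases, eligible, seed = seed)
  if (endpoint == "mortality") {
    pat <- eligible$patients
    died <- pat$patient_id[!is.na(pat$death_time)]
    pairs <- pairs[pairs$case_id %in% died, , drop = FALSE]
  }
  idx <- pair_index_times(pairs)
  labels <- idx[, c("patient_id", "is_case")]
  scored <- score_windows(eligible, idx, scores = scores, spec = spec,
                          carry = carry)
  aucs <- auc_by_window(scored, labels)

  feats <- sofa_model_features(scored[score == "SOFA"], spec)
  feats <- merge(feats, labels, by = "patient_id")

  covars <- eligible$patients[
    , intersect(c("patient_id", "age", "sex", "severe_sepsis", "pneumonia",
                  "chf"), names(eligible$patients))]
  fcov <- as.data.frame(merge(feats, covars, by = "patient_id"))

  model_or <- function(pos) {
    tryCatch(
      adjusted_or(pos, fcov$is_case,
                  fcov[, setdiff(names(covars), "patient_id")],
                  penalized = TRUE),
      error = function(e) list(or_adj = NA_real_, ci95 = c(NA, NA),
                               p = NA_real_, method = conditionMessage(e)))
  }
  y_earliest <- youden_threshold(fcov$earliest, fcov$is_case)
  y_peak <- youden_threshold(fcov$peak, fcov$is_case)
  y_delta <- derive_delta_rule(fcov$earliest, fcov$delta, fcov$is_case)
  models <- list(
    earliest = list(threshold = y_earliest$threshold,
                    performance = y_earliest$performance,
                    adjusted = model_or(fcov$earliest >= y_earliest$threshold)),
    peak = list(threshold = y_peak$threshold,
                performance = y_peak$performance,
                adjusted = model_or(fcov$peak >= y_peak$threshold)),
    delta = list(rule = y_delta$rule,
                 performance = y_delta$performance,
                 adjusted = model_or(
                   fcov$earliest >= y_delta$rule["theta_base"] |
                   fcov$delta > y_delta$rule["theta_delta"]))
  )

  traj <- trajectory_table(scored[score == "SOFA"], labels,
                           eligible$patients, spec = spec)
  trajectory <- tryCatch(fit_trajectories(traj),
                         error = function(e) e)

  pat <- eligible$patients
  baseline <- summarize_baseline(
    pat[pat$patient_id %in% pairs$case_id, , drop = FALSE],
    pat[pat$patient_id %in% pairs$control_id, , drop = FALSE])

  list(exclusions = attr(eligible, "exclusions"), cases = cases,
       pairs = pairs, scored = scored, labels = labels, aucs = aucs,
       features = fcov, models = models, trajectory = trajectory,
       baseline = baseline)
}
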