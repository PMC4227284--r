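# Window assignment, worst-value selection and the imputation cascade.

test_that("observations land in the half-open window containing their hours-before-index", {
  idx <- EPOCH + 100 * 3600
  adm <- EPOCH
  ts <- idx - c(0.5, 12, 12.0001, 24, 47.9, 71.9, 72, 120) * 3600
  lab <- assign_windows(ts, idx, adm)
  expect_identical(lab, c("W1", "W2", "W2", "W3", "W3", "W4", NA, NA))
  # after the index or before admission: unassigned
  expect_true(is.na(assign_windows(idx + 3600, idx, adm)))
  expect_true(is.na(assign_windows(adm - 3600, idx, adm)))
  expect_error(assign_windows(ts, adm - 3600, adm), "precedes admission")
})

test_that("window spec validates ordering", {
  expect_error(window_spec(c(0, 24, 12, 48, 72)), "increasing")
  spec <- window_spec()
  expect_identical(spec$label, c("W1", "W2", "W3", "W4"))
  expect_identical(spec$start, c(0, 12, 24, 48))
})

test_that("worst value earns the most band points, ties broken toward the index", {
  sofa <- score_definition("SOFA")
  expect_identical(worst_value(c(1.0, 3.4, 2.0), sofa, "creatinine"), 3.4)
  mews <- score_definition("MEWS")
  expect_identical(worst_value(c(55, 130), mews, "heart_rate"), 130)
  expect_identical(worst_value(42, mews, "heart_rate"), 42)
  # 1.3 and 1.8 both score 1 SOFA renal point; the more deranged reading wins
  expect_identical(
    worst_value(c(1.3, 1.8), sofa, "creatinine", hours_before = c(2, 5)), 1.8)
  # equally extreme two-sided tie (MEWS temperature 34.9 vs 38.6, both 2
  # points, equidistant from the normal band midpoint): closest to index wins
  expect_identical(
    worst_value(c(34.9, 38.6), mews, "temperature", hours_before = c(6, 3)),
    38.6)
  expect_identical(
    worst_value(c(34.9, 38.6), mews, "temperature", hours_before = c(3, 6)),
    34.9)
  expect_error(worst_value(numeric(0), sofa, "creatinine"), "empty")
})

test_that("brute-force check: the chosen worst never scores fewer points than any reading", {
  set.seed(21)
  sofa <- score_definition("SOFA")
  for (i in 1:50) {
    vals <- runif(sample(1:6, 1), 0.2, 8)
    w <- worst_value(vals, sofa, "creatinine")
    pts <- band_points(sofa$components$creatinine$bands, vals)
    expect_identical(band_points(sofa$components$creatinine$bands, w),
                     max(pts))
  }
})

# A one-patient cohort with controllable lab measurements per window.
# Index at 72 h after admission so W1..W4 map to 60-72, 48-60, 24-48, 0-24 h
# after admission.
lab_cohort <- function(obs_df, los_h = 200) {
  make_mini_cohort(mini_patient("A", los_h = los_h), obs_df)
}
idx_72 <- function() data.frame(patient_id = "A",
                                index_time = EPOCH + 72 * 3600)

test_that("a value measured only in a far window is carried toward the index, never the reverse", {
  # platelets measured in W3 only (24-48 h before index = 24-48 h after adm)
  co <- lab_cohort(data.frame(patient_id = "A", rel_h = 30, kind = "lab",
                              name = "platelets", value = 80))
  f <- windowed_features(co, idx_72(), "SOFA")
  plt <- as.data.frame(f[f$component == "platelets", ])
  expect_identical(plt$value[plt$window == "W3"], 80)
  expect_identical(plt$provenance[plt$window == "W3"], "measured")
  expect_identical(plt$value[plt$window == "W2"], 80)
  expect_identical(plt$provenance[plt$window == "W2"], "carried")
  expect_identical(plt$value[plt$window == "W1"], 80)
  expect_identical(plt$provenance[plt$window == "W1"], "carried")
  # no future leakage: W4 (farther from index) must not see W3's value
  expect_identical(plt$provenance[plt$window == "W4"], "normal_default")
  expect_equal(plt$value[plt$window == "W4"],
               as.numeric(normal_values()$platelets$mean))
})

test_that("one-step carry stops at the adjacent window; nearest carry searches outward", {
  co <- lab_cohort(data.frame(patient_id = "A", rel_h = 30, kind = "lab",
                              name = "platelets", value = 80))
  f1 <- windowed_features(co, idx_72(), "SOFA", carry = "one_step")
  plt <- as.data.frame(f1[f1$component == "platelets", ])
  expect_identical(plt$provenance[plt$window == "W2"], "carried")
  expect_identical(plt$provenance[plt$window == "W1"], "normal_default")
})

test_that("an analyte never measured defaults to normal in every window; measured everywhere is identity", {
  co <- lab_cohort(data.frame(patient_id = "A",
                              rel_h = c(66, 54, 30, 10),
                              kind = "lab", name = "creatinine",
                              value = c(2.5, 2.0, 1.5, 1.0)))
  f <- windowed_features(co, idx_72(), "SOFA")
  cr <- as.data.frame(f[f$component == "creatinine", ])
  expect_identical(cr$provenance, rep("measured", 4))
  expect_identical(cr$value[match(c("W1", "W2", "W3", "W4"), cr$window)],
                   c(2.5, 2.0, 1.5, 1.0))
  bil <- as.data.frame(f[f$component == "bilirubin", ])
  expect_identical(bil$provenance, rep("normal_default", 4))
  expect_identical(unique(bil$value), normal_values()$bilirubin$mean)
})

test_that("after the cascade every in-hospital cell is complete", {
  set.seed(31)
  co <- generate_cohort(cohort_params(n_admissions = 120, seed = 31))
  cases <- identify_cases(build_cohort(co))
  if (nrow(cases) > 4) cases <- cases[1:4, ]
  idx <- cases[, c("patient_id", "index_time")]
  for (nm in c("SOFA", "SAPS2")) {
    f <- windowed_features(co, idx, nm)
    expect_false(anyNA(f$value))
    expect_true(all(f$provenance %in%
                      c("measured", "carried", "normal_default")))
  }
})

test_that("windows predating admission are flagged as out of hospital", {
  # admitted 30 h before index: W4 (48-72 h) precedes admission
  pat <- mini_patient("B", admit_h = 0, los_h = 100)
  co <- make_mini_cohort(pat, data.frame(patient_id = "B", rel_h = 5,
                                         kind = "lab", name = "creatinine",
                                         value = 1.0))
  idx <- data.frame(patient_id = "B", index_time = EPOCH + 30 * 3600)
  f <- windowed_features(co, idx, "SOFA")
  hosp <- unique(as.data.frame(f)[, c("window", "in_hospital")])
  expect_true(all(hosp$in_hospital[hosp$window %in% c("W1", "W2", "W3")]))
  expect_false(any(hosp$in_hospital[hosp$window == "W4"]))
})

test_that("score_windows produces one total per score, patient and window", {
  co <- generate_cohort(cohort_params(n_admissions = 150, seed = 41))
  elig <- build_cohort(co)
  cases <- identify_cases(elig)
  pairs <- sample_controls(cases, elig, seed = 1)
  idx <- pair_index_times(pairs)
  sc <- score_windows(elig, idx)
  expect_setequal(unique(sc$score), score_names())
  expect_identical(nrow(sc), length(score_names()) * nrow(idx) * 4L)
  expect_true(all(sc$total >= 0))
  # deterministic
  sc2 <- score_windows(elig, idx)
  expect_identical(sc, sc2)
})
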