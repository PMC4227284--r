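# Synthetic ward cohort generator: parameter validation, determinism,
# calibration of the case rate, drift and missingness, and ground truth.

test_that("invalid parameters raise errors naming the offending field", {
  expect_error(cohort_params(n_admissions = 1), "n_admissions")
  expect_error(cohort_params(case_fraction = 1.2), "case_fraction")
  expect_error(cohort_params(vitals_availability = -0.1),
               "vitals_availability")
  expect_error(cohort_params(median_time_to_event = 0),
               "median_time_to_event")
  expect_error(cohort_params(drift_effect = -1), "drift_effect")
})

test_that("generation is deterministic under seed and returns the requested count", {
  p <- cohort_params(n_admissions = 100, case_fraction = 0.10, seed = 7)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(nrow(a$patients), 100L)
  expect_identical(a$patients, b$patients)
  expect_identical(a$observations, b$observations)
  expect_identical(ground_truth(a), ground_truth(b))
})

test_that("record invariants hold: timestamps within the stay, plausible physiology", {
  co <- generate_cohort(cohort_params(n_admissions = 200, seed = 5))
  pat <- co$patients
  expect_true(all(pat$admission_time < pat$discharge_time))
  obs <- co$observations
  adm <- pat$admission_time[match(obs$patient_id, pat$patient_id)]
  dis <- pat$discharge_time[match(obs$patient_id, pat$patient_id)]
  expect_true(all(obs$timestamp >= adm & obs$timestamp <= dis))
  for (col in c("icu_transfer_time", "icu_consult_time",
                "rapid_response_time", "death_time")) {
    ok <- is.na(pat[[col]]) | pat[[col]] >= pat$admission_time
    expect_true(all(ok), label = col)
  }
  hr <- obs[obs$name == "heart_rate", ]$value
  expect_true(all(hr >= 10 & hr <= 300))
  spo2 <- obs[obs$name == "spo2", ]$value
  expect_true(all(spo2 >= 0 & spo2 <= 100))
  ph <- obs[obs$name == "ph", ]$value
  expect_true(all(ph >= 6.5 & ph <= 8.0))
})

test_that("the realized case count matches the binomial expectation at study scale", {
  p <- cohort_params(n_admissions = 5188, case_fraction = 328 / 5188, seed = 1)
  co <- generate_cohort(p)
  n_cases <- sum(ground_truth(co)$is_case)
  sd2 <- 2 * sqrt(5188 * (328 / 5188) * (1 - 328 / 5188))
  expect_lt(abs(n_cases - 328), sd2)
  # composition sanity: every case has at least one event channel
  pat <- co$patients
  gt <- ground_truth(co)
  has_ev <- !is.na(pat$icu_transfer_time) | !is.na(pat$icu_consult_time) |
    !is.na(pat$rapid_response_time) | !is.na(pat$death_time)
  expect_identical(unname(has_ev), unname(gt$is_case))
})

test_that("with zero drift, case and control physiology are indistinguishable", {
  p <- cohort_params(n_admissions = 2500, drift_effect = 0, seed = 11)
  co <- generate_cohort(p)
  gt <- ground_truth(co)
  case_ids <- gt$patient_id[gt$is_case]
  hr <- co$observations[name == "heart_rate"]
  x <- hr[patient_id %in% case_ids, value]
  y <- hr[!patient_id %in% case_ids, value]
  set.seed(3)
  x <- sample(x, min(2000, length(x)))
  y <- sample(y, min(2000, length(y)))
  expect_gt(stats::ks.test(x, y)$p.value, 0.01)
})

test_that("with drift, case physiology is deranged in the declared direction near the event", {
  p <- cohort_params(n_admissions = 3000, seed = 13)
  co <- generate_cohort(p)
  gt <- ground_truth(co)
  ev <- gt$event_time[match(co$observations$patient_id, gt$patient_id)]
  hb <- as.numeric(difftime(ev, co$observations$timestamp, units = "hours"))
  is_case_obs <- co$observations$patient_id %in% gt$patient_id[gt$is_case]
  near <- is_case_obs & !is.na(hb) & hb >= 0 & hb < 12
  normals <- normal_values()
  for (analyte in c("heart_rate", "lactate", "systolic_bp", "platelets")) {
    rows <- co$observations$name == analyte
    x <- co$observations$value[rows & near]                 # cases, 0-12 h
    y <- co$observations$value[rows & !is_case_obs]          # controls
    alt <- if (normals[[analyte]]$derange == "high") "greater" else "less"
    expect_lt(stats::t.test(x, y, alternative = alt)$p.value, 1e-4)
  }
})

test_that("realized per-block availability is close to the configured rates", {
  p <- cohort_params(n_admissions = 800, seed = 17)
  co <- generate_cohort(p)
  pat <- co$patients
  los_h <- as.numeric(difftime(pat$discharge_time, pat$admission_time,
                               units = "hours"))
  # full 12-h vitals blocks per patient vs blocks with >= 1 vitals reading
  vit <- co$observations[kind == "vital" & name == "heart_rate"]
  adm <- pat$admission_time[match(vit$patient_id, pat$patient_id)]
  rel <- as.numeric(difftime(vit$timestamp, adm, units = "hours"))
  observed <- unique(data.frame(pid = vit$patient_id,
                                block = floor(rel / 12)))
  n_full <- pmax(0, floor(los_h / 12))
  grid <- data.frame(
    pid = rep(pat$patient_id, n_full),
    block = unlist(lapply(n_full, function(k) seq_len(k) - 1)))
  observed$hit <- TRUE
  m <- merge(grid, observed, by = c("pid", "block"), all.x = TRUE)
  frac <- mean(!is.na(m$hit))
  se <- sqrt(0.97 * 0.03 / nrow(grid))
  expect_lt(abs(frac - 0.97), 3 * se + 0.005)
  # blood gases in roughly the configured fraction of patients
  abg_pat <- unique(co$observations[kind == "abg", patient_id])
  expect_lt(abs(length(abg_pat) / nrow(pat) - 0.30), 0.05)
})

test_that("ground truth flags exactly the patients with events and rejects foreign cohorts", {
  co <- generate_cohort(cohort_params(n_admissions = 100,
                                      case_fraction = 0.1, seed = 7))
  gt <- ground_truth(co)
  expect_identical(nrow(gt), 100L)
  expect_identical(sum(gt$is_case),
                   sum(!is.na(co$patients$icu_transfer_time) |
                       !is.na(co$patients$icu_consult_time) |
                       !is.na(co$patients$rapid_response_time) |
                       !is.na(co$patients$death_time)))
  none <- generate_cohort(cohort_params(n_admissions = 50,
                                        case_fraction = 0, seed = 2))
  expect_identical(sum(ground_truth(none)$is_case), 0L)
  d <- tempfile()
  write_cohort(co, d)
  foreign <- read_cohort(d)
  expect_error(ground_truth(foreign), "provenance")
})

test_that("cohort files round-trip through the CSV writer and reader", {
  co <- generate_cohort(cohort_params(n_admissions = 60, seed = 9))
  d <- tempfile()
  write_cohort(co, d)
  expect_true(all(file.exists(file.path(d, c("patients.csv",
                                             "observations.csv",
                                             "params.json")))))
  back <- read_cohort(d)
  expect_identical(nrow(back$patients), nrow(co$patients))
  expect_identical(nrow(back$observations), nrow(co$observations))
  expect_identical(back$patients$patient_id, co$patients$patient_id)
  a <- co$observations[order(patient_id, name, timestamp)]
  b <- back$observations[order(patient_id, name, timestamp)]
  expect_equal(a$value, b$value, tolerance = 1e-9)
  expect_identical(format(a$timestamp, "%Y-%m-%d %H:%M:%S"),
                   format(b$timestamp, "%Y-%m-%d %H:%M:%S"))
})
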