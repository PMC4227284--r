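# Shared fixtures built in code: tiny hand-assembled cohorts for the
# windowing and design tests, and a random-snapshot generator for the
# scoring property tests.

EPOCH <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")

# Assemble a ward_cohort from hand-written patient rows and long
# observations (times in hours since each patient's admission).
make_mini_cohort <- function(patients, obs = NULL) {
  defaults <- data.frame(
    age = 50, sex = "female", race = "other", bmi = 25,
    infection_source = "other", infection_dx = TRUE,
    direct_icu_admit = FALSE, care_limits = FALSE,
    admission_type = "medical", severe_sepsis = FALSE, chf = FALSE,
    diabetes = FALSE, copd = FALSE, liver_disease = FALSE,
    renal_disease = FALSE, malignancy = FALSE, metastatic_cancer = FALSE,
    mi_history = FALSE, hiv = FALSE, nursing_home = FALSE,
    septic_shock = FALSE, terminal_illness = FALSE, pneumonia = FALSE,
    stringsAsFactors = FALSE
  )
  for (col in names(defaults)) {
    if (!col %in% names(patients)) patients[[col]] <- defaults[[col]]
  }
  for (col in c("icu_transfer_time", "icu_consult_time",
                "rapid_response_time", "death_time")) {
    if (!col %in% names(patients)) {
      patients[[col]] <- as.POSIXct(rep(NA, nrow(patients)))
    }
  }
  if (is.null(obs)) {
    obs <- data.frame(patient_id = character(0), rel_h = numeric(0),
                      kind = character(0), name = character(0),
                      value = numeric(0))
  }
  adm <- patients$admission_time[match(obs$patient_id, patients$patient_id)]
  observations <- data.table::data.table(
    patient_id = obs$patient_id,
    timestamp = adm + obs$rel_h * 3600,
    kind = obs$kind, name = obs$name, value = obs$value)
  structure(list(patients = patients, observations = observations,
                 params = NULL, .truth = NULL),
            class = "ward_cohort")
}

mini_patient <- function(id, admit_h = 0, los_h = 120, ...) {
  extra <- list(...)
  row <- data.frame(patient_id = id,
                    admission_time = EPOCH + admit_h * 3600,
                    discharge_time = EPOCH + (admit_h + los_h) * 3600,
                    age = 50, sex = "female", race = "other", bmi = 25,
                    infection_source = "other", infection_dx = TRUE,
                    direct_icu_admit = FALSE, care_limits = FALSE,
                    admission_type = "medical",
                    stringsAsFactors = FALSE)
  for (col in c("icu_transfer_time", "icu_consult_time",
                "rapid_response_time", "death_time")) {
    row[[col]] <- as.POSIXct(NA, tz = "UTC")
  }
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

# Random physiologically plausible snapshot: values near normal with
# occasional excursions across the whole plausible range.
random_snapshot <- function() {
  normals <- wardscores::normal_values()
  snap <- wardscores::normal_snapshot(age = runif(1, 18, 95))
  for (nm in names(normals)) {
    e <- normals[[nm]]
    v <- if (runif(1) < 0.3) runif(1, e$lo, e$hi) else
      rnorm(1, e$mean, 2 * e$sd)
    snap[[nm]] <- min(max(v, e$lo), e$hi)
  }
  snap$gcs <- sample(3:15, 1)
  snap$admission_type <- sample(c("scheduled_surgical", "medical",
                                  "unscheduled_surgical"), 1)
  for (flag in c("supplemental_o2", "severe_sepsis", "pneumonia",
                 "nursing_home", "malignancy", "copd", "liver_disease",
                 "diabetes", "metastatic_cancer", "hematologic_malignancy",
                 "aids", "septic_shock", "terminal_illness", "chf")) {
    snap[[flag]] <- runif(1) < 0.2
  }
  snap
}

# Brute-force band lookup: linear scan over the fixture's intervals.
scan_bands <- function(bands, value) {
  for (i in seq_len(nrow(bands))) {
    if (value >= bands$lo[i] && value < bands$hi[i]) return(bands$points[i])
  }
  stop("no band contains ", value)
}

# Brute-force AUC: concordant-pair fraction with ties counted one half.
brute_auc <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  s <- 0
  for (a in x) for (b in y) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x) * length(y))
}
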