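# Synthetic ward-EHR cohort generator. Emulates the statistical structure a
# nested case-control deterioration analysis assumes: infection admissions
# from the ER, a small fraction deteriorating (ICU transfer / consult /
# rapid response / death), physiology drawn around documented normal
# midpoints with case physiology drifting toward derangement in the hours
# before the event, and realistic per-block missingness of vitals and labs.

.AVPU_CODES <- c(A = 1L, V = 2L, P = 3L, U = 4L)

.check_prop <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("cohort_params: '", field, "' must be a proportion in [0, 1]")
  }
}

#' Parameters for the synthetic ward cohort generator
#'
#' Defaults reproduce the cohort structure the analysis assumes: 5,188
#' infection admissions with a 328/5188 case fraction; log-normal time from
#' admission to deterioration with median 32 h and log-scale spread chosen
#' so the quartiles sit near 12 and 124 h; per-12-h-block vitals
#' availability 0.97 and per-24-h metabolic-panel availability 0.94;
#' arterial blood gases in 30% of patients; case physiology departing from
#' baseline starting `drift_onset` = 48 h before the event at
#' `drift_effect` = 0.5 baseline standard deviations per 12 h on the
#' deranged side of each analyte; event-type composition 142 ICU transfers,
#' 200 rapid responses or consults, 110 deaths per 328 cases (overlap
#' allowed); comorbidity and demographic contrasts between cases and
#' controls follow the baseline table of the emulated study design.
#'
#' @param n_admissions Number of admissions to simulate.
#' @param case_fraction Probability an admission deteriorates.
#' @param median_time_to_event Median hours from admission to the first
#'   deterioration event.
#' @param tte_sdlog Log-scale SD of the time-to-event distribution.
#' @param los_meanlog,los_sdlog Log-normal parameters of control length of
#'   stay, hours.
#' @param vitals_availability Probability a 12-h block of vitals is charted.
#' @param labs_availability Probability a 24-h metabolic panel is charted.
#' @param abg_fraction Fraction of patients with any arterial blood gas.
#' @param drift_onset Hours before the event at which case physiology
#'   starts deviating.
#' @param drift_effect Standardized shift per 12 h of drift, applied on the
#'   deranged side of each analyte.
#' @param event_type_probs Named probabilities for
#'   `icu_transfer`, `icu_consult`, `rapid_response`, `death` (independent,
#'   conditioned on at least one).
#' @param comorbidity_prevalences Named list; each entry `c(case=, control=)`.
#' @param baseline Per-analyte baseline distribution list; defaults to the
#'   shipped normal-values fixture ([normal_values()]).
#' @param admission_span_days Calendar span over which admissions arrive.
#' @param direct_icu_rate,care_limit_rate,infection_rate Marginal rates of
#'   the exclusion flags.
#' @param vitals_interval_h,labs_interval_h Charting intervals.
#' @param seed Integer seed; identical params + seed give identical cohorts.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_admissions = 5188,
                          case_fraction = 328 / 5188,
                          median_time_to_event = 32,
                          tte_sdlog = log(124 / 12) / (2 * stats::qnorm(0.75)),
                          los_meanlog = log(60),
                          los_sdlog = 0.8,
                          vitals_availability = 0.97,
                          labs_availability = 0.94,
                          abg_fraction = 0.30,
                          drift_onset = 48,
                          drift_effect = 0.5,
                          event_type_probs = c(icu_transfer = 142 / 328,
                                               icu_consult = 100 / 328,
                                               rapid_response = 100 / 328,
                                               death = 110 / 328),
                          comorbidity_prevalences = list(
                            severe_sepsis     = c(case = 0.76, control = 0.32),
                            chf               = c(case = 0.38, control = 0.30),
                            diabetes          = c(case = 0.43, control = 0.41),
                            copd              = c(case = 0.38, control = 0.41),
                            liver_disease     = c(case = 0.25, control = 0.23),
                            renal_disease     = c(case = 0.27, control = 0.25),
                            malignancy        = c(case = 0.23, control = 0.19),
                            metastatic_cancer = c(case = 0.09, control = 0.07),
                            mi_history        = c(case = 0.17, control = 0.15),
                            hiv               = c(case = 0.05, control = 0.06),
                            nursing_home      = c(case = 0.15, control = 0.08),
                            septic_shock      = c(case = 0.20, control = 0.04),
                            terminal_illness  = c(case = 0.08, control = 0.04)
                          ),
                          baseline = NULL,
                          admission_span_days = 121,
                          direct_icu_rate = 0.02,
                          care_limit_rate = 0.02,
                          infection_rate = 0.97,
                          vitals_interval_h = 4,
                          labs_interval_h = 24,
                          seed = 1L) {
  if (!is.numeric(n_admissions) || length(n_admissions) != 1 ||
      n_admissions < 2) {
    stop("cohort_params: 'n_admissions' must be a single count >= 2")
  }
  .check_prop(case_fraction, "case_fraction")
  .check_prop(vitals_availability, "vitals_availability")
  .check_prop(labs_availability, "labs_availability")
  .check_prop(abg_fraction, "abg_fraction")
  .check_prop(unlist(event_type_probs), "event_type_probs")
  for (nm in names(comorbidity_prevalences)) {
    .check_prop(comorbidity_prevalences[[nm]],
                paste0("comorbidity_prevalences$", nm))
  }
  if (!is.numeric(median_time_to_event) || median_time_to_event <= 0) {
    stop("cohort_params: 'median_time_to_event' must be > 0")
  }
  if (drift_onset <= 0) stop("cohort_params: 'drift_onset' must be > 0")
  if (drift_effect < 0) stop("cohort_params: 'drift_effect' must be >= 0")
  if (is.null(baseline)) baseline <- normal_values()
  structure(
    list(n_admissions = as.integer(n_admissions),
         case_fraction = case_fraction,
         median_time_to_event = median_time_to_event,
         tte_sdlog = tte_sdlog,
         los_meanlog = los_meanlog, los_sdlog = los_sdlog,
         vitals_availability = vitals_availability,
         labs_availability = labs_availability,
         abg_fraction = abg_fraction,
         drift_onset = drift_onset, drift_effect = drift_effect,
         event_type_probs = event_type_probs,
         comorbidity_prevalences = comorbidity_prevalences,
         baseline = baseline,
         admission_span_days = admission_span_days,
         direct_icu_rate = direct_icu_rate,
         care_limit_rate = care_limit_rate,
         infection_rate = infection_rate,
         vitals_interval_h = vitals_interval_h,
         labs_interval_h = labs_interval_h,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

.draw_flag <- function(is_case, prev) {
  stats::runif(length(is_case)) < ifelse(is_case, prev["case"], prev["control"])
}

# Latent standardized derangement for case observations: 0 until
# drift_onset hours before the event, then linear in time at drift_effect
# SD per 12 h up to the event.
.severity_z <- function(hours_before_index, is_case, drift_onset, drift_effect) {
  z <- drift_effect * (drift_onset - hours_before_index) / 12
  z[!is_case | is.na(hours_before_index)] <- 0
  pmin(pmax(z, 0), drift_effect * drift_onset / 12)
}

#' Generate a synthetic ward cohort
#'
#' Simulates admissions, demographics, comorbidities, deterioration events
#' and the time-stamped vitals / laboratory / blood-gas record for each
#' patient. Cases carry a monotone physiologic drift toward derangement
#' beginning `drift_onset` hours before their first event; controls are
#' drift-free, so any case-control difference in physiology is the drift
#' plus the configured comorbidity contrasts. Fully deterministic under
#' `params$seed`.
#'
#' @param params A [cohort_params()] object.
#' @return A `ward_cohort`: list with `patients` (one row per admission),
#'   `observations` (long table: patient_id, timestamp, kind, name, value;
#'   AVPU coded 1-4 for A/V/P/U), `params`, and an internal ground-truth
#'   table retrievable with [ground_truth()].
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("generate_cohort expects a cohort_params object")
  }
  set.seed(params$seed)
  n <- params$n_admissions
  epoch <- as.POSIXct("2009-12-01 00:00:00", tz = "UTC")

  is_case <- stats::runif(n) < params$case_fraction
  n_case <- sum(is_case)

  admission_h <- stats::runif(n, 0, params$admission_span_days * 24)
  age <- round(.rtruncnorm(n, ifelse(is_case, 66, 63),
                           ifelse(is_case, 16, 17), 18, 100))
  sex <- ifelse(stats::runif(n) < ifelse(is_case, 0.53, 0.63),
                "female", "male")
  race_levels <- c("white", "black", "hispanic", "other")
  race <- character(n)
  race[is_case] <- sample(race_levels, n_case, replace = TRUE,
                          prob = c(0.28, 0.29, 0.33, 0.10))
  race[!is_case] <- sample(race_levels, n - n_case, replace = TRUE,
                           prob = c(0.18, 0.34, 0.41, 0.07))
  bmi <- round(stats::rlnorm(n, log(27.5), 0.22), 1)

  src_levels <- c("pneumonia", "urinary", "skin_soft_tissue", "peritonitis",
                  "other")
  infection_source <- character(n)
  infection_source[is_case] <- sample(src_levels, n_case, replace = TRUE,
                                      prob = c(0.42, 0.22, 0.04, 0.03, 0.29))
  infection_source[!is_case] <- sample(src_levels, n - n_case, replace = TRUE,
                                       prob = c(0.26, 0.28, 0.06, 0.01, 0.39))

  com <- params$comorbidity_prevalences
  flags <- lapply(com, .draw_flag, is_case = is_case)
  names(flags) <- names(com)
  flags$pneumonia <- infection_source == "pneumonia"
  # septic shock implies severe sepsis
  flags$severe_sepsis <- flags$severe_sepsis | flags$septic_shock

  direct_icu_admit <- stats::runif(n) < params$direct_icu_rate
  care_limits <- stats::runif(n) < params$care_limit_rate
  infection_dx <- stats::runif(n) < params$infection_rate

  # Times: cases get a time-to-first-event; everyone gets a length of stay.
  tte <- rep(NA_real_, n)
  tte[is_case] <- stats::rlnorm(n_case, log(params$median_time_to_event),
                                params$tte_sdlog)
  los <- stats::rlnorm(n, params$los_meanlog, params$los_sdlog)
  los <- pmax(los, 6)

  # Event channels, conditioned on at least one firing per case.
  ev_names <- names(params$event_type_probs)
  ev <- matrix(FALSE, n, length(ev_names), dimnames = list(NULL, ev_names))
  if (n_case > 0) {
    for (j in ev_names) {
      ev[is_case, j] <- stats::runif(n_case) < params$event_type_probs[[j]]
    }
    none <- is_case & rowSums(ev) == 0
    if (any(none)) {
      pick <- sample(ev_names, sum(none), replace = TRUE,
                     prob = params$event_type_probs)
      ev[cbind(which(none), match(pick, ev_names))] <- TRUE
    }
  }
  ev_time <- matrix(NA_real_, n, length(ev_names),
                    dimnames = list(NULL, ev_names))
  for (j in ev_names) {
    has <- ev[, j]
    ev_time[has, j] <- tte[has] + stats::rexp(sum(has), 1 / 18)
  }
  # The earliest event defines the index; pin one occurring channel to the
  # drawn time-to-event, and push death (when it is not that channel) after
  # every other event so it ends the stay.
  if (n_case > 0) {
    case_idx <- which(is_case)
    first_ch <- vapply(case_idx, function(i) {
      occ <- ev_names[ev[i, ]]
      if (length(occ) == 1) occ else
        sample(occ, 1, prob = params$event_type_probs[occ])
    }, "")
    ev_time[cbind(case_idx, match(first_ch, ev_names))] <- tte[case_idx]
    d <- case_idx[ev[case_idx, "death"] & first_ch != "death"]
    if (length(d)) {
      other_max <- apply(ev_time[d, setdiff(ev_names, "death"), drop = FALSE],
                         1, max, na.rm = TRUE)
      ev_time[d, "death"] <- other_max + stats::rexp(length(d), 1 / 12)
    }
  }

  # Discharge: death ends the stay; other cases stay past the event.
  discharge_h <- admission_h + los
  post_event <- stats::rlnorm(n, log(72), 0.7)
  idx_cases <- which(is_case)
  for (i in idx_cases) {
    if (ev[i, "death"]) {
      discharge_h[i] <- admission_h[i] + ev_time[i, "death"]
    } else {
      last_ev <- max(ev_time[i, ], na.rm = TRUE)
      discharge_h[i] <- admission_h[i] + last_ev + post_event[i]
    }
  }
  los_h <- discharge_h - admission_h
  index_offset <- tte  # hours from admission to first event (cases)

  patient_id <- sprintf("P%05d", seq_len(n))
  patients <- data.frame(
    patient_id = patient_id,
    admission_time = epoch + admission_h * 3600,
    discharge_time = epoch + discharge_h * 3600,
    age = age, sex = sex, race = race, bmi = bmi,
    infection_source = infection_source,
    infection_dx = infection_dx,
    direct_icu_admit = direct_icu_admit,
    care_limits = care_limits,
    admission_type = "medical",
    stringsAsFactors = FALSE
  )
  for (nm in names(flags)) patients[[nm]] <- flags[[nm]]
  for (j in ev_names) {
    patients[[paste0(j, "_time")]] <- epoch + (admission_h + ev_time[, j]) * 3600
  }

  observations <- .generate_observations(
    params, patient_id, admission_h, los_h, is_case, index_offset)
  observations$timestamp <- epoch + observations$time_h * 3600
  observations$time_h <- NULL
  data.table::setcolorder(
    observations, c("patient_id", "timestamp", "kind", "name", "value"))

  truth <- data.frame(
    patient_id = patient_id,
    is_case = is_case,
    event_time = epoch + (admission_h + index_offset) * 3600,
    drift_onset_used = ifelse(is_case, params$drift_onset, NA_real_),
    stringsAsFactors = FALSE
  )

  structure(list(patients = patients,
                 observations = observations[],
                 params = params,
                 .truth = truth),
            class = "ward_cohort")
}

# Build the long observation table. Absolute hours (since cohort epoch) in
# column time_h; AVPU coded 1-4.
.generate_observations <- function(params, patient_id, admission_h, los_h,
                                   is_case, index_offset) {
  n <- length(patient_id)
  baseline <- params$baseline
  index_abs <- admission_h + index_offset  # NA for controls

  schedule <- function(interval, first) {
    counts <- pmax(0L, as.integer(floor((los_h - first) / interval)) + 1L)
    i <- rep(seq_len(n), counts)
    within <- sequence(counts) - 1L
    t_rel <- first + within * interval +
      stats::runif(length(i), -0.4, 0.4) * min(1, interval / 4)
    t_rel <- pmin(pmax(t_rel, 0.1), rep(los_h, counts) - 0.05)
    list(i = i, t_rel = t_rel)
  }

  drop_blocks <- function(i, t_rel, block_h, avail) {
    block <- floor(t_rel / block_h)
    key <- paste(i, block)
    ukey <- unique(key)
    keep <- stats::runif(length(ukey)) < avail
    names(keep) <- ukey
    keep[key]
  }

  draw_panel <- function(i, t_rel, analytes) {
    hrs_before <- index_abs[i] - (admission_h[i] + t_rel)
    hrs_before[hrs_before < 0] <- NA  # post-event: no pre-index drift
    z <- .severity_z(hrs_before, is_case[i], params$drift_onset,
                     params$drift_effect)
    out <- vector("list", length(analytes))
    for (k in seq_along(analytes)) {
      a <- baseline[[analytes[k]]]
      dir <- if (identical(a$derange, "high")) 1 else -1
      v <- a$mean + dir * z * a$sd + stats::rnorm(length(i), 0, a$sd)
      v <- pmin(pmax(v, a$lo), a$hi)
      out[[k]] <- data.table::data.table(
        patient_id = patient_id[i],
        time_h = admission_h[i] + t_rel,
        name = analytes[k], value = v)
    }
    list(table = data.table::rbindlist(out), z = z)
  }

  # Vitals every vitals_interval_h, dropped in 12-h blocks.
  sv <- schedule(params$vitals_interval_h, 1)
  keep <- drop_blocks(sv$i, sv$t_rel, 12, params$vitals_availability)
  sv$i <- sv$i[keep]; sv$t_rel <- sv$t_rel[keep]
  vit_names <- c("heart_rate", "respiratory_rate", "systolic_bp",
                 "diastolic_bp", "temperature", "spo2")
  vit <- draw_panel(sv$i, sv$t_rel, vit_names)
  vitals <- vit$table
  vitals[, kind := "vital"]
  # AVPU: deterministic in the latent severity (alert until deep drift);
  # supplemental O2 charted when the drawn saturation dips below 92%.
  z <- vit$z
  avpu <- ifelse(z < 1.2, 1L, ifelse(z < 2.0, 2L, ifelse(z < 2.8, 3L, 4L)))
  spo2 <- vitals[name == "spo2", value]
  extra <- data.table::rbindlist(list(
    data.table::data.table(patient_id = patient_id[sv$i],
                           time_h = admission_h[sv$i] + sv$t_rel,
                           name = "avpu", value = as.numeric(avpu),
                           kind = "vital"),
    data.table::data.table(patient_id = patient_id[sv$i],
                           time_h = admission_h[sv$i] + sv$t_rel,
                           name = "supplemental_o2",
                           value = as.numeric(spo2 < 92),
                           kind = "vital")
  ))

  # Metabolic panel + CBC daily, dropped in 24-h blocks.
  sl <- schedule(params$labs_interval_h, 5)
  keepl <- drop_blocks(sl$i, sl$t_rel, 24, params$labs_availability)
  sl$i <- sl$i[keepl]; sl$t_rel <- sl$t_rel[keepl]
  lab_names <- c("wbc", "platelets", "bilirubin", "creatinine", "bun",
                 "sodium", "potassium", "bicarbonate", "hematocrit",
                 "glucose", "albumin", "lactate", "band_fraction")
  labs <- draw_panel(sl$i, sl$t_rel, lab_names)$table
  labs[, kind := "lab"]

  # Blood gases: only a fraction of patients ever get one.
  abg_pt <- stats::runif(n) < params$abg_fraction
  sa <- schedule(params$labs_interval_h, 8)
  keepa <- abg_pt[sa$i]
  sa$i <- sa$i[keepa]; sa$t_rel <- sa$t_rel[keepa]
  abg <- draw_panel(sa$i, sa$t_rel, c("pao2", "paco2", "ph"))$table
  abg[, kind := "abg"]

  data.table::rbindlist(list(vitals, extra, labs, abg), use.names = TRUE)
}

#' @export
print.ward_cohort <- function(x, ...) {
  gt <- x$.truth
  cat(sprintf("<ward_cohort> %d admissions, %d with a deterioration event\n",
              nrow(x$patients), if (is.null(gt)) NA else sum(gt$is_case)))
  cat(sprintf("  %d observations (%s)\n", nrow(x$observations),
              paste(names(table(x$observations$kind)), collapse = "/")))
  invisible(x)
}

#' Ground truth of a generated cohort
#'
#' @param cohort A `ward_cohort` from [generate_cohort()]. Cohorts read back
#'   from disk do not carry generation provenance and raise an error.
#' @return Data frame: patient_id, is_case, event_time, drift_onset_used.
#' @export
ground_truth <- function(cohort) {
  if (!inherits(cohort, "ward_cohort") || is.null(cohort$.truth)) {
    stop("ground_truth: cohort lacks generation provenance ",
         "(not produced by generate_cohort in this session)")
  }
  cohort$.truth
}

#' Write a cohort to plain-text files
#'
#' Writes `patients.csv` (one row per admission, ISO-8601 timestamps),
#' `observations.csv` (long: patient_id, timestamp, kind, name, value; AVPU
#' written as letters) and `params.json` (generator parameters + seed).
#'
#' @param cohort A `ward_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ward_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  pat <- cohort$patients
  for (col in names(pat)) {
    if (inherits(pat[[col]], "POSIXct")) pat[[col]] <- iso(pat[[col]])
  }
  utils::write.csv(pat, file.path(dir, "patients.csv"), row.names = FALSE,
                   na = "")
  obs <- data.table::copy(cohort$observations)
  obs[, timestamp := iso(timestamp)]
  obs[, value := as.character(value)]
  obs[name == "avpu", value := names(.AVPU_CODES)[as.integer(value)]]
  data.table::fwrite(obs, file.path(dir, "observations.csv"))
  par <- cohort$params
  par$baseline <- NULL  # shipped fixture, not re-serialized
  jsonlite::write_json(unclass(par), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `patients.csv`, `observations.csv`,
#'   `params.json`.
#' @return A `ward_cohort` (without generation ground truth).
#' @export
read_cohort <- function(dir) {
  pat <- utils::read.csv(file.path(dir, "patients.csv"),
                         stringsAsFactors = FALSE)
  for (col in grep("_time$", names(pat), value = TRUE)) {
    pat[[col]] <- as.POSIXct(pat[[col]], format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  }
  obs <- data.table::fread(file.path(dir, "observations.csv"),
                           colClasses = list(character = "value"))
  obs[, timestamp := as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC")]
  obs[name == "avpu", value := as.character(.AVPU_CODES[value])]
  obs[, value := as.numeric(value)]
  par <- jsonlite::read_json(file.path(dir, "params.json"),
                             simplifyVector = TRUE)
  structure(list(patients = pat, observations = obs[], params = par,
                 .truth = NULL),
            class = "ward_cohort")
}
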