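# Study design: inclusion/exclusion rules, case definition and index times,
# and risk-set sampling of admission-date-matched controls.

.EVENT_COLS <- c("icu_transfer_time", "icu_consult_time",
                 "rapid_response_time", "death_time")

#' Apply the inclusion and exclusion rules
#'
#' Keeps admissions with an infection diagnosis present on admission and
#' drops direct ICU admissions from the ER and patients with limits on
#' life-sustaining interventions. Per-rule exclusion counts are attached as
#' the `"exclusions"` attribute.
#'
#' @param cohort A `ward_cohort`.
#' @param infection_codes Optional character vector of diagnosis codes; when
#'   supplied and the patient table has an `icd9` column, inclusion is
#'   decided by code membership instead of the `infection_dx` flag.
#' @return The filtered `ward_cohort`.
#' @export
build_cohort <- function(cohort, infection_codes = NULL) {
  stopifnot(inherits(cohort, "ward_cohort"))
  pat <- cohort$patients
  infected <- if (!is.null(infection_codes) && "icd9" %in% names(pat)) {
    pat$icd9 %in% infection_codes
  } else if ("infection_dx" %in% names(pat)) {
    pat$infection_dx
  } else {
    stop("build_cohort: patients carry neither infection_dx nor icd9")
  }
  excl <- c(
    no_infection_dx = sum(!infected),
    direct_icu_admit = sum(infected & pat$direct_icu_admit),
    care_limits = sum(infected & !pat$direct_icu_admit & pat$care_limits)
  )
  keep <- infected & !pat$direct_icu_admit & !pat$care_limits
  out <- cohort
  out$patients <- pat[keep, , drop = FALSE]
  ids <- out$patients$patient_id
  out$observations <- cohort$observations[patient_id %in% ids]
  if (!is.null(cohort$.truth)) {
    out$.truth <- cohort$.truth[cohort$.truth$patient_id %in% ids, ,
                                drop = FALSE]
  }
  attr(out, "exclusions") <- c(n_input = nrow(pat), excl,
                               n_eligible = sum(keep))
  out
}

#' Identify cases and their index times
#'
#' A case is any admission with a qualifying deterioration event (ICU
#' transfer, critical care consult, rapid response, or in-hospital death);
#' the index time is the earliest of these events.
#'
#' @param cohort A `ward_cohort` (typically after [build_cohort()]).
#' @return Data frame: patient_id, admission_time, index_time, offset_h
#'   (admission-to-index hours), one row per case.
#' @export
identify_cases <- function(cohort) {
  pat <- cohort$patients
  ev_cols <- intersect(.EVENT_COLS, names(pat))
  if (length(ev_cols) == 0) stop("identify_cases: no event columns present")
  ev <- sapply(pat[ev_cols], as.numeric)
  if (!is.matrix(ev)) ev <- matrix(ev, nrow = nrow(pat))
  idx_num <- suppressWarnings(apply(ev, 1, min, na.rm = TRUE))
  idx_num[!is.finite(idx_num)] <- NA
  index_time <- as.POSIXct(idx_num, origin = "1970-01-01", tz = "UTC")
  is_case <- !is.na(idx_num)
  if (any(is_case & index_time < pat$admission_time)) {
    stop("identify_cases: event recorded before admission")
  }
  out <- data.frame(
    patient_id = pat$patient_id[is_case],
    admission_time = pat$admission_time[is_case],
    index_time = index_time[is_case],
    stringsAsFactors = FALSE
  )
  out$offset_h <- as.numeric(difftime(out$index_time, out$admission_time,
                                      units = "hours"))
  out
}

#' Sample one matched control per case by risk-set sampling
#'
#' For each case, one control is drawn uniformly at random from admissions
#' that never experienced any qualifying event and survived to discharge,
#' were admitted on the same calendar day as the case, and stayed longer
#' than the case's admission-to-index interval. The control's index time is
#' set to the same admission-to-index offset as its case. Controls are used
#' without replacement. When no same-day candidate exists the date match is
#' widened one day at a time up to `widen_to` days; a case with no eligible
#' control even then is dropped and counted in the `"unmatched"` attribute.
#'
#' @param cases Data frame from [identify_cases()].
#' @param cohort The eligible `ward_cohort`.
#' @param seed Integer seed for the sampling.
#' @param match_window_days Initial admission-date tolerance (default 0 =
#'   same calendar day).
#' @param widen_to Maximum tolerance, in days, tried before giving up.
#' @return A `case_control_pairs` data frame: case_id, control_id,
#'   case_index_time, control_index_time, admission_to_index_hours.
#' @export
sample_controls <- function(cases, cohort, seed = 1L,
                            match_window_days = 0L, widen_to = 3L) {
  pat <- cohort$patients
  ev_cols <- intersect(.EVENT_COLS, names(pat))
  any_event <- Reduce(`|`, lapply(pat[ev_cols], function(x) !is.na(x)))
  pool <- pat[!any_event, , drop = FALSE]
  pool_day <- as.Date(pool$admission_time, tz = "UTC")
  pool_los_h <- as.numeric(difftime(pool$discharge_time, pool$admission_time,
                                    units = "hours"))
  used <- logical(nrow(pool))

  set.seed(seed)
  rows <- vector("list", nrow(cases))
  unmatched <- character(0)
  ord <- order(cases$index_time)  # process in event order (risk sets)
  for (i in ord) {
    day <- as.Date(cases$admission_time[i], tz = "UTC")
    offset <- cases$offset_h[i]
    chosen <- NA_integer_
    for (k in match_window_days:widen_to) {
      cand <- which(!used & abs(as.numeric(pool_day - day)) <= k &
                      pool_los_h > offset)
      if (length(cand)) {
        chosen <- if (length(cand) == 1) cand else sample(cand, 1)
        break
      }
    }
    if (is.na(chosen)) {
      unmatched <- c(unmatched, cases$patient_id[i])
      next
    }
    used[chosen] <- TRUE
    rows[[i]] <- data.frame(
      case_id = cases$patient_id[i],
      control_id = pool$patient_id[chosen],
      case_index_time = cases$index_time[i],
      control_index_time = pool$admission_time[chosen] + offset * 3600,
      admission_to_index_hours = offset,
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(pairs)) {
    pairs <- data.frame(case_id = character(0), control_id = character(0),
                        case_index_time = as.POSIXct(character(0)),
                        control_index_time = as.POSIXct(character(0)),
                        admission_to_index_hours = numeric(0))
  }
  rownames(pairs) <- NULL
  class(pairs) <- c("case_control_pairs", "data.frame")
  attr(pairs, "unmatched") <- unmatched
  pairs
}

#' Index times of all matched subjects
#'
#' Stacks cases and their matched controls into the patient_id/index_time
#' table the windowing pipeline consumes, with the case/control label.
#'
#' @param pairs A `case_control_pairs` data frame.
#' @return Data frame: patient_id, index_time, is_case.
#' @export
pair_index_times <- function(pairs) {
  data.frame(
    patient_id = c(pairs$case_id, pairs$control_id),
    index_time = c(pairs$case_index_time, pairs$control_index_time),
    is_case = rep(c(TRUE, FALSE), each = nrow(pairs)),
    stringsAsFactors = FALSE
  )
}
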