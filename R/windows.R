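# Pre-index time windows: map each patient's observation stream onto the
# four windows before the index time, pick the worst value per component
# under the relevant score's band table, and fill gaps by the carry-back /
# assume-normal cascade.

#' The four pre-index windows
#'
#' @param boundaries Numeric vector of window edges in hours before index,
#'   default `c(0, 12, 24, 48, 72)`: windows 0-12, 12-24, 24-48, 48-72 h.
#' @param labels Window labels, nearest-to-index first.
#' @return A `window_spec` data frame with columns `label`, `start`, `end`
#'   (hours before index; half-open `[start, end)`).
#' @export
window_spec <- function(boundaries = c(0, 12, 24, 48, 72),
                        labels = paste0("W", seq_len(length(boundaries) - 1))) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("window_spec: boundaries must be strictly increasing")
  }
  spec <- data.frame(label = labels,
                     start = boundaries[-length(boundaries)],
                     end = boundaries[-1],
                     stringsAsFactors = FALSE)
  class(spec) <- c("window_spec", "data.frame")
  spec
}

#' Assign observations to pre-index windows
#'
#' An observation at clock time `t` lands in the window whose half-open
#' interval `[start, end)` of hours-before-index contains `index_time - t`;
#' a reading taken exactly 12 h before the index therefore belongs to the
#' 12-24 h window. Observations after the index, before admission, or
#' beyond the farthest window edge get `NA`.
#'
#' @param timestamps POSIXct observation times.
#' @param index_time POSIXct index time (scalar).
#' @param admission_time POSIXct admission time (scalar); must be <= index.
#' @param spec A [window_spec()].
#' @return Character vector of window labels (NA where unassigned).
#' @export
assign_windows <- function(timestamps, index_time, admission_time,
                           spec = window_spec()) {
  if (index_time < admission_time) {
    stop("assign_windows: index time precedes admission")
  }
  hb <- as.numeric(difftime(index_time, timestamps, units = "hours"))
  w <- findInterval(hb, c(spec$start, spec$end[nrow(spec)]))
  lab <- rep(NA_character_, length(hb))
  ok <- w >= 1 & w <= nrow(spec) & hb >= 0 & timestamps >= admission_time &
    hb < spec$end[nrow(spec)]
  lab[ok] <- spec$label[w[ok]]
  lab
}

#' Worst value of one component within one window
#'
#' "Worst" is the observation earning the most points under the component's
#' band table in the given score definition; ties go to the observation
#' closest to the index time. Components a score consumes only through a
#' special-term hook have no band table; for those the worst value is the
#' extreme on the deranged side declared in the normal-values registry.
#'
#' @param values Numeric observations of one component in one window.
#' @param definition A [score_definition()].
#' @param component Canonical component name.
#' @param hours_before Hours before index per observation (for tie-breaks);
#'   defaults to the input order (last = closest).
#' @return The worst single value.
#' @export
worst_value <- function(values, definition, component,
                        hours_before = rev(seq_along(values))) {
  if (length(values) == 0) stop("worst_value: empty observation list")
  cmp <- definition$components[[component]]
  if (!is.null(cmp)) {
    pts <- band_points(cmp$bands, values)
    ord <- order(-pts, -.extremeness(values, cmp, component), hours_before)
  } else {
    dir <- .component_direction(component)
    ord <- order(if (dir > 0) -values else values, hours_before)
  }
  values[ord[1]]
}

# Secondary worst-value key among readings with equal band points: how far
# the value sits on the deranged side. For one-sided components this is the
# (signed) value itself; for two-sided band tables it is the distance from
# the midpoint of the zero-point band.
.extremeness <- function(values, cmp, component) {
  if (identical(cmp$direction, "high")) return(values)
  if (identical(cmp$direction, "low")) return(-values)
  zero <- cmp$bands[cmp$bands$points == min(cmp$bands$points), ][1, ]
  mid <- if (is.finite(zero$lo) && is.finite(zero$hi)) {
    (zero$lo + zero$hi) / 2
  } else {
    .component_normal(component)
  }
  abs(values - mid)
}

# Deranged direction (+1 worse-high / -1 worse-low) for hook-only components.
.component_direction <- function(component) {
  normals <- normal_values()
  entry <- normals[[component]]
  if (!is.null(entry)) return(if (identical(entry$derange, "high")) 1 else -1)
  switch(component, gcs = -1, map = -1, pf_ratio = -1, fio2 = 1,
         stop("no derangement direction known for component: ", component))
}

# Normal default for any windowed component; map/pf_ratio/gcs/fio2 are
# derived from the registry midpoints.
.component_normal <- function(component) {
  normals <- normal_values()
  entry <- normals[[component]]
  if (!is.null(entry)) return(as.numeric(entry$mean))
  switch(component,
    map = (normals$systolic_bp$mean + 2 * normals$diastolic_bp$mean) / 3,
    pf_ratio = normals$pao2$mean / 0.21,
    gcs = 15,
    fio2 = 0.21,
    stop("component absent from normal-values fixture: ", component)
  )
}

# Long observation table for windowing: patient_id, hb (hours before
# index), component, value. Adds derived rows (gcs from AVPU, map from
# paired pressures, pf_ratio from PaO2 at charted FiO2 0.21) and drops
# anything outside [admission, index) or beyond the farthest window.
.windowing_obs <- function(cohort, index_times, spec) {
  obs <- data.table::as.data.table(cohort$observations)
  idx <- data.table::as.data.table(index_times)[, .(patient_id, index_time)]
  pat <- data.table::as.data.table(cohort$patients)[
    , .(patient_id, admission_time)]
  obs <- obs[idx, on = "patient_id", nomatch = NULL]
  obs <- obs[pat, on = "patient_id", nomatch = NULL]
  obs[, hb := as.numeric(difftime(index_time, timestamp, units = "hours"))]
  obs <- obs[hb >= 0 & hb < max(spec$end) & timestamp >= admission_time]
  # AVPU codes -> GCS
  obs[name == "avpu", `:=`(name = "gcs", value = c(15, 13, 8, 3)[value])]
  # paired systolic/diastolic -> MAP at the same timestamp
  bp <- data.table::dcast(
    obs[name %in% c("systolic_bp", "diastolic_bp")],
    patient_id + timestamp + hb ~ name, value.var = "value",
    fun.aggregate = mean)
  if (nrow(bp) && all(c("systolic_bp", "diastolic_bp") %in% names(bp))) {
    bp <- bp[!is.na(systolic_bp) & !is.na(diastolic_bp)]
    map_rows <- bp[, .(patient_id, timestamp, hb, name = "map",
                       value = (systolic_bp + 2 * diastolic_bp) / 3)]
  } else {
    map_rows <- NULL
  }
  pf_rows <- obs[name == "pao2",
                 .(patient_id, timestamp, hb, name = "pf_ratio",
                   value = value / 0.21)]
  obs <- data.table::rbindlist(list(
    obs[, .(patient_id, timestamp, hb, name, value)], map_rows, pf_rows),
    use.names = TRUE)
  obs[, window := assign_windows_hb(hb, spec)]
  obs[!is.na(window)]
}

# window label from hours-before-index (vectorized, no timestamps needed)
assign_windows_hb <- function(hb, spec = window_spec()) {
  w <- findInterval(hb, c(spec$start, spec$end[nrow(spec)]))
  lab <- rep(NA_character_, length(hb))
  ok <- !is.na(hb) & w >= 1 & w <= nrow(spec)
  lab[ok] <- spec$label[w[ok]]
  lab
}

#' Windowed worst-value features for one score
#'
#' For every matched patient and pre-index window, selects the worst
#' observed value of each component the score requires (worst = most points
#' under that score's band table, ties to the reading nearest the index),
#' then completes missing cells by the imputation cascade
#' ([impute_cascade()]): carry the nearest measured value from a window
#' farther from the index (earlier in clock time), otherwise assume normal.
#'
#' @param cohort A `ward_cohort`.
#' @param index_times Data frame with `patient_id`, `index_time` (POSIXct).
#' @param definition A [score_definition()] or score name.
#' @param spec A [window_spec()].
#' @param carry `"nearest"` (search outward past empty windows) or
#'   `"one_step"` (strictly the adjacent earlier window).
#' @return data.table: patient_id, window, in_hospital, component, value,
#'   provenance (`measured` / `carried` / `normal_default`).
#' @export
windowed_features <- function(cohort, index_times, definition,
                              spec = window_spec(), carry = "nearest") {
  if (is.character(definition)) definition <- score_definition(definition)
  carry <- match.arg(carry, c("nearest", "one_step"))
  comps <- setdiff(required_components(definition),
                   c("age", "admission_type"))
  obs <- .windowing_obs(cohort, index_times, spec)
  obs <- obs[name %in% comps]

  worsts <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    oc <- obs[name == comps[k]]
    if (nrow(oc) == 0) next
    cmp <- definition$components[[comps[k]]]
    if (!is.null(cmp)) {
      oc[, pts := band_points(cmp$bands, value)]
      oc[, ext := .extremeness(value, cmp, comps[k])]
    } else {
      oc[, pts := .component_direction(comps[k]) * value]
      oc[, ext := 0]
    }
    data.table::setorder(oc, patient_id, window, -pts, -ext, hb)
    worsts[[k]] <- oc[, .(value = value[1L]), by = .(patient_id, window)][
      , component := comps[k]]
  }
  worsts <- data.table::rbindlist(worsts[!vapply(worsts, is.null, TRUE)])

  idx <- data.table::as.data.table(index_times)
  pat <- data.table::as.data.table(cohort$patients)[
    , .(patient_id, admission_time)]
  idx <- idx[pat, on = "patient_id", nomatch = NULL]
  idx[, offset_h := as.numeric(difftime(index_time, admission_time,
                                        units = "hours"))]
  impute_cascade(worsts, idx[, .(patient_id, offset_h)], comps, spec, carry)
}

#' Carry-back / assume-normal imputation cascade
#'
#' Completes the per-window worst-value grid: a component missing in window
#' `w` is filled from the nearest window farther from the index (earlier in
#' clock time) holding a measured value; if no earlier window was measured,
#' the documented normal midpoint is used. Values are never carried from a
#' window nearer the index, so no deterioration signal can leak backward in
#' time. Windows predating admission are flagged `in_hospital = FALSE` (and
#' filled with normal defaults for completeness, but downstream analyses
#' exclude them).
#'
#' @param worsts data.table of measured worst values: patient_id, window,
#'   component, value.
#' @param offsets data.table: patient_id, offset_h (admission-to-index
#'   hours).
#' @param comps Components to complete.
#' @param spec A [window_spec()].
#' @param carry `"nearest"` or `"one_step"`.
#' @return data.table: patient_id, window, in_hospital, component, value,
#'   provenance.
#' @export
impute_cascade <- function(worsts, offsets, comps, spec = window_spec(),
                           carry = "nearest") {
  offsets <- data.table::as.data.table(offsets)
  grid <- data.table::CJ(patient_id = offsets$patient_id,
                         window = spec$label, component = comps,
                         unique = TRUE)
  if (nrow(worsts)) {
    grid <- worsts[grid, on = c("patient_id", "window", "component")]
  } else {
    grid[, value := NA_real_]
  }
  grid[, provenance := ifelse(is.na(value), NA_character_, "measured")]
  grid <- grid[offsets, on = "patient_id"]
  grid[, win_i := match(window, spec$label)]
  grid[, in_hospital := offset_h > spec$start[win_i]]

  nw <- nrow(spec)
  # wide per (patient, component): one column per window, near-to-far order
  wide <- data.table::dcast(grid, patient_id + component ~ win_i,
                            value.var = "value")
  vals <- as.matrix(wide[, as.character(seq_len(nw)), with = FALSE])
  measured <- !is.na(vals)
  filled <- vals
  prov <- matrix(ifelse(measured, "measured", NA_character_),
                 nrow(vals), nw)
  for (w in seq_len(nw)) {
    need <- !measured[, w]
    if (!any(need)) next
    src_range <- if (carry == "one_step") {
      if (w + 1 <= nw) (w + 1) else integer(0)
    } else {
      if (w + 1 <= nw) (w + 1):nw else integer(0)
    }
    src_val <- rep(NA_real_, nrow(vals))
    for (s in src_range) {
      take <- need & is.na(src_val) & measured[, s]
      src_val[take] <- vals[take, s]
    }
    carried <- need & !is.na(src_val)
    filled[carried, w] <- src_val[carried]
    prov[carried, w] <- "carried"
    defaulted <- need & is.na(src_val)
    if (any(defaulted)) {
      normal_map <- vapply(unique(wide$component[defaulted]),
                           .component_normal, 0)
      filled[defaulted, w] <- normal_map[wide$component[defaulted]]
      prov[defaulted, w] <- "normal_default"
    }
  }
  long <- data.table::data.table(
    patient_id = rep(wide$patient_id, nw),
    component = rep(wide$component, nw),
    win_i = rep(seq_len(nw), each = nrow(wide)),
    value = as.vector(filled),
    provenance = as.vector(prov))
  long[, window := spec$label[win_i]]
  out <- long[grid[, .(patient_id, component, win_i, in_hospital)],
              on = c("patient_id", "component", "win_i")]
  data.table::setorder(out, patient_id, win_i, component)
  out[, .(patient_id, window, in_hospital, component, value, provenance)]
}

#' Per-window snapshots and scores for the nine systems
#'
#' Runs the full windowing pipeline for each requested score: worst values
#' per window under that score's band tables, imputation cascade, snapshot
#' assembly (adding age, sex, admission type and comorbidity flags from the
#' patient table) and scoring.
#'
#' @inheritParams windowed_features
#' @param scores Character vector of score names (default all nine).
#' @return data.table: patient_id, window, in_hospital, score, total,
#'   n_defaulted (components filled with normal defaults).
#' @export
score_windows <- function(cohort, index_times, scores = score_names(),
                          spec = window_spec(), carry = "nearest") {
  pat <- data.table::as.data.table(cohort$patients)
  out <- vector("list", length(scores))
  for (k in seq_along(scores)) {
    def <- score_definition(scores[k])
    feats <- windowed_features(cohort, index_times, def, spec, carry)
    snap <- data.table::dcast(feats, patient_id + window + in_hospital ~
                                component, value.var = "value")
    ndef <- feats[, .(n_defaulted = sum(provenance == "normal_default")),
                  by = .(patient_id, window)]
    snap <- snap[ndef, on = c("patient_id", "window")]
    keep <- intersect(
      c("patient_id", "age", "sex", "admission_type", "severe_sepsis",
        "pneumonia", "chf", "diabetes", "copd", "liver_disease",
        "renal_disease", "malignancy", "metastatic_cancer", "mi_history",
        "hiv", "nursing_home", "septic_shock", "terminal_illness"),
      names(pat))
    snap <- snap[pat[, keep, with = FALSE], on = "patient_id",
                 nomatch = NULL]
    res <- score_table(def, as.data.frame(snap))
    out[[k]] <- data.table::data.table(
      patient_id = snap$patient_id, window = snap$window,
      in_hospital = snap$in_hospital, score = scores[k],
      total = res$total, n_defaulted = snap$n_defaulted)
  }
  scored <- data.table::rbindlist(out)
  data.table::setorder(scored, score, patient_id, window)
  scored[]
}
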