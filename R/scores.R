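# Severity-score engine: generic band lookup over fixture tables plus the
# per-score special terms that do not fit a one-dimensional band (GCS
# arithmetic, FiO2-dependent oxygenation, admission-type and chronic-disease
# points, multi-variable triggers).

.AVPU_GCS <- c(A = 15L, V = 13L, P = 8L, U = 3L)

#' Convert an AVPU level to its near-equivalent Glasgow Coma Scale value
#'
#' Wards commonly chart consciousness as alert / responds to voice /
#' responds to pain / unresponsive rather than a full GCS. This maps each
#' level to a published near-equivalent GCS value (A=15, V=13, P=8, U=3),
#' which is what the GCS-based components of the nine scores consume. The
#' mapping is strictly monotone: A > V > P > U.
#'
#' @param avpu Character vector of levels in `c("A","V","P","U")`.
#' @return Integer GCS values in 3..15.
#' @export
#' @examples
#' avpu_to_gcs(c("A", "V", "P", "U"))
avpu_to_gcs <- function(avpu) {
  avpu <- as.character(avpu)
  bad <- !avpu %in% names(.AVPU_GCS)
  if (any(bad)) stop("unknown AVPU level: ", avpu[which(bad)[1]])
  unname(.AVPU_GCS[avpu])
}

.flag_col <- function(df, name) {
  if (name %in% names(df)) {
    v <- df[[name]]
    v[is.na(v)] <- FALSE
    as.logical(v)
  } else {
    rep(FALSE, nrow(df))
  }
}

.num_col <- function(df, name, score) {
  if (!name %in% names(df) || anyNA(df[[name]])) {
    stop(score, ": component '", name,
         "' missing or NA in snapshot (run the imputation cascade first)")
  }
  as.numeric(df[[name]])
}

# Special-term hooks. Each entry lists the numeric snapshot columns it needs
# (flags are soft: absent means FALSE / not collected) and a vectorized
# function over a snapshot table returning integer points.
.score_hooks <- list(
  # Dose-free vasopressor escalation of the SOFA cardiovascular component:
  # any vasopressor lifts a hypotensive ward patient's cardiovascular score
  # from the MAP band (<=1) to the mid catecholamine band (3). Ward cohorts
  # are unventilated and unsupported, so this is inert by default.
  sofa_vasopressors = list(
    requires = character(0),
    fn = function(df) ifelse(.flag_col(df, "vasopressors"), 2L, 0L)
  ),
  apache2_gcs = list(
    requires = "gcs",
    fn = function(df) as.integer(round(15 - .num_col(df, "gcs", "APACHE2")))
  ),
  apache2_oxygenation = list(
    requires = c("pao2", "paco2", "fio2"),
    fn = function(df) {
      fio2 <- .num_col(df, "fio2", "APACHE2")
      pao2 <- .num_col(df, "pao2", "APACHE2")
      paco2 <- .num_col(df, "paco2", "APACHE2")
      aado2 <- fio2 * 713 - paco2 / 0.8 - pao2
      pts_hi <- ifelse(aado2 >= 500, 4L,
                ifelse(aado2 >= 350, 3L,
                ifelse(aado2 >= 200, 2L, 0L)))
      pts_lo <- ifelse(pao2 > 70, 0L,
                ifelse(pao2 > 60, 1L,
                ifelse(pao2 >= 55, 3L, 4L)))
      as.integer(ifelse(fio2 >= 0.5, pts_hi, pts_lo))
    }
  ),
  saps2_ventilated_pf = list(
    requires = character(0),
    fn = function(df) {
      vent <- .flag_col(df, "mechanical_ventilation")
      if (!any(vent)) return(rep(0L, nrow(df)))
      pf <- .num_col(df, "pf_ratio", "SAPS2")
      pts <- ifelse(pf < 100, 11L, ifelse(pf < 200, 9L, 6L))
      as.integer(ifelse(vent, pts, 0L))
    }
  ),
  saps2_chronic_disease = list(
    requires = character(0),
    fn = function(df) {
      pmax(ifelse(.flag_col(df, "aids"), 17L, 0L),
           ifelse(.flag_col(df, "hematologic_malignancy"), 10L, 0L),
           ifelse(.flag_col(df, "metastatic_cancer"), 9L, 0L))
    }
  ),
  saps2_admission_type = list(
    requires = character(0),
    fn = function(df) {
      type <- if ("admission_type" %in% names(df)) {
        as.character(df$admission_type)
      } else {
        rep("medical", nrow(df))
      }
      pts <- c(scheduled_surgical = 0L, medical = 6L, unscheduled_surgical = 8L)
      bad <- !type %in% names(pts)
      if (any(bad)) stop("SAPS2: unknown admission_type: ", type[which(bad)[1]])
      unname(pts[type])
    }
  ),
  meds_resp_distress = list(
    requires = c("respiratory_rate", "spo2"),
    fn = function(df) {
      rr <- .num_col(df, "respiratory_rate", "MEDS")
      spo2 <- .num_col(df, "spo2", "MEDS")
      ifelse(rr > 20 | spo2 < 90, 3L, 0L)
    }
  ),
  meds_altered_mental_status = list(
    requires = "gcs",
    fn = function(df) ifelse(.num_col(df, "gcs", "MEDS") < 15, 2L, 0L)
  ),
  scs_consciousness = list(
    requires = "gcs",
    fn = function(df) {
      gcs <- .num_col(df, "gcs", "SCS")
      ifelse(gcs <= 8, 4L, ifelse(gcs < 15, 2L, 0L))
    }
  )
)

#' Components a score definition requires from a snapshot
#'
#' Numeric components from the band tables plus the numeric inputs of the
#' definition's hooks. Boolean flag terms are not listed: an absent flag is
#' read as FALSE (not collected scores normal).
#'
#' @param definition A [score_definition()].
#' @return Character vector of component names.
#' @export
required_components <- function(definition) {
  stopifnot(inherits(definition, "score_definition"))
  hooks <- vapply(definition$special_terms, function(s) {
    if (identical(s$type, "hook")) s$name else NA_character_
  }, "")
  hooks <- hooks[!is.na(hooks)]
  extra <- unlist(lapply(hooks, function(h) .score_hooks[[h]]$requires))
  unique(c(names(definition$components), extra))
}

#' Fill the derived snapshot components
#'
#' Derives mean arterial pressure as `(SBP + 2 DBP)/3` where not directly
#' recorded, the PaO2/FiO2 ratio (FiO2 defaults to 0.21, room air, when not
#' charted), and GCS from AVPU where only AVPU was charted. Returns the
#' table with the derived columns added.
#'
#' @param df Snapshot table (one row per snapshot).
#' @return The same table with `map`, `pf_ratio`, `gcs`, `fio2` present.
#' @export
derive_snapshot_components <- function(df) {
  if (!"fio2" %in% names(df)) df$fio2 <- 0.21
  df$fio2[is.na(df$fio2)] <- 0.21
  if (!"map" %in% names(df) || anyNA(df$map)) {
    if (all(c("systolic_bp", "diastolic_bp") %in% names(df))) {
      map <- (df$systolic_bp + 2 * df$diastolic_bp) / 3
      if ("map" %in% names(df)) {
        df$map <- ifelse(is.na(df$map), map, df$map)
      } else {
        df$map <- map
      }
    }
  }
  if ((!"gcs" %in% names(df) || anyNA(df$gcs)) && "avpu" %in% names(df)) {
    gcs <- avpu_to_gcs(df$avpu)
    if ("gcs" %in% names(df)) {
      df$gcs <- ifelse(is.na(df$gcs), gcs, df$gcs)
    } else {
      df$gcs <- gcs
    }
  }
  if (all(c("pao2", "fio2") %in% names(df))) {
    df$pf_ratio <- df$pao2 / df$fio2
  }
  df
}

#' Score a table of snapshots under one definition
#'
#' Vectorized scoring: every row of `df` is one complete snapshot (worst
#' values for one patient-window, after imputation). Band components are
#' looked up in the fixture tables; flag terms add their points when the
#' flag is TRUE (an absent flag column counts as FALSE); hooks compute their
#' term from the raw snapshot columns.
#'
#' @param definition A [score_definition()].
#' @param df Snapshot table.
#' @return List with `total` (integer vector) and `points` (integer matrix,
#'   one column per component / special term).
#' @export
score_table <- function(definition, df) {
  stopifnot(inherits(definition, "score_definition"), is.data.frame(df))
  df <- derive_snapshot_components(df)
  n <- nrow(df)
  cols <- list()
  for (cmp in definition$components) {
    vals <- .num_col(df, cmp$name, definition$name)
    cols[[cmp$name]] <- as.integer(band_points(cmp$bands, vals))
  }
  for (s in definition$special_terms) {
    if (identical(s$type, "flag")) {
      cols[[paste0("flag_", s$component)]] <-
        ifelse(.flag_col(df, s$component), s$points, 0L)
    } else if (identical(s$type, "hook")) {
      hook <- .score_hooks[[s$name]]
      if (is.null(hook)) stop(definition$name, ": unknown hook ", s$name)
      cols[[s$name]] <- as.integer(hook$fn(df))
    } else {
      stop(definition$name, ": unknown special term type ", s$type)
    }
  }
  points <- do.call(cbind, cols)
  total <- as.integer(rowSums(points))
  out_of_range <- total < definition$total_range[1] |
    total > definition$total_range[2]
  if (any(out_of_range)) {
    stop(definition$name, ": total ", total[which(out_of_range)[1]],
         " outside declared range [", definition$total_range[1], ", ",
         definition$total_range[2], "]")
  }
  list(total = total, points = points)
}

#' Compute one severity score for a single snapshot
#'
#' @param definition A [score_definition()] (or a score name).
#' @param snapshot Named list or one-row data frame of component values; an
#'   optional `provenance` attribute (named character vector with values
#'   `measured` / `carried` / `normal_default`) is propagated into
#'   `defaulted_components`.
#' @return A `score_result`: list with `score`, `total`, `per_component`,
#'   `defaulted_components`.
#' @export
#' @examples
#' snap <- normal_snapshot()
#' compute_score(score_definition("SOFA"), snap)$total  # 0
compute_score <- function(definition, snapshot) {
  if (is.character(definition)) definition <- score_definition(definition)
  prov <- attr(snapshot, "provenance")
  df <- if (is.data.frame(snapshot)) snapshot else
    as.data.frame(snapshot[!vapply(snapshot, is.null, TRUE)],
                  stringsAsFactors = FALSE)
  if (nrow(df) != 1L) stop("compute_score expects a single snapshot")
  res <- score_table(definition, df)
  defaulted <- character(0)
  if (!is.null(prov)) {
    used <- required_components(definition)
    defaulted <- intersect(names(prov)[prov == "normal_default"], used)
  }
  structure(
    list(score = definition$name, total = res$total[1],
         per_component = res$points[1, ], defaulted_components = defaulted),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %s = %d\n", x$score, x$total))
  nz <- x$per_component[x$per_component != 0]
  if (length(nz)) {
    cat("  nonzero components:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  }
  if (length(x$defaulted_components)) {
    cat("  defaulted:", paste(x$defaulted_components, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compute all nine scores for a single snapshot
#'
#' @param snapshot As in [compute_score()].
#' @return Named list of `score_result`s, one per system.
#' @export
compute_all_scores <- function(snapshot) {
  out <- lapply(score_names(), function(nm) {
    tryCatch(compute_score(score_definition(nm), snapshot),
             error = function(e) stop(nm, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  names(out) <- score_names()
  out
}

#' A fully normal reference snapshot
#'
#' Every analyte at its documented normal midpoint (the shared
#' normal-values fixture), a 35-year-old alert patient with no comorbidity
#' flags, breathing room air, admission type neutral (scheduled surgical).
#' Scores the documented minimum of every system; used as the base for
#' imputation defaults and in tests.
#'
#' @param age Age in years (default 35, below every age band).
#' @return Named list snapshot with a `provenance` attribute marking every
#'   entry `normal_default`.
#' @export
normal_snapshot <- function(age = 35) {
  normals <- normal_values()
  snap <- lapply(normals, `[[`, "mean")
  snap$age <- age
  snap$gcs <- 15
  snap$avpu <- "A"
  snap$sex <- "female"
  snap$admission_type <- "scheduled_surgical"
  for (flag in c("supplemental_o2", "mechanical_ventilation", "vasopressors",
                 "chronic_organ_insufficiency", "terminal_illness",
                 "septic_shock", "pneumonia", "nursing_home", "malignancy",
                 "copd", "liver_disease", "diabetes", "metastatic_cancer",
                 "hematologic_malignancy", "aids", "severe_sepsis", "chf")) {
    snap[[flag]] <- FALSE
  }
  prov <- rep("normal_default", length(snap))
  names(prov) <- names(snap)
  attr(snap, "provenance") <- prov
  snap
}
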