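# Mixed-effects modelling of score trajectories over the pre-index windows:
# does the mean score of cases rise toward the index while controls stay
# flat, after adjusting for baseline differences?

#' Assemble the long score-trajectory table
#'
#' One row per matched subject per in-hospital window, with the window
#' recoded as time (farthest-from-index window first, so "later" means
#' closer to the event) and baseline covariates attached.
#'
#' @param scored Output of [score_windows()] filtered to one score.
#' @param labels Data frame: patient_id, is_case.
#' @param patients Patient table carrying the covariates.
#' @param covariates Covariate columns to attach.
#' @param spec The [window_spec()] used.
#' @return data.frame ready for [fit_trajectories()].
#' @export
trajectory_table <- function(scored, labels, patients,
                             covariates = c("age", "sex", "severe_sepsis",
                                            "pneumonia", "chf"),
                             spec = window_spec()) {
  sc <- data.table::as.data.table(scored)[in_hospital == TRUE]
  if (length(unique(sc$score)) > 1) {
    stop("trajectory_table: filter to a single score first")
  }
  lab <- data.table::as.data.table(labels)[, .(patient_id, is_case)]
  sc <- sc[lab, on = "patient_id", nomatch = NULL]
  covariates <- intersect(covariates, names(patients))
  pat <- data.table::as.data.table(patients)[
    , c("patient_id", covariates), with = FALSE]
  sc <- sc[pat, on = "patient_id", nomatch = NULL]
  out <- as.data.frame(sc)
  # time runs from the farthest window (earliest clock time) to the nearest
  out$time <- factor(out$window, levels = rev(spec$label))
  out$group <- factor(ifelse(out$is_case, "case", "control"),
                      levels = c("control", "case"))
  out
}

#' Mixed-effects model of score trajectories with consecutive contrasts
#'
#' Fits a linear mixed model of the windowed score on group, window (as
#' categorical time), their interaction and baseline covariates, with a
#' patient-level random intercept; a random intercept + slope structure is
#' also fitted and the structure with the smaller AIC (maximum likelihood)
#' is kept. Within each group, contrasts between consecutive windows are
#' tested with Satterthwaite degrees of freedom.
#'
#' @param traj Long table from [trajectory_table()].
#' @param covariates Covariate columns (subset of those in `traj`).
#' @return A `trajectory_fit`: list with `model` (lmerTest fit), `aic`
#'   (named, both candidate structures), `random_structure`, `fixed`
#'   (fixed-effect table), `contrasts` (group, interval, estimate, se, df,
#'   p), `interaction_p` (joint test of the group-by-window interaction),
#'   `converged`.
#' @export
fit_trajectories <- function(traj, covariates = c("age", "sex",
                                                  "severe_sepsis",
                                                  "pneumonia", "chf")) {
  covariates <- intersect(covariates, names(traj))
  if (length(unique(traj$group)) < 2) {
    stop("fit_trajectories: both groups must be present")
  }
  traj$time_num <- as.integer(traj$time) - 1L
  rhs <- paste(c("group * time", covariates), collapse = " + ")
  f1 <- stats::as.formula(paste("total ~", rhs, "+ (1 | patient_id)"))
  f2 <- stats::as.formula(paste("total ~", rhs,
                                "+ (1 + time_num | patient_id)"))
  fit1 <- suppressMessages(suppressWarnings(
    lmerTest::lmer(f1, data = traj, REML = FALSE)))
  fit2 <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(f2, data = traj, REML = FALSE))),
    error = function(e) NULL)
  aic <- c(intercept = stats::AIC(fit1),
           intercept_slope = if (is.null(fit2)) NA_real_ else stats::AIC(fit2))
  use2 <- !is.null(fit2) && !is.na(aic[2]) && aic[2] < aic[1]
  model <- if (use2) fit2 else fit1
  conv <- length(model@optinfo$conv$lme4$messages) == 0

  fe <- lme4::fixef(model)
  times <- levels(traj$time)
  mk_L <- function(group, from, to) {
    L <- stats::setNames(rep(0, length(fe)), names(fe))
    term <- function(t) paste0("time", t)
    iterm <- function(t) paste0("groupcase:time", t)
    if (term(to) %in% names(L)) L[term(to)] <- 1
    if (term(from) %in% names(L)) L[term(from)] <- -1
    if (group == "case") {
      if (iterm(to) %in% names(L)) L[iterm(to)] <- 1
      if (iterm(from) %in% names(L)) L[iterm(from)] <- -1
    }
    L
  }
  rows <- list()
  for (g in c("control", "case")) {
    for (k in seq_len(length(times) - 1)) {
      L <- mk_L(g, times[k], times[k + 1])
      ct <- lmerTest::contest(model, L, joint = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        group = g,
        interval = paste(times[k], "->", times[k + 1]),
        estimate = ct$Estimate, se = ct$`Std. Error`, df = ct$df,
        p = ct$`Pr(>|t|)`, stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)

  int_terms <- grep("^groupcase:time", names(fe), value = TRUE)
  Lj <- matrix(0, length(int_terms), length(fe),
               dimnames = list(int_terms, names(fe)))
  for (t in int_terms) Lj[t, t] <- 1
  jt <- lmerTest::contest(model, Lj, joint = TRUE)

  structure(
    list(model = model, aic = aic,
         random_structure = if (use2) "intercept_slope" else "intercept",
         fixed = fe, contrasts = contrasts,
         interaction_p = jt$`Pr(>F)`, converged = conv),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "<trajectory_fit> random structure: %s (AIC %.1f vs %.1f)%s\n",
    x$random_structure, x$aic[1], x$aic[2],
    if (x$converged) "" else " [did not converge cleanly]"))
  cat(sprintf("group x window interaction p = %.3g\n", x$interaction_p))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
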