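# Time-resolved discrimination: DeLong AUC, paired and unpaired AUC
# comparisons, and the score-by-window AUC table.

.check_labels <- function(labels, n) {
  labels <- as.logical(labels)
  if (length(labels) != n) stop("labels and scores differ in length")
  if (anyNA(labels)) stop("labels contain NA")
  if (all(labels) || !any(labels)) {
    stop("both classes must be present (single-class input)")
  }
  labels
}

# DeLong structural components: per-case and per-control placement values.
.delong_components <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi),
       m = length(x), n = length(y))
}

#' AUC with DeLong variance and confidence interval
#'
#' The area under the ROC curve computed as the Mann-Whitney concordance
#' (ties counted one half), with its variance from DeLong's structural
#' components and a Wald 95% interval.
#'
#' @param scores Numeric risk scores.
#' @param labels Logical (or 0/1) case indicators, same length.
#' @return A `roc_result`: list with `auc`, `variance`, `ci95`, `n_cases`,
#'   `n_controls`.
#' @export
#' @examples
#' auc_delong(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc  # 1
auc_delong <- function(scores, labels) {
  labels <- .check_labels(labels, length(scores))
  d <- .delong_components(scores, labels)
  v <- stats::var(d$v10) / d$m + stats::var(d$v01) / d$n
  half <- stats::qnorm(0.975) * sqrt(v)
  structure(
    list(auc = d$auc, variance = v,
         ci95 = c(max(0, d$auc - half), min(1, d$auc + half)),
         n_cases = d$m, n_controls = d$n),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_cases, x$n_controls))
  invisible(x)
}

#' DeLong test for two correlated AUCs on the same subjects
#'
#' Paired comparison of two scores measured on the same cases and controls,
#' using the covariance of the DeLong structural components.
#'
#' @param scores_a,scores_b Numeric scores, same subjects in the same order.
#' @param labels Case indicators.
#' @return List with `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("delong_paired_test: score vectors differ in length")
  }
  labels <- .check_labels(labels, length(scores_a))
  da <- .delong_components(scores_a, labels)
  db <- .delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  diff <- da$auc - db$auc
  if (v <= .Machine$double.eps) {
    z <- 0
  } else {
    z <- diff / sqrt(v)
  }
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Ad hoc z-test for two AUCs from unequal samples
#'
#' Compares two AUCs that were not measured on the same subjects, assuming
#' a fixed correlation `rho` (default 0.5) between the estimates:
#' `z = (a1 - a2) / sqrt(v1 + v2 - 2 rho sqrt(v1 v2))`.
#'
#' @param auc_a,auc_b The two AUCs.
#' @param var_a,var_b Their variances (must be > 0).
#' @param rho Assumed correlation.
#' @return List with `z` and two-sided `p`.
#' @export
adhoc_z_unequal <- function(auc_a, var_a, auc_b, var_b, rho = 0.5) {
  if (var_a <= 0 || var_b <= 0) stop("adhoc_z_unequal: variances must be > 0")
  denom2 <- var_a + var_b - 2 * rho * sqrt(var_a * var_b)
  if (denom2 <= 0) stop("adhoc_z_unequal: non-positive variance of the difference")
  z <- (auc_a - auc_b) / sqrt(denom2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' AUC per score per window
#'
#' Computes one [auc_delong()] per (score, window) cell of a windowed score
#' table. Rows whose window predates admission (`in_hospital = FALSE`) are
#' excluded from that window's ROC. A cell where only one class remains is
#' flagged rather than silently dropped.
#'
#' @param scored Long table from [score_windows()]: patient_id, window,
#'   in_hospital, score, total.
#' @param labels Data frame: patient_id, is_case.
#' @return data.table with score, window, n_cases, n_controls, auc,
#'   variance, lo, hi, flagged; plus the paper's qualitative discrimination
#'   tag (`>= 0.70` acceptable, `>= 0.80` excellent).
#' @export
auc_by_window <- function(scored, labels) {
  sc <- data.table::as.data.table(scored)
  lab <- data.table::as.data.table(labels)[, .(patient_id, is_case)]
  sc <- sc[lab, on = "patient_id", nomatch = NULL]
  sc <- sc[in_hospital == TRUE]
  out <- sc[, {
    if (length(unique(is_case)) < 2) {
      list(n_cases = sum(is_case), n_controls = sum(!is_case),
           auc = NA_real_, variance = NA_real_, lo = NA_real_,
           hi = NA_real_, flagged = "single_class")
    } else {
      r <- auc_delong(total, is_case)
      list(n_cases = r$n_cases, n_controls = r$n_controls, auc = r$auc,
           variance = r$variance, lo = r$ci95[1], hi = r$ci95[2],
           flagged = NA_character_)
    }
  }, by = .(score, window)]
  out[, discrimination := ifelse(is.na(auc), NA_character_,
                          ifelse(auc >= 0.80, "excellent",
                          ifelse(auc >= 0.70, "acceptable", "poor")))]
  data.table::setorder(out, score, window)
  out[]
}
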