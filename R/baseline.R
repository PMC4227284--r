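# Baseline characteristics table: per-characteristic summaries for cases
# and controls with the appropriate univariate comparison.

.normal_enough <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) return(FALSE)
  if (length(x) > 500) x <- x[seq(1, length(x), length.out = 500)]
  if (length(unique(x)) < 3) return(FALSE)
  stats::shapiro.test(x)$p.value > 0.05
}

.fisher_p <- function(tab) {
  tryCatch(stats::fisher.test(tab, workspace = 2e7)$p.value,
           error = function(e) stats::chisq.test(tab)$p.value)
}

#' Baseline characteristics of cases and controls
#'
#' Summarizes each characteristic per group - count and percentage of the
#' group for categorical variables, median and IQR for continuous ones -
#' and compares groups with a two-sided Fisher exact test (categorical) or
#' Student t / Wilcoxon rank-sum test (continuous; t when both groups pass
#' a Shapiro-Wilk normality screen at alpha 0.05, Wilcoxon otherwise).
#'
#' @param cases,controls Data frames of patient rows per group.
#' @param continuous Continuous characteristic columns.
#' @param categorical Categorical / logical characteristic columns.
#' @return Data frame: characteristic, level, control and case summaries
#'   (counts, percentages or median/IQR), test used, p value.
#' @export
summarize_baseline <- function(cases, controls,
                               continuous = c("age", "bmi"),
                               categorical = c("sex", "race",
                                               "infection_source",
                                               "severe_sepsis", "pneumonia",
                                               "chf", "diabetes", "copd",
                                               "liver_disease",
                                               "renal_disease", "malignancy",
                                               "metastatic_cancer",
                                               "mi_history", "hiv")) {
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    stop("summarize_baseline: empty group")
  }
  continuous <- intersect(continuous, intersect(names(cases), names(controls)))
  categorical <- intersect(categorical, intersect(names(cases),
                                                  names(controls)))
  rows <- list()
  add <- function(df) rows[[length(rows) + 1]] <<- df

  for (v in continuous) {
    xc <- cases[[v]]; xk <- controls[[v]]
    use_t <- .normal_enough(xc) && .normal_enough(xk)
    p <- if (use_t) stats::t.test(xc, xk)$p.value else
      stats::wilcox.test(xc, xk, exact = FALSE)$p.value
    fmt <- function(x) sprintf("%.0f (%.0f-%.0f)",
                               stats::median(x, na.rm = TRUE),
                               stats::quantile(x, 0.25, na.rm = TRUE),
                               stats::quantile(x, 0.75, na.rm = TRUE))
    add(data.frame(characteristic = v, level = "median (IQR)",
                   controls = fmt(xk), cases = fmt(xc),
                   control_n = NA_real_, case_n = NA_real_,
                   control_pct = NA_real_, case_pct = NA_real_,
                   test = if (use_t) "t" else "wilcoxon", p = p,
                   stringsAsFactors = FALSE))
  }

  for (v in categorical) {
    xc <- cases[[v]]; xk <- controls[[v]]
    if (is.logical(xc)) {
      tab <- rbind(control = c(sum(xk), sum(!xk)),
                   case = c(sum(xc), sum(!xc)))
      p <- .fisher_p(tab)
      add(data.frame(characteristic = v, level = "yes",
                     controls = sprintf("%d (%.0f)", sum(xk),
                                        100 * mean(xk)),
                     cases = sprintf("%d (%.0f)", sum(xc), 100 * mean(xc)),
                     control_n = sum(xk), case_n = sum(xc),
                     control_pct = 100 * mean(xk),
                     case_pct = 100 * mean(xc),
                     test = "fisher", p = p, stringsAsFactors = FALSE))
    } else {
      lev <- sort(unique(c(xc, xk)))
      tab <- rbind(table(factor(xk, lev)), table(factor(xc, lev)))
      p <- .fisher_p(tab)
      for (l in lev) {
        add(data.frame(characteristic = v, level = l,
                       controls = sprintf("%d (%.0f)", sum(xk == l),
                                          100 * mean(xk == l)),
                       cases = sprintf("%d (%.0f)", sum(xc == l),
                                       100 * mean(xc == l)),
                       control_n = sum(xk == l), case_n = sum(xc == l),
                       control_pct = 100 * mean(xk == l),
                       case_pct = 100 * mean(xc == l),
                       test = "fisher", p = p, stringsAsFactors = FALSE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
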