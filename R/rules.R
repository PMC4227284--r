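# Threshold selection and the two-threshold decision rule on the earliest
# score and its change over time, with crude and adjusted odds ratios.

#' Performance of a binary rule against case status
#'
#' Builds the 2x2 table of rule positivity by case status and derives
#' sensitivity, specificity, the Youden index and the crude odds ratio with
#' a Woolf (log-OR) 95% interval. A zero cell triggers the
#' Haldane-Anscombe 0.5 correction for the OR, flagged in the result.
#'
#' @param positive Logical rule indicator per subject.
#' @param labels Case indicators.
#' @return A `rule_performance` list: `counts` (tp, fn, fp, tn),
#'   `sensitivity`, `specificity`, `youden`, `or_crude`, `or_ci95`,
#'   `corrected` (Haldane-Anscombe applied).
#' @export
rule_performance <- function(positive, labels) {
  labels <- .check_labels(labels, length(positive))
  positive <- as.logical(positive)
  tp <- sum(positive & labels); fn <- sum(!positive & labels)
  fp <- sum(positive & !labels); tn <- sum(!positive & !labels)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc["tp"] * cc["tn"]) / (cc["fp"] * cc["fn"])
  se_log <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  structure(
    list(counts = cells, sensitivity = sens, specificity = spec,
         youden = sens + spec - 1, or_crude = unname(or),
         or_ci95 = unname(ci), corrected = corrected),
    class = "rule_performance"
  )
}

#' @export
print.rule_performance <- function(x, ...) {
  cat(sprintf(
    "sens %.1f%%, spec %.1f%%, Youden %.3f, OR %.2f (95%% CI %.2f-%.2f)%s\n",
    100 * x$sensitivity, 100 * x$specificity, x$youden, x$or_crude,
    x$or_ci95[1], x$or_ci95[2],
    if (x$corrected) " [0.5 correction]" else ""))
  invisible(x)
}

#' Youden-optimal single threshold
#'
#' Scans every observed score value as a candidate `score >= t` rule and
#' returns the threshold maximizing the Youden index (sensitivity +
#' specificity - 1); ties go to the lowest threshold.
#'
#' @param scores Numeric scores.
#' @param labels Case indicators.
#' @return List with `threshold`, `youden` and the full
#'   [rule_performance()] at the optimum.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- .check_labels(labels, length(scores))
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pos <- scores >= t
    sum(pos & labels) / sum(labels) + sum(!pos & !labels) / sum(!labels) - 1
  }, 0)
  best <- cand[which.max(j)]  # which.max takes the first (lowest) maximizer
  list(threshold = best, youden = max(j),
       performance = rule_performance(scores >= best, labels))
}

#' Derive the two-threshold rule on earliest score and score change
#'
#' Exhaustive grid search over integer threshold pairs for the rule
#' "positive if earliest score >= theta_base OR delta > theta_delta", where
#' delta is the change from the earliest available in-hospital score to the
#' score nearest the index. The pair maximizing the Youden index is
#' returned; ties resolve to the lexicographically smaller
#' (theta_base, theta_delta). The base grid extends one step past the
#' maximum observed earliest score so the search can switch the base arm
#' off; the delta grid extends one step below the minimum so it can fire
#' always.
#'
#' @param earliest Earliest in-hospital score per subject.
#' @param delta Change in score per subject (nearest-to-index minus
#'   earliest).
#' @param labels Case indicators.
#' @return List with `rule` (theta_base, theta_delta), `youden`, and the
#'   [rule_performance()] at the optimum.
#' @export
derive_delta_rule <- function(earliest, delta, labels) {
  labels <- .check_labels(labels, length(earliest))
  if (length(delta) != length(earliest)) {
    stop("derive_delta_rule: earliest and delta differ in length")
  }
  tb_grid <- seq(floor(min(earliest)), ceiling(max(earliest)) + 1)
  td_grid <- seq(floor(min(delta)) - 1, ceiling(max(delta)))
  if (length(tb_grid) < 1 || length(td_grid) < 1) {
    stop("derive_delta_rule: degenerate threshold grid")
  }
  n_case <- sum(labels); n_ctrl <- sum(!labels)
  best <- NULL
  for (tb in tb_grid) {
    base_pos <- earliest >= tb
    for (td in td_grid) {
      pos <- base_pos | delta > td
      j <- sum(pos & labels) / n_case + sum(!pos & !labels) / n_ctrl - 1
      if (is.null(best) || j > best$youden + 1e-12) {
        best <- list(rule = c(theta_base = tb, theta_delta = td), youden = j)
      }
    }
  }
  pos <- earliest >= best$rule["theta_base"] | delta > best$rule["theta_delta"]
  best$performance <- rule_performance(pos, labels)
  best
}

#' Evaluate a decision rule or single-threshold model
#'
#' Applies one of the three model families to per-subject features and
#' returns its [rule_performance()]: `"earliest"` (earliest score >=
#' threshold), `"peak"` (maximum in-hospital score >= threshold), or
#' `"delta"` (earliest >= theta_base OR delta > theta_delta).
#'
#' @param model `"earliest"`, `"peak"` or `"delta"`.
#' @param features Data frame with columns `earliest`, `peak`, `delta` (per
#'   subject, as from [sofa_model_features()]).
#' @param labels Case indicators.
#' @param threshold Threshold for the single-threshold models.
#' @param rule Named vector (theta_base, theta_delta) for the delta rule.
#' @return A [rule_performance()].
#' @export
evaluate_rule <- function(model, features, labels, threshold = NULL,
                          rule = NULL) {
  model <- match.arg(model, c("earliest", "peak", "delta"))
  pos <- switch(model,
    earliest = features$earliest >= threshold,
    peak = features$peak >= threshold,
    delta = features$earliest >= rule["theta_base"] |
            features$delta > rule["theta_delta"]
  )
  rule_performance(pos, labels)
}

#' Per-subject earliest / peak / delta score features
#'
#' From the windowed totals of one score: `earliest` is the score in the
#' farthest-from-index in-hospital window (the earliest data available in
#' clock time), `current` the score in the window nearest the index,
#' `delta = current - earliest`, and `peak` the maximum over in-hospital
#' windows. Subjects with data in a single window have delta 0 by
#' construction and are classified by the base threshold alone.
#'
#' @param scored Output of [score_windows()] filtered to one score.
#' @param spec The [window_spec()] used.
#' @return data.table: patient_id, earliest, current, delta, peak.
#' @export
sofa_model_features <- function(scored, spec = window_spec()) {
  sc <- data.table::as.data.table(scored)
  if (length(unique(sc$score)) > 1) {
    stop("sofa_model_features: filter to a single score first")
  }
  sc <- sc[in_hospital == TRUE]
  sc[, win_i := match(window, spec$label)]
  sc[, .(earliest = total[which.max(win_i)],
         current = total[which.min(win_i)],
         delta = total[which.min(win_i)] - total[which.max(win_i)],
         peak = max(total)),
     by = patient_id]
}

#' Covariate-adjusted odds ratio for a rule indicator
#'
#' Unconditional logistic regression of case status on the rule indicator
#' plus baseline covariates; the adjusted OR is the exponentiated rule
#' coefficient with a Wald 95% interval. Perfect or quasi-perfect
#' separation raises an error unless `penalized = TRUE`, in which case a
#' Firth bias-reduced fit (Jeffreys-prior score correction) is used.
#'
#' @param indicator Logical rule indicator.
#' @param labels Case indicators.
#' @param covariates Data frame of adjustment covariates (e.g. age, sex,
#'   severe sepsis, pneumonia, congestive heart failure).
#' @param penalized Use the Firth fallback on separation.
#' @return List with `or_adj`, `ci95`, `p`, `method`.
#' @export
adjusted_or <- function(indicator, labels, covariates, penalized = FALSE) {
  labels <- .check_labels(labels, length(indicator))
  if (length(unique(indicator)) < 2) {
    stop("adjusted_or: rule indicator is constant; no estimate")
  }
  df <- data.frame(.y = as.integer(labels), .rule = as.integer(indicator),
                   covariates)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  probs <- stats::fitted(fit)
  separated <- !fit$converged || any(probs > 1 - 1e-8) || any(probs < 1e-8) ||
    abs(stats::coef(fit)[".rule"]) > 15
  if (separated) {
    if (!penalized) {
      stop("adjusted_or: (quasi-)separation detected; refit with ",
           "penalized = TRUE for a Firth bias-reduced estimate")
    }
    X <- stats::model.matrix(.y ~ ., data = df)
    f <- .firth_logistic(X, df$.y)
    i <- match(".rule", colnames(X))
    est <- f$coef[i]; se <- f$se[i]
    method <- "firth"
  } else {
    est <- stats::coef(fit)[".rule"]
    se <- sqrt(stats::vcov(fit)[".rule", ".rule"])
    method <- "glm"
  }
  z <- est / se
  list(or_adj = unname(exp(est)),
       ci95 = unname(exp(est + c(-1, 1) * stats::qnorm(0.975) * se)),
       p = 2 * stats::pnorm(-abs(z)), method = method)
}

# Firth bias-reduced logistic regression (score function corrected by half
# the trace of the hat matrix derivative; standard Newton iterations).
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * w, X)
    inv <- solve(XtWX)
    h <- rowSums((X %*% inv) * (X * w))
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- inv %*% U
    b <- b + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% b)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- sqrt(diag(solve(crossprod(X * w, X))))
  list(coef = stats::setNames(as.vector(b), colnames(X)),
       se = stats::setNames(se, colnames(X)))
}

#' Crude OR implied by a sensitivity/specificity pair in a balanced design
#'
#' In a 1:1 case-control analysis the 2x2 cross-product reduces to
#' `(sens * spec) / ((1 - sens) * (1 - spec))`; useful as an internal
#' consistency check between reported sensitivity/specificity and the
#' reported crude OR.
#'
#' @param sens,spec Proportions in (0, 1).
#' @return The implied odds ratio.
#' @export
implied_or <- function(sens, spec) {
  (sens * spec) / ((1 - sens) * (1 - spec))
}
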