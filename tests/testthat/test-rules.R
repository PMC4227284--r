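# Youden threshold selection, the two-threshold delta rule, rule
# performance arithmetic and adjusted odds ratios.

test_that("Youden scan returns the lowest maximizing threshold", {
  r <- youden_threshold(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r$threshold, 5)
  expect_identical(r$youden, 1)
  same <- youden_threshold(rep(c(1, 2), 10), rep(c(TRUE, FALSE), 10))
  expect_equal(same$youden, 0, tolerance = 1e-12)
})

test_that("Youden scan equals exhaustive enumeration on random datasets", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    scores <- sample(0:12, n, replace = TRUE)
    labels <- runif(n) < 0.5
    if (all(labels) || !any(labels)) next
    r <- youden_threshold(scores, labels)
    cand <- sort(unique(scores))
    best_j <- -Inf; best_t <- NA
    for (t in cand) {
      pos <- scores >= t
      j <- mean(pos[labels]) + mean(!pos[!labels]) - 1
      if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
    }
    expect_identical(r$threshold, best_t)
    expect_equal(r$youden, best_j, tolerance = 1e-12)
  }
})

test_that("the delta rule separates a separable dataset and matches brute force", {
  # all cases rise, all controls do not
  earliest <- c(0, 1, 2, 0, 1, 2)
  delta <- c(2, 1, 3, 0, -1, 0)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- derive_delta_rule(earliest, delta, labels)
  expect_identical(r$youden, 1)
  expect_equal(unname(r$rule["theta_delta"]), 0)
  # base arm must not fire on any control
  expect_true(r$rule["theta_base"] > 2)

  set.seed(13)
  for (i in 1:40) {
    n <- sample(12:60, 1)
    earliest <- sample(0:10, n, replace = TRUE)
    delta <- sample(-4:6, n, replace = TRUE)
    labels <- runif(n) < 0.5
    if (all(labels) || !any(labels)) next
    r <- derive_delta_rule(earliest, delta, labels)
    # independent enumeration over the same integer grid
    best <- c(-Inf, NA, NA)
    for (tb in min(earliest):(max(earliest) + 1)) {
      for (td in (min(delta) - 1):max(delta)) {
        pos <- earliest >= tb | delta > td
        j <- mean(pos[labels]) + mean(!pos[!labels]) - 1
        if (j > best[1] + 1e-12) best <- c(j, tb, td)
      }
    }
    expect_equal(r$youden, best[1], tolerance = 1e-12)
    expect_equal(unname(as.numeric(r$rule)), best[2:3])
  }
})

test_that("rule performance reproduces hand arithmetic on a constructed 2x2 table", {
  pos <- rep(c(TRUE, FALSE, TRUE, FALSE), c(246, 82, 92, 236))
  lab <- rep(c(TRUE, FALSE), c(328, 328))
  perf <- rule_performance(pos, lab)
  expect_identical(unname(perf$counts),
                   c(246L, 82L, 92L, 236L))
  expect_equal(perf$sensitivity, 0.75, tolerance = 1e-12)
  expect_equal(perf$specificity, 236 / 328, tolerance = 1e-12)
  expect_equal(perf$or_crude, (246 * 236) / (92 * 82), tolerance = 1e-12)
  expect_equal(perf$or_crude, 7.70, tolerance = 0.01)
  expect_false(perf$corrected)
})

test_that("degenerate rules and symmetric tables behave as the algebra dictates", {
  lab <- rep(c(TRUE, FALSE), each = 20)
  allpos <- rule_performance(rep(TRUE, 40), lab)
  expect_identical(allpos$sensitivity, 1)
  expect_identical(allpos$specificity, 0)
  expect_true(allpos$corrected)  # zero cells -> Haldane-Anscombe
  # symmetric table TP = TN, FP = FN: OR = (TP/FP)^2
  pos <- rep(c(TRUE, FALSE, TRUE, FALSE), c(15, 5, 5, 15))
  sym <- rule_performance(pos, lab)
  expect_equal(sym$or_crude, (15 / 5)^2, tolerance = 1e-12)
})

test_that("in a balanced design the crude OR equals the sens/spec cross-product identity", {
  set.seed(14)
  for (i in 1:20) {
    n <- 50
    lab <- rep(c(TRUE, FALSE), each = n)
    pos <- runif(2 * n) < ifelse(lab, 0.7, 0.3)
    perf <- rule_performance(pos, lab)
    if (perf$corrected) next
    s <- perf$sensitivity; p <- perf$specificity
    expect_equal(perf$or_crude, implied_or(s, p), tolerance = 1e-10)
  }
})

test_that("model features derive earliest, current, delta and peak from in-hospital windows", {
  scored <- data.table::data.table(
    patient_id = "x", window = c("W1", "W2", "W3", "W4"),
    in_hospital = c(TRUE, TRUE, TRUE, FALSE), score = "SOFA",
    total = c(6L, 4L, 2L, 9L))
  f <- sofa_model_features(scored)
  expect_identical(f$earliest, 2L)  # W3 is the farthest in-hospital window
  expect_identical(f$current, 6L)
  expect_identical(f$delta, 4L)
  expect_identical(f$peak, 6L)     # W4 ignored: predates admission
  # single in-hospital window: delta 0 by construction
  one <- scored[1]
  f1 <- sofa_model_features(one)
  expect_identical(f1$delta, 0L)
})

test_that("evaluate_rule applies the three model families consistently", {
  feats <- data.frame(earliest = c(3, 1, 0, 2), peak = c(5, 2, 1, 2),
                      delta = c(2, 1, 0, -1))
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  pe <- evaluate_rule("earliest", feats, lab, threshold = 1)
  expect_equal(pe$sensitivity, 1)
  pd <- evaluate_rule("delta", feats, lab,
                      rule = c(theta_base = 3, theta_delta = 0))
  expect_equal(pd$sensitivity, 1)
  expect_equal(pd$specificity, 1)
})

test_that("adjusted OR approximates the crude OR when covariates are noise, and recovers known effects", {
  set.seed(15)
  n <- 2000
  rule <- runif(n) < 0.4
  covs <- data.frame(age = rnorm(n, 60, 10), sex = sample(c("f", "m"), n, TRUE))
  beta <- 1.2
  y <- runif(n) < plogis(-1 + beta * rule)
  crude <- rule_performance(rule, y)
  adj <- adjusted_or(rule, y, covs)
  expect_identical(adj$method, "glm")
  expect_gt(adj$or_adj, crude$or_ci95[1])
  expect_lt(adj$or_adj, crude$or_ci95[2])
  # parameter recovery within 2 SE on the log-odds scale
  se <- (log(adj$ci95[2]) - log(adj$ci95[1])) / (2 * qnorm(0.975))
  expect_lt(abs(log(adj$or_adj) - beta), 2 * se)
})

test_that("constant indicators and separation are rejected; the penalized fallback fits", {
  lab <- rep(c(TRUE, FALSE), each = 20)
  covs <- data.frame(age = rnorm(40))
  expect_error(adjusted_or(rep(TRUE, 40), lab, covs), "constant")
  sep <- lab  # indicator identical to outcome: perfect separation
  expect_error(adjusted_or(sep, lab, covs), "separation")
  pen <- adjusted_or(sep, lab, covs, penalized = TRUE)
  expect_identical(pen$method, "firth")
  expect_true(is.finite(pen$or_adj))
  expect_true(all(is.finite(pen$ci95)))
})
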