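# DeLong AUC machinery and the score-by-window discrimination table.

test_that("AUC handles perfect separation, ties, and the hand-counted mixed case", {
  expect_identical(auc_delong(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_identical(auc_delong(rep(5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  # cases {2,3}, controls {1,3}: concordant pairs (2>1) and (3>1), the
  # (3,3) tie counts one half, (2<3) is discordant: (1+0+1+0.5)/4 = 0.625
  r <- auc_delong(c(2, 3, 1, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r$auc, 0.625)
  expect_identical(brute_auc(c(2, 3, 1, 3), c(TRUE, TRUE, FALSE, FALSE)),
                   0.625)
  expect_error(auc_delong(1:4, rep(TRUE, 4)), "single-class")
})

test_that("AUC equals brute-force concordant-pair counting on random datasets", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    scores <- sample(0:15, n, replace = TRUE)
    labels <- runif(n) < 0.4
    if (all(labels) || !any(labels)) next
    expect_equal(auc_delong(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("label reversal maps the AUC to its complement", {
  set.seed(6)
  scores <- rnorm(80)
  labels <- runif(80) < 0.5
  a <- auc_delong(scores, labels)
  b <- auc_delong(scores, !labels)
  expect_equal(a$auc, 1 - b$auc, tolerance = 1e-12)
  expect_equal(a$variance, b$variance, tolerance = 1e-12)
  expect_true(a$ci95[1] <= a$auc && a$auc <= a$ci95[2])
})

test_that("AUC, variance and paired test agree with an independent implementation", {
  set.seed(8)
  for (i in 1:10) {
    n <- 60
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    sa <- rnorm(n, mean = ifelse(labels, 0.8, 0)) + sample(0:2, n, TRUE)
    sb <- 0.5 * sa + rnorm(n)
    ra <- auc_delong(sa, labels)
    roc_a <- pROC::roc(response = labels, predictor = sa, quiet = TRUE,
                       direction = "<")
    expect_equal(ra$auc, as.numeric(pROC::auc(roc_a)), tolerance = 1e-10)
    expect_equal(ra$variance, pROC::var(roc_a, method = "delong"),
                 tolerance = 1e-10)
    roc_b <- pROC::roc(response = labels, predictor = sb, quiet = TRUE,
                       direction = "<")
    ours <- delong_paired_test(sa, sb, labels)
    ref <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
    expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-8)
  }
})

test_that("the paired test is null for identical scores and monotone transforms", {
  set.seed(9)
  s <- rnorm(50)
  labels <- rep(c(TRUE, FALSE), 25)
  same <- delong_paired_test(s, s, labels)
  expect_identical(same$z, 0)
  expect_identical(same$p, 1)
  mono <- delong_paired_test(s, exp(2 * s) + 3, labels)
  expect_identical(mono$z, 0)
  expect_error(delong_paired_test(s, s[-1], labels), "length")
})

test_that("the ad hoc z-test matches its algebra", {
  expect_identical(adhoc_z_unequal(0.7, 0.001, 0.7, 0.002)$z, 0)
  # equal variances v and rho = 0.5: denominator reduces to sqrt(v)
  r <- adhoc_z_unequal(0.78, 4e-4, 0.76, 4e-4)
  expect_equal(r$z, (0.78 - 0.76) / sqrt(4e-4), tolerance = 1e-12)
  expect_equal(r$z, 1.0, tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-1), tolerance = 1e-12)
  expect_error(adhoc_z_unequal(0.7, 0, 0.7, 1e-4), "variances")
})

test_that("DeLong intervals cover the null AUC at close to nominal rate", {
  set.seed(10)
  cover <- logical(400)
  aucs <- numeric(400)
  for (i in seq_along(cover)) {
    scores <- rnorm(100)
    labels <- rep(c(TRUE, FALSE), each = 50)
    r <- auc_delong(scores, labels)
    cover[i] <- r$ci95[1] <= 0.5 && 0.5 <= r$ci95[2]
    aucs[i] <- r$auc
  }
  expect_gt(mean(cover), 0.915)
  expect_lt(mean(cover), 0.985)
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("the window table excludes out-of-hospital windows and flags single-class cells", {
  scored <- data.table::data.table(
    patient_id = rep(c("a", "b", "c", "d"), each = 2),
    window = rep(c("W1", "W2"), 4),
    in_hospital = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    score = "SOFA",
    total = c(5, 4, 6, 9, 1, 0, 2, 9))
  labels <- data.frame(patient_id = c("a", "b", "c", "d"),
                       is_case = c(TRUE, TRUE, FALSE, FALSE))
  tab <- auc_by_window(scored, labels)
  w1 <- tab[tab$window == "W1", ]
  expect_identical(w1$n_cases, 2L)
  expect_identical(w1$auc, 1)
  # W2 keeps only in-hospital rows: one case, one control
  w2 <- tab[tab$window == "W2", ]
  expect_identical(w2$n_cases + w2$n_controls, 2L)
  # single-class cell is flagged, not dropped
  lab1 <- data.frame(patient_id = c("a", "b", "c", "d"),
                     is_case = c(TRUE, TRUE, TRUE, TRUE))
  expect_error(tab1 <- auc_by_window(scored, lab1), NA)
  expect_identical(unique(tab1$flagged), "single_class")
  # label reversal complements every AUC
  labels_rev <- labels
  labels_rev$is_case <- !labels$is_case
  tabr <- auc_by_window(scored, labels_rev)
  expect_equal(tabr$auc, 1 - tab$auc, tolerance = 1e-12)
})
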