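test_that("confusion counts tally with positives called at score >= threshold", {
  cc <- confusion_at_threshold(c(0.9, 0.1), c(1, 0), 0.5)
  expect_identical(cc[c("tp", "fp", "fn", "tn")], list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  cc2 <- confusion_at_threshold(c(0.7, 0.6, 0.4, 0.2), c(1, 0, 1, 0), 0.5)
  expect_identical(cc2[c("tp", "fp", "fn", "tn")], list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  # threshold at/below the minimum score calls everyone positive
  cc3 <- confusion_at_threshold(c(0.7, 0.6, 0.4, 0.2), c(1, 0, 1, 0), 0)
  expect_identical(cc3$fn, 0L)
  expect_identical(cc3$tn, 0L)

  expect_error(confusion_at_threshold(numeric(0), numeric(0), 0.5), "empty")
  expect_error(confusion_at_threshold(1, 2, 0.5), "0/1")
})

test_that("basic measures follow their definitions and mark undefined ones NA", {
  m <- basic_measures(confusion_counts(1, 0, 0, 1))
  expect_equal(m[c("sensitivity", "specificity", "youden")],
               list(sensitivity = 1, specificity = 1, youden = 1))
  m2 <- basic_measures(confusion_counts(1, 1, 1, 1))
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 0.5)
  expect_equal(m2$youden, 0)
  expect_equal(m2$accuracy, 0.5)
  m3 <- basic_measures(confusion_counts(0, 5, 0, 0))
  expect_true(is.na(m3$sensitivity))  # no positive patients
  expect_true(is.na(m3$npv))          # nobody called negative
  expect_equal(m3$specificity, 0)
  expect_error(confusion_counts(-1, 0, 0, 2), "nonnegative")
})

test_that("AUC equals the tie-corrected pair count and is transform invariant", {
  expect_equal(roc_curve_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_curve_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  set.seed(53)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties guaranteed
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_curve_auc(scores, labels)
    expect_equal(r$auc, auc_pair_oracle(scores, labels), tolerance = 1e-12)
    # strictly increasing transform leaves the AUC unchanged
    expect_equal(roc_curve_auc(exp(3 * scores), labels)$auc, r$auc,
                 tolerance = 1e-12)
    expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  }
  expect_error(roc_curve_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC and DeLong interval agree with the pROC reference", {
  set.seed(59)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- rep(c(1, 0), c(40, 60))
  r <- roc_curve_auc(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(r$ci95, ci[c(1, 3)], tolerance = 1e-6)
})

test_that("ROC points trace a monotone curve from (0,0) to (1,1)", {
  set.seed(61)
  r <- roc_curve_auc(runif(80), rbinom(80, 1, 0.4))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(unlist(r$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
})

test_that("Youden cut-point maximizes sensitivity + specificity - 1", {
  out <- youden_optimal_cutpoint(c(0.7, 0.6, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(out$measures$youden, 0.5)

  sep <- youden_optimal_cutpoint(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$measures$youden, 1)
  expect_true(sep$threshold > 0.2 && sep$threshold <= 0.8)

  # agreement with exhaustive search over every observed score as threshold
  set.seed(67)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    s <- round(runif(n), 2)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    best <- youden_optimal_cutpoint(s, l)
    brute <- max(vapply(c(s, -Inf, Inf), function(t) {
      basic_measures(confusion_at_threshold(s, l, t))$youden
    }, numeric(1)))
    expect_equal(best$measures$youden, brute, tolerance = 1e-12)
  }

  # uninformative scores at large n: optimal Youden stays small
  set.seed(71)
  expect_lt(youden_optimal_cutpoint(runif(2000), rbinom(2000, 1, 0.5))$measures$youden,
            0.1)
})

test_that("Brier score handles perfect, constant and weighted forecasts", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 7), rbinom(7, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.3), c(1, 0), weights = c(1, 3)), 0.0775)
  p <- runif(20); o <- rbinom(20, 1, 0.5)
  expect_identical(brier_score(p, o, weights = rep(2.7, 20)), brier_score(p, o))
  expect_error(brier_score(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
  expect_error(brier_score(p, o, weights = rep(0, 20)), "zero")
})
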