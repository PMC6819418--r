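# Model kinds the split-validation loop knows how to refit per repetition.
.fit_by_kind <- function(kind, cohort) {
  switch(kind,
         "linear" = ,
         "linear-regression" = fit_linear_dose_model(cohort),
         "main-effect" = ,
         "logistic-main-effect" = fit_logistic_main_effect(cohort),
         "interaction" = ,
         "logistic-interaction" = fit_logistic_interaction(cohort),
         "bmi" = ,
         "a_heart" = ,
         "d_median" = ,
         "ptv" = fit_univariate_logistic(cohort, kind),
         stop("unknown model_kind: ", kind))
}

#' Repeated random-split internal validation
#'
#' Because metrics computed on the data that built the model are overly
#' optimistic, the cohort is repeatedly split at random into a training
#' fraction (default 70%) and a held-out test fraction; the chosen model is
#' refitted on each training split and its position decisions scored on the
#' held-out patients. Beyond the error rates, the `|dose difference|` of
#' every misclassified held-out patient is pooled across repetitions, since
#' a misclassification near 0 Gy costs little while one at several Gy is
#' clinically expensive.
#'
#' Training splits that contain a single outcome class (possible for the
#' logistic kinds in small cohorts) are redrawn, with the number of redraws
#' reported.
#'
#' @param cohort A labelled [position_cohort][as_cohort].
#' @param model_kind One of `"linear"` (default), `"main-effect"`,
#'   `"interaction"`, or a single predictor name (`"bmi"`, `"a_heart"`,
#'   `"d_median"`, `"ptv"`) for a univariate logistic model.
#' @param train_frac Training fraction in (0, 1); test size is
#'   `round((1 - train_frac) * n)`.
#' @param n_reps Number of random splits, default 1000.
#' @param seed Integer seed.
#' @return An object of class `split_validation`: list with `n_reps`,
#'   per-repetition vectors `sensitivity`, `specificity`, `accuracy`, pooled
#'   `misclassified_doses` (Gy), pooled-count aggregates (`pooled`), mean
#'   aggregates (`means`), and `n_redraws`.
#' @export
repeated_split_validation <- function(cohort, model_kind = "linear",
                                      train_frac = 0.7, n_reps = 1000,
                                      seed = NULL) {
  stopifnot(inherits(cohort, "position_cohort"))
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  n_reps <- as.integer(n_reps)
  n <- nrow(cohort)
  n_test <- round((1 - train_frac) * n)
  if (n_test < 1L || n - n_test < 2L) stop("cohort too small for this split")
  .fit_by_kind(model_kind, cohort)  # fail fast on unknown kind
  if (!is.null(seed)) set.seed(seed)

  sens <- spec <- acc <- numeric(n_reps)
  pooled <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  miss_doses <- vector("list", n_reps)
  needs_two_classes <- model_kind != "linear" && model_kind != "linear-regression"
  n_redraws <- 0L

  for (rep in seq_len(n_reps)) {
    repeat {
      test_idx <- sample.int(n, n_test)
      train <- cohort[-test_idx, , drop = FALSE]
      class(train) <- class(cohort)
      if (!needs_two_classes || length(unique(train$label)) == 2L) break
      n_redraws <- n_redraws + 1L
    }
    test <- cohort[test_idx, , drop = FALSE]
    class(test) <- class(cohort)
    model <- .fit_by_kind(model_kind, train)
    decision <- predict(model, test)$decision
    lab <- test$label
    tp <- sum(decision == 1 & lab == 1); fp <- sum(decision == 1 & lab == 0)
    fn <- sum(decision == 0 & lab == 1); tn <- sum(decision == 0 & lab == 0)
    pooled <- pooled + c(tp = tp, fp = fp, fn = fn, tn = tn)
    sens[rep] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[rep] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    acc[rep] <- (tp + tn) / n_test
    miss_doses[[rep]] <- abs(test$dose_diff[decision != lab])
  }

  misclassified_doses <- unlist(miss_doses, use.names = FALSE)
  structure(list(
    n_reps = n_reps, model_kind = model_kind, train_frac = train_frac,
    sensitivity = sens, specificity = spec, accuracy = acc,
    misclassified_doses = misclassified_doses,
    means = list(sensitivity = mean(sens, na.rm = TRUE),
                 specificity = mean(spec, na.rm = TRUE),
                 accuracy = mean(acc)),
    pooled = list(counts = as.list(pooled),
                  sensitivity = pooled["tp"] / (pooled["tp"] + pooled["fn"]),
                  specificity = pooled["tn"] / (pooled["tn"] + pooled["fp"]),
                  accuracy = (pooled["tp"] + pooled["tn"]) / sum(pooled)),
    n_redraws = n_redraws
  ), class = "split_validation")
}

#' @export
print.split_validation <- function(x, ...) {
  cat(sprintf("<split_validation> %s model, %d reps at %.0f/%.0f split\n",
              x$model_kind, x$n_reps, 100 * x$train_frac, 100 * (1 - x$train_frac)))
  cat(sprintf("  mean sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$means$sensitivity, x$means$specificity, x$means$accuracy))
  cat(sprintf("  %d misclassified held-out patients pooled; %d split redraws\n",
              length(x$misclassified_doses), x$n_redraws))
  invisible(x)
}

#' Summary statistics of the misclassified dose
#'
#' Descriptive statistics of the pooled `|dose difference|` of misclassified
#' held-out patients from [repeated_split_validation()] — the dose cost a
#' bare error rate hides. An empty pool (no misclassifications) yields `NA`s.
#'
#' @param s A `split_validation` object.
#' @return Named list: `mean`, `median`, `p90` (Gy).
#' @export
misclassified_dose_summary <- function(s) {
  stopifnot(inherits(s, "split_validation"))
  d <- s$misclassified_doses
  if (length(d) == 0L) {
    return(list(mean = NA_real_, median = NA_real_, p90 = NA_real_))
  }
  list(mean = mean(d), median = stats::median(d),
       p90 = unname(stats::quantile(d, 0.90, type = 7)))
}

#' Evaluate a frozen model on an external cohort
#'
#' Applies an already-fitted model, without refitting, to an independent
#' cohort carrying the model's covariates and gold-standard labels, and
#' reports the confusion counts and accuracy.
#'
#' @param model A `position_model`.
#' @param external_cohort A labelled [position_cohort][as_cohort].
#' @return List with `counts` ([confusion_counts]), `accuracy` and
#'   `measures` (from [basic_measures()]).
#' @export
external_evaluation <- function(model, external_cohort) {
  stopifnot(inherits(model, "position_model"),
            inherits(external_cohort, "position_cohort"))
  if (nrow(external_cohort) == 0L) stop("external cohort is empty")
  decision <- predict(model, external_cohort)$decision
  lab <- external_cohort$label
  cc <- confusion_counts(tp = sum(decision == 1 & lab == 1),
                         fp = sum(decision == 1 & lab == 0),
                         fn = sum(decision == 0 & lab == 1),
                         tn = sum(decision == 0 & lab == 0))
  m <- basic_measures(cc)
  list(counts = cc, accuracy = m$accuracy, measures = m)
}
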