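#' Peirce benefit of a classification
#'
#' The utility of a classification rule per patient: the profit of each true
#' positive minus the loss of each false positive, averaged over the cohort,
#' `B = (profit * TP - loss * FP) / N`. Net benefit is this quantity
#' normalized by the profit, with the loss-to-profit ratio set to the odds of
#' the threshold probability.
#'
#' @param counts A [confusion_counts] object.
#' @param profit Utility of a true positive decision.
#' @param loss Disutility of a false positive decision.
#' @return Scalar benefit.
#' @seealso [net_benefit()]
#' @export
benefit_peirce <- function(counts, profit, loss) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  (profit * counts$tp - loss * counts$fp) / n
}

#' Net benefit at a threshold probability
#'
#' `NB = TP/N - (p_t / (1 - p_t)) * FP/N`: the true-positive rate offset by
#' the false-positive rate weighted by the odds of the threshold probability
#' `p_t`. The odds encode the assumed loss-to-profit ratio of a false versus
#' true positive call, which is precisely the probability cut at which a
#' patient would be indifferent. Defined for `0 <= p_t < 1`; at `p_t = 1`
#' the odds diverge.
#'
#' @param counts A [confusion_counts] object.
#' @param p_t Threshold probability (vectorized), each in `[0, 1)`.
#' @return Numeric vector of net benefit values, one per `p_t`.
#' @export
net_benefit <- function(counts, p_t) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (any(p_t < 0 | p_t >= 1)) {
    stop("p_t must lie in [0, 1); odds are undefined at p_t = 1")
  }
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  counts$tp / n - (p_t / (1 - p_t)) * counts$fp / n
}

# net benefit straight from decisions + labels (no counts object), vectorized
# over the p_t grid; used by decision_curve and the bootstrap.
.nb_from_calls <- function(call_pos, labels, p_t) {
  n <- length(labels)
  tp <- sum(call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0)
  tp / n - (p_t / (1 - p_t)) * fp / n
}

#' Decision curves for one or more models
#'
#' Computes the net benefit of each model over a grid of threshold
#' probabilities, alongside the two reference strategies: treat-all (send
#' every patient to the supine-preferred pathway) and treat-none (net
#' benefit identically zero). For logistic-kind models a patient is called
#' positive at grid point `p_t` iff the predicted probability is at least
#' `p_t`. The linear dose model classifies by the fixed sign rule, so its
#' calls do not change along the grid and its curve varies only through the
#' odds weighting of false positives; this renders the model exactly as its
#' published decision rule behaves. Pass the model through
#' [calibrate_linear_model()] first to place it on the probability axis
#' like the logistic candidates.
#'
#' @param models A named list of `position_model` objects (a bare model is
#'   accepted and wrapped).
#' @param cohort A labelled [position_cohort][as_cohort].
#' @param grid Increasing vector of threshold probabilities in `(0, 1)`;
#'   default `seq(0.01, 0.99, by = 0.01)`.
#' @return A data frame of class `decision_curve` with columns `p_t`, one
#'   net-benefit column per model, `treat_all` and `treat_none`.
#' @export
decision_curve <- function(models, cohort, grid = seq(0.01, 0.99, by = 0.01)) {
  if (inherits(models, "position_model")) {
    models <- stats::setNames(list(models), models$kind)
  }
  stopifnot(inherits(cohort, "position_cohort"))
  if (length(grid) == 0L) stop("empty threshold grid")
  if (any(grid <= 0 | grid >= 1)) stop("grid must lie strictly inside (0, 1)")
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("models must be a named list")
  }
  labels <- cohort$label
  n <- length(labels)
  prev <- mean(labels == 1)

  out <- data.frame(p_t = grid)
  for (nm in names(models)) {
    model <- models[[nm]]
    pred <- predict(model, cohort)
    if (model$kind == "linear-regression") {
      call_pos <- pred$decision == 1
      out[[nm]] <- .nb_from_calls(call_pos, labels, grid)
    } else {
      out[[nm]] <- vapply(grid, function(pt) {
        .nb_from_calls(pred$prediction >= pt, labels, pt)
      }, numeric(1))
    }
  }
  out$treat_all <- prev - (grid / (1 - grid)) * (1 - prev)
  out$treat_none <- 0
  attr(out, "prevalence") <- prev
  attr(out, "model_names") <- names(models)
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' Recalibrate the linear dose model onto the probability axis
#'
#' Optional interpretation layer: fits a univariate logistic regression of
#' the position label on the linear model's predicted dose difference, so
#' the linear model can be thresholded along the decision-curve grid like
#' the logistic candidates instead of acting as a fixed sign-rule
#' classifier.
#'
#' @param model A `position_model` of kind `"linear-regression"`.
#' @param cohort The labelled cohort to calibrate on.
#' @return A `position_model` of kind `"calibrated-linear"`;
#'   [predict.position_model()] composes the stored linear model with the
#'   logistic link, so new data only need the original anatomy covariates.
#' @export
calibrate_linear_model <- function(model, cohort) {
  stopifnot(inherits(model, "position_model"),
            model$kind == "linear-regression")
  pred <- predict(model, cohort)$prediction
  aug <- cohort
  aug$.linear_prediction <- pred
  fit <- fit_univariate_logistic(aug, ".linear_prediction")
  fit$base_model <- model
  fit$kind <- "calibrated-linear"
  fit
}

#' Bootstrap percentile confidence bands for net benefit
#'
#' The model is fitted once on the full cohort and held fixed; bootstrap
#' resamples of (predicted probability, label) pairs — with replacement,
#' of size `size` (default the cohort size) — recompute the net benefit by
#' definition at every grid point, and the 2.5th and 97.5th empirical
#' percentiles (type-7, linear interpolation) form the band. Set
#' `refit = TRUE` to refit the model on each resample instead, which widens
#' the band by the model-fitting variability.
#'
#' @inheritParams decision_curve
#' @param model A single `position_model`.
#' @param n_boot Number of bootstrap resamples (>= 2), default 1000.
#' @param seed Integer seed for reproducibility.
#' @param size Resample size; defaults to `nrow(cohort)`.
#' @param refit Refit the model on every resample (default `FALSE`).
#' @param conf_level Band coverage, default 0.95.
#' @return Data frame with columns `p_t`, `nb` (full-cohort point estimate),
#'   `lower`, `upper`.
#' @export
bootstrap_nb_ci <- function(model, cohort, grid = seq(0.01, 0.99, by = 0.01),
                            n_boot = 1000, seed = NULL, size = NULL,
                            refit = FALSE, conf_level = 0.95) {
  stopifnot(inherits(model, "position_model"), inherits(cohort, "position_cohort"))
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (any(grid <= 0 | grid >= 1)) stop("grid must lie strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  if (is.null(size)) size <- n
  labels <- cohort$label
  alpha <- (1 - conf_level) / 2

  refit_fun <- if (refit) {
    switch(model$kind,
           "linear-regression" = fit_linear_dose_model,
           "logistic-main-effect" = fit_logistic_main_effect,
           "logistic-interaction" = fit_logistic_interaction,
           "univariate-logistic" = function(co) fit_univariate_logistic(co, model$terms),
           stop("refit not supported for kind ", model$kind))
  } else {
    NULL
  }

  pred <- predict(model, cohort)
  point <- if (model$kind == "linear-regression") {
    .nb_from_calls(pred$decision == 1, labels, grid)
  } else {
    vapply(grid, function(pt) .nb_from_calls(pred$prediction >= pt, labels, pt),
           numeric(1))
  }

  nb_mat <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, size, replace = TRUE)
    lab_b <- labels[idx]
    if (refit) {
      co_b <- cohort[idx, , drop = FALSE]
      class(co_b) <- class(cohort)
      model_b <- tryCatch(refit_fun(co_b), error = function(e) model)
      pred_b <- predict(model_b, co_b)
    } else {
      pred_b <- pred[idx, , drop = FALSE]
    }
    nb_mat[b, ] <- if (model$kind == "linear-regression") {
      .nb_from_calls(pred_b$decision == 1, lab_b, grid)
    } else {
      vapply(grid, function(pt) .nb_from_calls(pred_b$prediction >= pt, lab_b, pt),
             numeric(1))
    }
  }
  data.frame(p_t = grid, nb = point,
             lower = apply(nb_mat, 2, stats::quantile, probs = alpha, type = 7),
             upper = apply(nb_mat, 2, stats::quantile, probs = 1 - alpha, type = 7))
}

#' Plot a decision curve
#'
#' Base-graphics rendering of a [decision_curve()]: one net-benefit series
#' per model plus the treat-all and treat-none references against threshold
#' probability.
#'
#' @param x A `decision_curve`.
#' @param ylim Vertical limits; defaults to a sensible window around the
#'   curves.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.decision_curve <- function(x, ylim = NULL, ...) {
  model_names <- attr(x, "model_names")
  series <- c(model_names, "treat_all", "treat_none")
  y <- as.matrix(as.data.frame(x)[series])
  if (is.null(ylim)) ylim <- c(min(-0.05, min(y)), max(y) * 1.05)
  cols <- c(seq_along(model_names) + 1, 1, 1)
  ltys <- c(rep(1, length(model_names)), 2, 3)
  graphics::matplot(x$p_t, y, type = "l", lty = ltys, col = cols, lwd = 2,
                    xlab = "Threshold probability", ylab = "Net benefit",
                    ylim = ylim, ...)
  graphics::legend("topright", legend = series, col = cols, lty = ltys,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
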