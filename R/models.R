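#' Hierarchical clustering of candidate predictors
#'
#' Explores multicollinearity before model building: predictors are clustered
#' agglomeratively with distance `1 - |r|`, where `r` is the pairwise Pearson
#' correlation, using average linkage. Strongly correlated predictors
#' (regardless of sign) merge early; the analyst picks poorly correlated ones
#' for a parsimonious model.
#'
#' @param cohort A [position_cohort][as_cohort].
#' @param predictors Character vector (length >= 2) of cohort column names.
#' @return An object of class `predictor_clustering`: a list with
#'   `dendrogram` (an [stats::hclust] merge history) and `similarity` (the
#'   Pearson correlation matrix).
#' @export
cluster_predictors <- function(cohort,
                               predictors = c("bmi", "a_heart", "d_median", "ptv")) {
  stopifnot(inherits(cohort, "position_cohort"))
  if (length(predictors) < 2L) stop("need at least 2 predictors")
  if (nrow(cohort) < 3L) stop("need at least 3 patients")
  missing_cols <- setdiff(predictors, names(cohort))
  if (length(missing_cols)) {
    stop("predictor(s) not in cohort: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(cohort)[predictors])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance predictor(s): ",
         paste(predictors[sds == 0], collapse = ", "))
  }
  r <- stats::cor(x)
  d <- stats::as.dist(1 - abs(r))
  structure(list(dendrogram = stats::hclust(d, method = "average"),
                 similarity = r),
            class = "predictor_clustering")
}

#' @export
print.predictor_clustering <- function(x, ...) {
  cat("<predictor_clustering> distance 1 - |Pearson r|, average linkage\n")
  print(round(x$similarity, 3))
  invisible(x)
}

# ---- internal model machinery -------------------------------------------

# A term is a covariate name or a product "a:b"; builds the corresponding
# design columns (no intercept) from a data frame.
.term_matrix <- function(terms, data) {
  if (length(terms) == 0L) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    absent <- setdiff(parts, names(data))
    if (length(absent)) {
      stop("missing covariate(s) for term '", tm, "': ",
           paste(absent, collapse = ", "))
    }
    v <- Reduce(`*`, lapply(parts, function(p) data[[p]]))
    if (any(!is.finite(v))) {
      stop("non-finite covariate value in term '", tm, "' at row(s): ",
           paste(which(!is.finite(v)), collapse = ", "))
    }
    v
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

.check_two_classes <- function(label) {
  if (length(unique(label)) < 2L) {
    stop("cohort contains a single outcome class; logistic fit undefined")
  }
}

# Cap for (quasi-)separated logistic fits: if any coefficient exceeds 15 on
# the standardized (per-SD) scale, shrink the slopes to the cap and re-fit the
# intercept at fixed slopes, keeping probabilities bounded away from 0/1 so
# resampling loops survive.
.cap_logistic <- function(coefs, X, y, cap = 15) {
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  std <- coefs[-1] * sds
  if (!any(!is.finite(std)) && max(abs(std)) <= cap) {
    return(list(coefficients = coefs, separation = FALSE))
  }
  std[!is.finite(std)] <- sign(std[!is.finite(std)]) * cap
  scale <- cap / max(abs(std))
  slopes <- (std * scale) / sds
  eta0 <- as.vector(X %*% slopes)
  nll <- function(b0) -sum(stats::dbinom(y, 1, stats::plogis(b0 + eta0), log = TRUE))
  b0 <- stats::optimize(nll, interval = c(-50, 50))$minimum
  list(coefficients = c(`(Intercept)` = b0, slopes), separation = TRUE)
}

.fit_logistic_terms <- function(cohort, terms, kind) {
  stopifnot(inherits(cohort, "position_cohort"))
  .check_two_classes(cohort$label)
  X <- .term_matrix(terms, cohort)
  if (ncol(X) > 0) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance term(s): ", paste(terms[sds == 0], collapse = ", "))
    }
  }
  df <- data.frame(.y = cohort$label, X, check.names = FALSE)
  fml <- if (length(terms)) {
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + ")))
  } else {
    .y ~ 1
  }
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", terms)[seq_along(coefs)]
  ses <- summary(fit)$coefficients[, "Std. Error"]
  names(ses) <- names(coefs)
  capped <- if (length(terms)) {
    .cap_logistic(coefs, X, cohort$label)
  } else {
    list(coefficients = coefs, separation = FALSE)
  }
  structure(list(kind = kind, terms = terms,
                 coefficients = capped$coefficients,
                 se = ses,
                 decision_rule = "positive (supine) if predicted probability >= threshold",
                 threshold = 0.5,
                 separation = capped$separation,
                 deviance = fit$deviance,
                 converged = fit$converged,
                 n = nrow(cohort)),
            class = "position_model")
}

# ---- exported fits -------------------------------------------------------

#' Univariate logistic probability model for one predictor
#'
#' Maximum-likelihood logistic regression of the preferred-position label on
#' a single covariate, used to turn each candidate predictor into a
#' probability prediction whose discrimination (AUC) and calibration (Brier
#' score) can be compared with the multivariate models. Complete or
#' quasi-complete separation is flagged and the standardized slope capped at
#' 15 rather than allowed to diverge.
#'
#' @param cohort A labelled [position_cohort][as_cohort].
#' @param predictor Name of the cohort column to use.
#' @return A `position_model` of kind `"univariate-logistic"`.
#' @export
fit_univariate_logistic <- function(cohort, predictor) {
  stopifnot(length(predictor) == 1L)
  .fit_logistic_terms(cohort, predictor, "univariate-logistic")
}

#' Main-effect multivariate logistic model
#'
#' Logistic regression of the preferred-position label on the three strongest
#' anatomical predictors: in-field heart area, BMI and the median
#' LAD-chest-wall distance. This is the additive ("main effect") candidate
#' model that backward likelihood-ratio selection arrives at on data with
#' this structure.
#'
#' @inheritParams fit_univariate_logistic
#' @return A `position_model` of kind `"logistic-main-effect"`.
#' @export
fit_logistic_main_effect <- function(cohort) {
  .fit_logistic_terms(cohort, c("a_heart", "bmi", "d_median"),
                      "logistic-main-effect")
}

#' Interaction-only multivariate logistic model
#'
#' Logistic regression with exactly two product terms, `a_heart * bmi` and
#' `a_heart * d_median`, plus an intercept and no main effects — the
#' non-hierarchical candidate that forward likelihood-ratio selection can
#' produce when interactions are on the candidate list.
#'
#' @inheritParams fit_univariate_logistic
#' @return A `position_model` of kind `"logistic-interaction"`.
#' @export
fit_logistic_interaction <- function(cohort) {
  .fit_logistic_terms(cohort, c("a_heart:bmi", "a_heart:d_median"),
                      "logistic-interaction")
}

#' Stepwise logistic model selection by likelihood-ratio tests
#'
#' SPSS-style forward or backward selection. Forward starts from the
#' intercept-only model and at each step adds the candidate term with the
#' smallest likelihood-ratio chi-square p-value, as long as it is below
#' `p_enter`. Backward starts from the full candidate model and repeatedly
#' removes the term with the largest p-value above `p_remove`. Each LR test
#' compares deviances of nested fits on one degree of freedom. Steps whose
#' fit fails to converge are skipped and logged.
#'
#' @inheritParams fit_univariate_logistic
#' @param candidate_terms Character vector of candidate terms; products such
#'   as `"a_heart:bmi"` are allowed.
#' @param direction `"forward"` or `"backward"`.
#' @param p_enter Entry p-value threshold (forward), default 0.05.
#' @param p_remove Removal p-value threshold (backward), default 0.10.
#' @return A `position_model` of kind `"stepwise-logistic"` with a
#'   `step_log` data frame recording every step.
#' @export
stepwise_logistic <- function(cohort, candidate_terms,
                              direction = c("forward", "backward"),
                              p_enter = 0.05, p_remove = 0.10) {
  direction <- match.arg(direction)
  if (length(candidate_terms) == 0L) stop("candidate_terms must be nonempty")
  stopifnot(inherits(cohort, "position_cohort"))
  .check_two_classes(cohort$label)

  dev_of <- function(terms) {
    fit <- tryCatch(.fit_logistic_terms(cohort, terms, "stepwise-logistic"),
                    error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) return(NULL)
    fit
  }

  log_rows <- list()
  add_log <- function(step, action, term, p, dev) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      step = step, action = action, term = term,
      p_value = p, deviance = dev, stringsAsFactors = FALSE)
  }

  current <- if (direction == "forward") character(0) else candidate_terms
  fit_cur <- dev_of(current)
  if (is.null(fit_cur)) stop("initial model failed to converge")
  step <- 0L

  repeat {
    step <- step + 1L
    if (direction == "forward") {
      pool <- setdiff(candidate_terms, current)
      if (!length(pool)) break
      pvals <- vapply(pool, function(tm) {
        fit_new <- dev_of(c(current, tm))
        if (is.null(fit_new)) {
          add_log(step, "skip-nonconvergent", tm, NA_real_, NA_real_)
          return(NA_real_)
        }
        stats::pchisq(fit_cur$deviance - fit_new$deviance, df = 1,
                      lower.tail = FALSE)
      }, numeric(1))
      if (all(is.na(pvals))) break
      best <- which.min(pvals)
      if (pvals[best] >= p_enter) break
      current <- c(current, pool[best])
      fit_cur <- dev_of(current)
      add_log(step, "add", pool[best], pvals[best], fit_cur$deviance)
    } else {
      if (!length(current)) break
      pvals <- vapply(current, function(tm) {
        fit_new <- dev_of(setdiff(current, tm))
        if (is.null(fit_new)) {
          add_log(step, "skip-nonconvergent", tm, NA_real_, NA_real_)
          return(NA_real_)
        }
        stats::pchisq(fit_new$deviance - fit_cur$deviance, df = 1,
                      lower.tail = FALSE)
      }, numeric(1))
      if (all(is.na(pvals))) break
      worst <- which.max(pvals)
      if (pvals[worst] <= p_remove) break
      current <- setdiff(current, current[worst])
      fit_cur <- dev_of(current)
      add_log(step, "remove", names(pvals)[worst], pvals[worst], fit_cur$deviance)
    }
  }

  out <- fit_cur
  out$kind <- "stepwise-logistic"
  out$direction <- direction
  out$step_log <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(step = integer(0), action = character(0), term = character(0),
               p_value = numeric(0), deviance = numeric(0))
  }
  out
}

#' Linear regression model for the dose difference
#'
#' Ordinary least squares fit of the continuous LAD mean dose difference on
#' in-field heart area, BMI and median LAD-chest-wall distance. Unlike the
#' logistic candidates this model predicts the dose difference itself (in
#' Gy); the position decision is the sign of the prediction, so large dose
#' differences weigh more in fitting than bare misclassification would.
#'
#' @inheritParams fit_univariate_logistic
#' @return A `position_model` of kind `"linear-regression"`.
#' @export
fit_linear_dose_model <- function(cohort) {
  stopifnot(inherits(cohort, "position_cohort"))
  terms <- c("a_heart", "bmi", "d_median")
  X <- .term_matrix(terms, cohort)
  if (nrow(X) < length(terms) + 2L) stop("cohort too small for OLS fit")
  df <- data.frame(.y = cohort$dose_diff, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(terms) + 1L) stop("design matrix is rank deficient")
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", terms)
  ses <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  names(ses) <- names(coefs)
  structure(list(kind = "linear-regression", terms = terms,
                 coefficients = coefs,
                 se = ses,
                 decision_rule = "sign of predicted dose difference",
                 threshold = NA_real_,
                 separation = FALSE,
                 sigma = suppressWarnings(summary(fit))$sigma,
                 n = nrow(cohort)),
            class = "position_model")
}

#' Predict positions for new patients
#'
#' For logistic-kind models, returns the predicted probability that the
#' supine position is preferred (label 1) and the binary decision
#' `probability >= threshold` (default threshold 0.5). For the linear model,
#' returns the predicted LAD mean dose difference in Gy and applies the sign
#' rule: a positive predicted difference means prone is preferred (decision
#' 0); a negative one means supine (decision 1); an exact zero falls to
#' prone, mirroring the gold-standard tie rule.
#'
#' @param object A `position_model`.
#' @param newdata A data frame (or cohort) carrying the model's covariates.
#' @param threshold Probability cut for logistic decisions; defaults to the
#'   model's stored threshold (0.5).
#' @param ... Unused.
#' @return A data frame with columns `prediction` (probability or Gy) and
#'   integer `decision` (1 = supine, 0 = prone).
#' @export
predict.position_model <- function(object, newdata, threshold = object$threshold, ...) {
  if (identical(object$kind, "calibrated-linear")) {
    newdata <- as.data.frame(newdata)
    newdata$.linear_prediction <- predict(object$base_model, newdata)$prediction
  }
  X <- .term_matrix(object$terms, newdata)
  eta <- object$coefficients[1] +
    (if (ncol(X)) as.vector(X %*% object$coefficients[-1]) else 0)
  if (object$kind == "linear-regression") {
    data.frame(prediction = eta, decision = gold_standard_label(eta))
  } else {
    p <- stats::plogis(eta)
    data.frame(prediction = p, decision = as.integer(p >= threshold))
  }
}

#' @export
print.position_model <- function(x, ...) {
  cat(sprintf("<position_model> kind: %s\n", x$kind))
  cat("  decision rule:", x$decision_rule, "\n")
  if (isTRUE(x$separation)) cat("  NOTE: separation detected; slopes capped\n")
  print(round(x$coefficients, 5))
  invisible(x)
}
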