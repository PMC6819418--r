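test_that("predictor clustering merges correlated predictors first", {
  set.seed(17)
  n <- 2000
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  x3 <- x1 + rnorm(n, sd = 0.05)
  co <- make_label_cohort(rbinom(n, 1, 0.5),
                          extra = list(x1 = x1, x2 = x2, x3 = x3))

  # duplicate columns merge at distance 0
  cl_dup <- cluster_predictors(transform(co, x4 = x1) |> as_cohort(),
                               c("x1", "x4"))
  expect_equal(min(cl_dup$dendrogram$height), 0, tolerance = 1e-12)

  # near-duplicates merge before the independent column joins
  cl <- cluster_predictors(co, c("x1", "x2", "x3"))
  first <- cl$dendrogram$merge[1, ]
  expect_setequal(abs(first), c(1, 3))  # x1 and x3

  # independent columns merge at distance near 1
  cl_ind <- cluster_predictors(co, c("x1", "x2"))
  expect_gt(max(cl_ind$dendrogram$height), 0.9)

  expect_error(cluster_predictors(transform(co, z = 1) |> as_cohort(),
                                  c("x1", "z")), "zero-variance")
})

test_that("univariate logistic MLE matches brute-force likelihood maximization", {
  nll <- function(b, x, y) -sum(dbinom(y, 1, plogis(b[1] + b[2] * x), log = TRUE))
  set.seed(23)
  checked <- 0L
  for (case in 1:20) {
    n <- sample(6:12, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.5 * x))
    if (length(unique(y)) < 2) next
    co <- make_label_cohort(y, extra = list(x = x))
    fit <- fit_univariate_logistic(co, "x")
    # near-separated draws sit on a likelihood plateau; the comparison is
    # only informative on well-conditioned fits
    if (fit$separation || max(abs(fit$coefficients)) > 5) next
    oracle <- optim(c(0, 0), nll, x = x, y = y, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 2000))
    expect_equal(unname(fit$coefficients), oracle$par, tolerance = 5e-4)
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
})

test_that("logistic score equations are satisfied at the reported optimum", {
  co <- generate_cohort(default_calibrated_config(n = 800, seed = 31))
  m <- fit_logistic_main_effect(co)
  X <- cbind(1, scale(as.matrix(as.data.frame(co)[m$terms])))
  # refit on standardized columns, then check the gradient of the log-likelihood
  zco <- co
  zco[m$terms] <- as.data.frame(X[, -1])
  class(zco) <- class(co)
  mz <- fit_logistic_main_effect(zco)
  p <- predict(mz, zco)$prediction
  grad <- crossprod(X, co$label - p)
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("separation is flagged and slopes capped instead of diverging", {
  y <- rep(c(0L, 1L), each = 10)
  co <- make_label_cohort(y, extra = list(x = as.numeric(y)))
  fit <- fit_univariate_logistic(co, "x")
  expect_true(fit$separation)
  p <- predict(fit, co)$prediction
  expect_true(all(p > 0 & p < 1))
  expect_lte(abs(fit$coefficients["x"] * sd(co$x)), 15 + 1e-8)
  # single-class cohort is an error, not a degenerate fit
  co1 <- make_label_cohort(rep(1L, 10), extra = list(x = rnorm(10)))
  expect_error(fit_univariate_logistic(co1, "x"), "single")
})

test_that("interaction model with constant heart area collapses to a rescaled main-effect fit", {
  set.seed(37)
  n <- 300
  co <- generate_cohort(default_calibrated_config(n = n, seed = 37))
  co$a_heart <- rep(4, n)
  co2 <- as_cohort(as.data.frame(co))
  fit_int <- fit_logistic_interaction(co2)
  # direct logistic on the products (equivalent parametrization)
  aug <- co2
  aug$z1 <- 4 * co2$bmi
  aug$z2 <- 4 * co2$d_median
  class(aug) <- class(co2)
  fit_ref <- positiondca:::.fit_logistic_terms(aug, c("z1", "z2"), "ref")
  expect_equal(predict(fit_int, co2)$prediction,
               predict(fit_ref, aug)$prediction, tolerance = 1e-6)
})

test_that("logistic fits are invariant to row order and row duplication", {
  co <- generate_cohort(default_calibrated_config(n = 150, seed = 41))
  m <- fit_logistic_main_effect(co)
  perm <- co[sample(nrow(co)), ]
  class(perm) <- class(co)
  expect_equal(fit_logistic_main_effect(perm)$coefficients, m$coefficients,
               tolerance = 1e-8)
  dup <- co[rep(seq_len(nrow(co)), 2), ]
  class(dup) <- class(co)
  expect_equal(fit_logistic_main_effect(dup)$coefficients, m$coefficients,
               tolerance = 1e-6)
})

test_that("noise-free linear cohorts are interpolated exactly and shifts move only the intercept", {
  cfg <- generator_config(n = 100, noise_sd = 0, seed = 43)
  co <- generate_cohort(cfg)
  fit <- fit_linear_dose_model(co)
  expect_equal(unname(fit$coefficients),
               c(cfg$beta0, cfg$beta_area, cfg$beta_bmi, cfg$beta_dist),
               tolerance = 1e-8)

  shifted <- as.data.frame(co)
  shifted$dose_diff <- NULL
  shifted$lad_supine <- shifted$lad_supine + 2.5
  fit2 <- fit_linear_dose_model(as_cohort(shifted))
  expect_equal(unname(fit2$coefficients["(Intercept)"] - fit$coefficients["(Intercept)"]),
               2.5, tolerance = 1e-8)
  expect_equal(fit2$coefficients[-1], fit$coefficients[-1], tolerance = 1e-8)
})

test_that("predictions follow the sign rule and the probability threshold", {
  lin <- structure(list(kind = "linear-regression", terms = character(0),
                        coefficients = c(`(Intercept)` = 3.2),
                        threshold = NA_real_),
                   class = "position_model")
  expect_identical(predict(lin, data.frame(x = 1))$decision, 0L)
  lin$coefficients <- c(`(Intercept)` = -0.1)
  expect_identical(predict(lin, data.frame(x = 1))$decision, 1L)
  lin$coefficients <- c(`(Intercept)` = 0)
  expect_identical(predict(lin, data.frame(x = 1))$decision, 0L)

  null_logit <- structure(list(kind = "univariate-logistic", terms = "x",
                               coefficients = c(`(Intercept)` = 0, x = 0),
                               threshold = 0.5),
                          class = "position_model")
  out <- predict(null_logit, data.frame(x = rnorm(5)))
  expect_equal(out$prediction, rep(0.5, 5))
  expect_identical(out$decision, rep(1L, 5))
  expect_error(predict(null_logit, data.frame(y = 1)), "missing covariate")
})

test_that("stepwise selection retains an informative term and is idempotent", {
  set.seed(47)
  n <- 2000
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x1))
  co <- make_label_cohort(y, extra = list(x1 = x1))
  back <- stepwise_logistic(co, "x1", direction = "backward")
  expect_identical(back$terms, "x1")

  noise <- replicate(3, rnorm(n))
  co2 <- make_label_cohort(y, extra = list(x1 = x1, n1 = noise[, 1],
                                           n2 = noise[, 2], n3 = noise[, 3]))
  fwd <- stepwise_logistic(co2, c("x1", "n1", "n2", "n3"),
                           direction = "forward", p_enter = 0.01)
  expect_true("x1" %in% fwd$terms)
  expect_identical(fwd$step_log$term[1], "x1")
  # forward-then-backward with matched thresholds leaves the set unchanged
  bwd <- stepwise_logistic(co2, fwd$terms, direction = "backward",
                           p_remove = 0.01)
  expect_setequal(bwd$terms, fwd$terms)
  expect_error(stepwise_logistic(co2, character(0)), "nonempty")
})
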