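#' Derive per-stage seeds from one global seed
#'
#' Each pipeline stage gets its own reproducible seed, drawn from a stream
#' initialized with the global seed, so any stage can be re-run in isolation
#' from the numbers recorded in the manifest.
#'
#' @param global_seed Integer seed.
#' @param n Number of stage seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
spawn_seeds <- function(global_seed, n = 6) {
  set.seed(global_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full synthetic position-choice study
#'
#' End-to-end orchestration on a generated cohort: simulate patients,
#' cluster the predictors, fit the four univariate logistic models, the
#' main-effect and interaction logistic models and the linear dose model,
#' tabulate AUC (with DeLong CI) and Brier score per model, compute decision
#' curves with a bootstrap confidence band for the main-effect model, and
#' run the repeated 70/30 split validation of the linear model. Everything
#' is written to `output_dir` as plain CSV/JSON plus a decision-curve PNG,
#' and a manifest records every stage seed.
#'
#' @param output_dir Directory to write the report bundle into (created if
#'   absent).
#' @param generator A [generator_config()]; its `seed` is overridden by the
#'   stage seed derived from `seed`.
#' @param grid Decision-curve threshold grid.
#' @param n_boot Bootstrap resamples for the net-benefit band.
#' @param cv_reps,train_frac Split-validation repetitions and training
#'   fraction.
#' @param seed Global seed; per-stage seeds are spawned from it.
#' @return Invisibly, a list with every in-memory result (`cohort`,
#'   `clustering`, `models`, `metrics_table`, `curve`, `nb_ci`,
#'   `cv`, `manifest`).
#' @export
reproduce_study <- function(output_dir,
                            generator = default_calibrated_config(),
                            grid = seq(0.01, 0.99, by = 0.01),
                            n_boot = 1000,
                            cv_reps = 1000,
                            train_frac = 0.7,
                            seed = 1) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(seed, 4)
  names(seeds) <- c("generate", "bootstrap", "crossval", "reserve")

  cohort <- generate_cohort(generator, seed = seeds[["generate"]])
  write_cohort_csv(cohort, file.path(output_dir, "cohort.csv"))

  clustering <- cluster_predictors(cohort)

  models <- list(
    ptv = fit_univariate_logistic(cohort, "ptv"),
    bmi = fit_univariate_logistic(cohort, "bmi"),
    d_median = fit_univariate_logistic(cohort, "d_median"),
    a_heart = fit_univariate_logistic(cohort, "a_heart"),
    main_effect = fit_logistic_main_effect(cohort),
    interaction = fit_logistic_interaction(cohort),
    linear = fit_linear_dose_model(cohort)
  )
  jsonlite::write_json(
    lapply(models, function(m) {
      list(kind = m$kind, terms = m$terms,
           coefficients = as.list(m$coefficients),
           decision_rule = m$decision_rule)
    }),
    file.path(output_dir, "models.json"), auto_unbox = TRUE, digits = NA)

  # model-comparison table: AUC + 95% CI + Brier per model
  metrics_table <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    pred <- predict(m, cohort)
    score <- pred$prediction
    if (m$kind == "linear-regression") score <- -score  # supine iff negative
    roc <- roc_curve_auc(score, cohort$label)
    brier <- if (m$kind == "linear-regression") {
      NA_real_  # no probability scale without recalibration
    } else {
      brier_score(pred$prediction, cohort$label)
    }
    data.frame(model = nm, kind = m$kind, auc = roc$auc,
               auc_ci_low = roc$ci95[1], auc_ci_high = roc$ci95[2],
               brier = brier, stringsAsFactors = FALSE)
  }))
  utils::write.csv(metrics_table, file.path(output_dir, "model_metrics.csv"),
                   row.names = FALSE)

  curve <- decision_curve(models, cohort, grid)
  utils::write.csv(as.data.frame(curve),
                   file.path(output_dir, "decision_curve.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(output_dir, "decision_curve.png"),
                 width = 900, height = 600)
  plot(curve)
  grDevices::dev.off()

  nb_ci <- bootstrap_nb_ci(models$main_effect, cohort, grid = grid,
                           n_boot = n_boot, seed = seeds[["bootstrap"]])
  utils::write.csv(nb_ci, file.path(output_dir, "net_benefit_ci.csv"),
                   row.names = FALSE)

  cv <- repeated_split_validation(cohort, "linear", train_frac = train_frac,
                                  n_reps = cv_reps, seed = seeds[["crossval"]])
  jsonlite::write_json(
    list(n_reps = cv$n_reps, model_kind = cv$model_kind,
         means = cv$means, pooled = cv$pooled,
         misclassified_dose = misclassified_dose_summary(cv),
         n_redraws = cv$n_redraws),
    file.path(output_dir, "crossval_summary.json"),
    auto_unbox = TRUE, digits = NA)

  manifest <- list(global_seed = seed, stage_seeds = as.list(seeds),
                   generator = list(n = generator$n,
                                    noise_sd = generator$noise_sd,
                                    heart_corr = generator$heart_corr),
                   grid = range(grid), n_boot = n_boot,
                   cv_reps = cv_reps, train_frac = train_frac)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, clustering = clustering, models = models,
                 metrics_table = metrics_table, curve = curve, nb_ci = nb_ci,
                 cv = cv, manifest = manifest))
}
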