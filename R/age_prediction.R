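#' Random-forest age-prediction configuration
#'
#' Defaults are the tuned optima of the underlying study: 1000 trees, maximum
#' depth 35, minimum of 2 samples per leaf, and all features considered at
#' every split (`max_features = "all"`, the historical regression reading of
#' scikit-learn's `"auto"`).
#'
#' @param n_estimators Number of trees.
#' @param max_depth Maximum tree depth.
#' @param min_samples_leaf Minimum number of samples in a terminal node.
#' @param max_features `"all"`, `"sqrt"` or `"third"` features tried per
#'   split.
#' @param seed Integer seed.
#' @return List of class `age_pred_config`.
#' @export
age_pred_config <- function(n_estimators = 1000L, max_depth = 35L,
                            min_samples_leaf = 2L,
                            max_features = c("all", "sqrt", "third"),
                            seed = 1L) {
  structure(list(
    n_estimators = .assert_count(n_estimators, "n_estimators", 1L),
    max_depth = .assert_count(max_depth, "max_depth", 1L),
    min_samples_leaf = .assert_count(min_samples_leaf, "min_samples_leaf", 1L),
    max_features = match.arg(max_features),
    seed = .assert_count(seed, "seed")
  ), class = "age_pred_config")
}

.age_design <- function(features, subjects, cells = NULL) {
  fm <- .feature_matrix(features, subject_ids = subjects$subject_id,
                        cells = cells)
  if (anyNA(fm$Y)) {
    bad <- colnames(fm$Y)[colSums(is.na(fm$Y)) > 0]
    abort(paste("missing values in feature columns:",
                paste(head(bad, 10), collapse = ", ")),
          class = "invalid_argument")
  }
  colnames(fm$Y) <- gsub(" ", "_", colnames(fm$Y))
  fm
}

#' Train a random-forest model predicting PMA at scan
#'
#' All parcel x metric feature columns (2288 at the default parcellation)
#' enter as predictors of PMA at scan. The forest is grown with
#' [ranger::ranger()] using impurity feature importance and is deterministic
#' given the config seed.
#'
#' @param features Long feature tibble for the training subjects.
#' @param subjects Training subject tibble (`pma_scan` is the target).
#' @param config An [age_pred_config()].
#' @return Object of class `age_model`.
#' @export
train_age_model <- function(features, subjects, config = age_pred_config()) {
  fm <- .age_design(features, subjects)
  mtry <- switch(config$max_features,
                 all = ncol(fm$Y),
                 sqrt = max(1L, floor(sqrt(ncol(fm$Y)))),
                 third = max(1L, floor(ncol(fm$Y) / 3)))
  fit <- ranger::ranger(
    x = fm$Y, y = subjects$pma_scan,
    num.trees = config$n_estimators,
    mtry = mtry,
    min.bucket = config$min_samples_leaf,
    max.depth = config$max_depth,
    importance = "impurity",
    seed = config$seed,
    num.threads = 1L
  )
  structure(list(fit = fit, cells = fm$cells,
                 train_subjects = subjects$subject_id,
                 config = config),
            class = "age_model")
}

#' Raw random-forest age predictions
#'
#' @param object An `age_model`.
#' @param features Long feature tibble for the subjects to predict.
#' @param subjects Subject tibble.
#' @param ... Unused.
#' @return Tibble `subject_id`, `true_pma`, `raw_pred` (weeks).
#' @export
predict.age_model <- function(object, features, subjects, ...) {
  fm <- .age_design(features, subjects, cells = object$cells)
  tibble(subject_id = subjects$subject_id,
         true_pma = subjects$pma_scan,
         raw_pred = predict(object$fit, data = fm$Y,
                            num.threads = 1L)$predictions)
}

#' Error-in-variables bias correction for age predictions
#'
#' Regression-to-the-mean makes raw forest predictions too old for young
#' subjects and too young for old ones. The correction regresses the raw
#' training predictions on true age (`raw = a + b * true`) and inverts:
#' `corrected = (raw - a) / b`. The alternative orientation fits true age on
#' the raw prediction and applies it directly.
#'
#' @param raw_pred Raw training predictions (weeks).
#' @param true_age True training ages (weeks).
#' @param orientation `"pred_on_true"` (default, inverted at application) or
#'   `"true_on_pred"`.
#' @return Object of class `bias_correction` with fields `a`, `b`.
#' @export
fit_bias_correction <- function(raw_pred, true_age,
                                orientation = c("pred_on_true", "true_on_pred")) {
  orientation <- match.arg(orientation)
  if (length(raw_pred) < 3L || length(raw_pred) != length(true_age)) {
    abort("need at least 3 paired training predictions",
          class = "invalid_argument")
  }
  if (sd(true_age) == 0) {
    abort("true ages are constant; no age signal to correct against",
          class = "invalid_argument")
  }
  co <- if (orientation == "pred_on_true") {
    coef(lm(raw_pred ~ true_age))
  } else {
    coef(lm(true_age ~ raw_pred))
  }
  if (abs(co[2]) < 1e-6) {
    abort("no age signal in predictions (|slope| < 1e-6)",
          class = "invalid_argument")
  }
  structure(list(a = unname(co[1]), b = unname(co[2]),
                 orientation = orientation),
            class = "bias_correction")
}

#' @rdname fit_bias_correction
#' @param correction A `bias_correction`.
#' @param raw Raw predictions to correct (weeks).
#' @export
apply_bias_correction <- function(correction, raw) {
  if (correction$orientation == "pred_on_true") {
    (raw - correction$a) / correction$b
  } else {
    correction$a + correction$b * raw
  }
}

#' Evaluate age prediction on a hold-out sample
#'
#' Applies the trained forest and the training-derived bias correction to a
#' hold-out sample (which must be disjoint from training) and reports the
#' MAE (weeks), MSE (weeks^2), Spearman rho and coefficient of determination
#' between corrected predictions and true PMA.
#'
#' @param model An `age_model`.
#' @param correction A `bias_correction` fitted on training predictions.
#' @param features,subjects Hold-out data.
#' @return Object of class `age_pred_report`; see [tidy.age_pred_report()].
#' @export
evaluate_age_model <- function(model, correction, features, subjects) {
  overlap <- intersect(subjects$subject_id, model$train_subjects)
  if (length(overlap)) {
    abort(paste("hold-out overlaps training set:",
                paste(head(overlap, 5), collapse = ", ")),
          class = "invalid_argument")
  }
  preds <- predict(model, features, subjects) |>
    mutate(corrected_pred = apply_bias_correction(correction, .data$raw_pred))
  err <- preds$corrected_pred - preds$true_pma
  structure(list(
    predictions = preds,
    mae = mean(abs(err)),
    mse = mean(err^2),
    spearman_rho = suppressWarnings(
      cor(preds$true_pma, preds$corrected_pred, method = "spearman")),
    r_squared = 1 - sum(err^2) /
      sum((preds$true_pma - mean(preds$true_pma))^2),
    correction = correction
  ), class = "age_pred_report")
}

#' @export
print.age_pred_report <- function(x, ...) {
  cat(sprintf(paste0("Age prediction report (%d hold-out subjects)\n",
                     "  MAE = %.3f weeks, MSE = %.3f weeks^2\n",
                     "  Spearman rho = %.3f, R^2 = %.3f\n"),
              nrow(x$predictions), x$mae, x$mse, x$spearman_rho, x$r_squared))
  invisible(x)
}

#' Tidy an age-prediction report
#'
#' @param x An `age_pred_report`.
#' @param ... Unused.
#' @return `tidy()`: per-subject true, raw and corrected predictions.
#'   `glance()`: one-row MAE/MSE/rho/R-squared summary.
#' @export
tidy.age_pred_report <- function(x, ...) x$predictions

#' @rdname tidy.age_pred_report
#' @export
glance.age_pred_report <- function(x, ...) {
  tibble(n = nrow(x$predictions), mae = x$mae, mse = x$mse,
         spearman_rho = x$spearman_rho, r_squared = x$r_squared)
}

#' Per-metric summary of top-decile feature importance
#'
#' Ranks all features by impurity importance, keeps the top
#' `ceil(top_fraction * n_features)` (ties broken by stable feature order)
#' and counts how many of them belong to each cortical metric.
#'
#' @param model An `age_model`.
#' @param top_fraction Fraction of features kept (default 0.10).
#' @return Tibble `metric`, `n_top`, `percent`, with attribute
#'   `decile_size`.
#' @export
summarize_importance <- function(model, top_fraction = 0.10) {
  .assert_fraction(top_fraction, "top_fraction")
  imp <- ranger::importance(model$fit)
  k <- as.integer(ceiling(top_fraction * length(imp)))
  top_idx <- order(-imp)[seq_len(k)]  # order() is stable, breaking ties
  top_metric <- model$cells$metric[top_idx]
  out <- tibble(metric = cortical_metrics) |>
    left_join(tibble(metric = top_metric) |> count(.data$metric, name = "n_top"),
              by = "metric") |>
    mutate(n_top = ifelse(is.na(.data$n_top), 0L, .data$n_top),
           percent = 100 * .data$n_top / k) |>
    arrange(desc(.data$n_top))
  attr(out, "decile_size") <- k
  out
}
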