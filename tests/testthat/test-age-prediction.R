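test_that("bias correction inverts the training regression exactly", {
  # identity correction
  id <- fit_bias_correction(c(38, 40, 42, 44), c(38, 40, 42, 44))
  expect_equal(id$a, 0, tolerance = 1e-10)
  expect_equal(id$b, 1, tolerance = 1e-10)
  expect_equal(apply_bias_correction(id, 41), 41, tolerance = 1e-9)

  # worked inversion: a = 10, b = 0.75, raw 40 -> 40
  true_age <- c(36, 38, 40, 42, 44)
  raw <- 10 + 0.75 * true_age
  bc <- fit_bias_correction(raw, true_age)
  expect_equal(bc$a, 10, tolerance = 1e-9)
  expect_equal(bc$b, 0.75, tolerance = 1e-9)
  expect_equal(apply_bias_correction(bc, 40), 40, tolerance = 1e-9)

  # algebraic identity: corrected training predictions regress on true age
  # with slope 1 and intercept 0
  set.seed(5)
  t_age <- runif(50, 37, 45)
  noisy_raw <- 12 + 0.6 * t_age + rnorm(50, 0, 0.4)
  bc2 <- fit_bias_correction(noisy_raw, t_age)
  corrected <- apply_bias_correction(bc2, noisy_raw)
  co <- coef(lm(corrected ~ t_age))
  expect_equal(unname(co[2]), 1, tolerance = 1e-8)
  expect_equal(unname(co[1]), 0, tolerance = 1e-8)

  expect_error(fit_bias_correction(c(1, 2), c(1, 2)),
               class = "invalid_argument")
  expect_error(fit_bias_correction(c(1, 2, 3), c(2, 2, 2)),
               class = "invalid_argument")
  expect_error(fit_bias_correction(c(2, 2, 2), c(1, 2, 3)),
               class = "invalid_argument")

  # alternative orientation applies the fit directly
  bc3 <- fit_bias_correction(noisy_raw, t_age, orientation = "true_on_pred")
  expect_equal(apply_bias_correction(bc3, noisy_raw[1]),
               unname(coef(lm(t_age ~ noisy_raw))[1] +
                        coef(lm(t_age ~ noisy_raw))[2] * noisy_raw[1]))
})

test_that("forest training is deterministic and handles a constant target", {
  sim <- tiny_sim(25, 0, parcels = 7, seed = 13)
  cfg <- age_pred_config(n_estimators = 50, seed = 7)
  m1 <- train_age_model(sim$features, sim$subjects, cfg)
  m2 <- train_age_model(sim$features, sim$subjects, cfg)
  p1 <- predict(m1, sim$features, sim$subjects)
  p2 <- predict(m2, sim$features, sim$subjects)
  expect_identical(p1$raw_pred, p2$raw_pred)

  const <- dplyr::mutate(sim$subjects, pma_scan = 40)
  mc <- train_age_model(sim$features, const, cfg)
  pc <- predict(mc, sim$features, const)
  expect_equal(pc$raw_pred, rep(40, 25))
})

test_that("predictions are invariant to feature row order", {
  sim <- tiny_sim(20, 0, parcels = 7, seed = 14)
  cfg <- age_pred_config(n_estimators = 50, seed = 3)
  m <- train_age_model(sim$features, sim$subjects, cfg)
  shuffled <- sim$features[sample(nrow(sim$features)), ]
  expect_equal(predict(m, sim$features, sim$subjects)$raw_pred,
               predict(m, shuffled, sim$subjects)$raw_pred)
})

test_that("the forest beats the train-mean baseline on age-graded features", {
  sim <- tiny_sim(60, 0, parcels = 10, seed = 15)
  sp <- split_cohort(sim$subjects, 0.25, seed = 1)
  tr_ids <- sp$subject_id[sp$split == "train"]
  ho_ids <- sp$subject_id[sp$split == "holdout"]
  tr <- dplyr::filter(sim$subjects, subject_id %in% tr_ids)
  ho <- dplyr::filter(sim$subjects, subject_id %in% ho_ids)
  m <- train_age_model(dplyr::filter(sim$features, subject_id %in% tr_ids),
                       tr, age_pred_config(n_estimators = 300, seed = 2))
  raw_tr <- predict(m, dplyr::filter(sim$features, subject_id %in% tr_ids), tr)
  bc <- fit_bias_correction(raw_tr$raw_pred, raw_tr$true_pma)
  rep <- evaluate_age_model(
    m, bc, dplyr::filter(sim$features, subject_id %in% ho_ids), ho)
  baseline_mae <- mean(abs(ho$pma_scan - mean(tr$pma_scan)))
  expect_lt(rep$mae, 0.75 * baseline_mae)
  expect_gt(rep$spearman_rho, 0.5)
  expect_lte(rep$mae^2, rep$mse + 1e-12)
  # hold-out must be disjoint from training
  expect_error(evaluate_age_model(
    m, bc, dplyr::filter(sim$features, subject_id %in% tr_ids), tr),
    class = "invalid_argument")
})

test_that("evaluation metrics hit their boundary cases", {
  # a perfect predictor and an anti-correlated one, via a stub forest
  fake_model <- function(preds, cells, train_ids) {
    structure(list(fit = structure(list(preds = preds), class = "stub_rf"),
                   cells = cells, train_subjects = train_ids,
                   config = age_pred_config(n_estimators = 1)),
              class = "age_model")
  }
  registerS3method("predict", "stub_rf",
                   function(object, data, ...) list(predictions = object$preds))
  sim <- tiny_sim(10, 0, parcels = 7, seed = 16)
  cells <- corticonorm:::.cell_grid(sim$parcels$parcel_id)
  m <- fake_model(sim$subjects$pma_scan, cells, "nobody")
  id <- structure(list(a = 0, b = 1, orientation = "pred_on_true"),
                  class = "bias_correction")
  rep <- evaluate_age_model(m, id, sim$features, sim$subjects)
  expect_equal(rep$mae, 0)
  expect_equal(rep$mse, 0)
  expect_equal(rep$spearman_rho, 1)
  expect_equal(rep$r_squared, 1)

  anti <- fake_model(-sim$subjects$pma_scan, cells, "nobody")
  rep2 <- evaluate_age_model(anti, id, sim$features, sim$subjects)
  expect_equal(rep2$spearman_rho, -1)
})

test_that("importance summary keeps the top decile and favours the signal", {
  cfg <- tiny_config(seed = 17)
  cfg$age_slope[] <- 0
  cfg$age_slope["SA", ] <- 4  # only SA carries age signal
  sim <- simulate_cohort(60, 0, n_parcels_per_hemisphere = 8,
                         config = cfg, seed = 17)
  m <- train_age_model(sim$features, sim$subjects,
                       age_pred_config(n_estimators = 300, seed = 4))
  imp <- summarize_importance(m, top_fraction = 0.10)
  k <- attr(imp, "decile_size")
  expect_equal(k, ceiling(0.10 * 16 * 8))
  expect_equal(sum(imp$n_top), k)
  expect_equal(imp$metric[1], "SA")
  expect_gt(imp$n_top[1] / k, 0.5)
  expect_equal(sum(imp$percent), 100)
})
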