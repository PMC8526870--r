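test_that("stratified split hits the configured fraction and is deterministic", {
  d <- sample_demographics(259, 0, seed = 1)
  sp <- split_cohort(d, 0.25, seed = 1)
  expect_equal(sum(sp$split == "holdout"), round(0.25 * 259))
  expect_setequal(sp$subject_id, d$subject_id)
  expect_identical(sp, split_cohort(d, 0.25, seed = 1))

  small <- sample_demographics(8, 0, seed = 2)
  sp8 <- split_cohort(small, 0.25, seed = 1)
  expect_equal(table(sp8$split)[["holdout"]], 2)
  expect_equal(table(sp8$split)[["train"]], 6)

  expect_error(split_cohort(d, 1.2), class = "invalid_argument")
  # only term-born subjects are partitioned
  mixed <- sample_demographics(40, 20, seed = 3)
  spm <- split_cohort(mixed, 0.25, seed = 1)
  expect_setequal(spm$subject_id,
                  mixed$subject_id[mixed$group == "term"])
})

test_that("PMA stratification matches train/hold-out age better than chance", {
  d <- sample_demographics(80, 0, seed = 4)
  gap <- function(split) {
    tr <- d$pma_scan[split$split == "train"]
    ho <- d$pma_scan[split$split == "holdout"]
    abs(mean(tr) - mean(ho))
  }
  strat <- numeric(50); naive <- numeric(50)
  for (s in seq_len(50)) {
    strat[s] <- gap(split_cohort(d, 0.25, seed = s))
    set.seed(s + 1000)
    idx <- sample(80, 20)
    naive[s] <- gap(tibble::tibble(
      subject_id = d$subject_id,
      split = ifelse(seq_len(80) %in% idx, "holdout", "train")))
  }
  expect_lt(mean(strat), mean(naive))
})

test_that("hyperparameters are recovered on simulated linear data", {
  set.seed(42)
  n <- 100
  pma <- runif(n, 38, 44)
  pma_std <- (pma - mean(pma)) / sd(pma)
  y <- 2 * pma_std + rnorm(n, 0, 0.1)
  subj <- one_cell_subjects(pma)
  feat <- one_cell_features(y)
  m <- fit_normative_model(feat, subj, restarts = 3, seed = 1)
  # de-standardized noise variance close to 0.01
  hp <- tidy(m)
  expect_gt(hp$noise_variance, 0.005)
  expect_lt(hp$noise_variance, 0.02)
  # predictive slope close to 2 per standardized PMA unit
  new <- one_cell_subjects(c(mean(pma), mean(pma) + sd(pma)))
  new$subject_id <- c("n1", "n2")
  pr <- predict(m, new)
  expect_lt(abs(diff(pr$mean) - 2), 0.1)
})

test_that("a constant output falls back to a noise-only model", {
  subj <- one_cell_subjects(runif(20, 38, 44))
  feat <- one_cell_features(rep(0.42, 20))
  m <- fit_normative_model(feat, subj, restarts = 1, seed = 1)
  expect_equal(m$cells$status, "constant")
  pr <- predict(m, one_cell_subjects(c(39, 43)))
  expect_equal(pr$mean, c(0.42, 0.42))
  expect_true(all(pr$variance > 0))
})

test_that("fitting is deterministic given data and seed", {
  sim <- tiny_sim(20, 0, parcels = 7, seed = 3)
  m1 <- fit_normative_model(sim$features, sim$subjects, restarts = 2, seed = 9)
  m2 <- fit_normative_model(sim$features, sim$subjects, restarts = 2, seed = 9)
  expect_identical(tidy(m1), tidy(m2))
})

test_that("optimized marginal likelihood beats every initialization", {
  set.seed(7)
  pma <- runif(40, 38, 44)
  y <- 0.02 * (pma - 40) + rnorm(40, 0, 0.05) + 0.3
  m <- fit_normative_model(one_cell_features(y), one_cell_subjects(pma),
                           restarts = 4, seed = 2)
  set.seed(2)  # replay the restart draws used inside the fit
  inits <- corticonorm:::.gp_inits(4)
  for (i in seq_len(nrow(inits))) {
    ys <- (y - mean(y)) / sd(y)
    val <- corticonorm:::.gp_nll(log(inits[i, ]), m$D2, m$XP, ys,
                                 want_grad = FALSE)$value
    expect_gte(m$cells$log_marginal_likelihood + 1e-6, -val)
  }
})

test_that("predictions interpolate the training data as noise vanishes", {
  # fixed kernel with negligible noise: posterior mean at a training input
  # must reproduce the training output
  set.seed(1)
  X <- cbind(runif(15, -1, 1), rbinom(15, 1, 0.5))
  D2 <- as.matrix(dist(X))^2
  XP <- tcrossprod(X)
  y <- sin(X[, 1]) + 0.2 * X[, 2]
  p <- c(1, 1, 0.5, 1e-10)
  ch <- corticonorm:::.cell_chol(p, D2, XP)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  K <- p[1] * exp(-D2 / (2 * p[2]^2)) + p[3] * XP  # k* at training inputs
  expect_equal(as.vector(K %*% alpha), y, tolerance = 1e-6)
})

test_that("linear-kernel GP equals closed-form Bayesian linear regression", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    y <- X %*% c(0.7, -0.3) + rnorm(n, 0, 0.3)
    Xs <- cbind(rnorm(4), rbinom(4, 1, 0.5))
    prior_var <- runif(1, 0.2, 2)
    noise_var <- runif(1, 0.05, 0.5)

    gp <- gp_posterior(X, y, Xs, rbf_variance = 0, rbf_lengthscale = 1,
                       linear_variance = prior_var,
                       noise_variance = noise_var)
    oracle <- blr_oracle(X, as.vector(y), Xs, prior_var, noise_var)
    expect_equal(gp$mean, oracle$mean, tolerance = 1e-6)
    expect_equal(gp$variance, oracle$variance, tolerance = 1e-6)
  }
})

test_that("predictive variance never drops below the noise variance", {
  sim <- tiny_sim(25, 0, parcels = 7, seed = 6)
  m <- fit_normative_model(sim$features, sim$subjects, restarts = 2, seed = 1)
  pr <- predict(m, sim$subjects[1:5, ])
  hp <- tidy(m)
  floor_by_cell <- hp$noise_variance[
    match(paste(pr$metric, pr$parcel_id), paste(hp$metric, hp$parcel_id))]
  expect_true(all(pr$variance >= floor_by_cell - 1e-10))
})

test_that("out-of-range PMA warns and empty prediction returns empty", {
  sim <- tiny_sim(15, 0, parcels = 7, seed = 8)
  m <- fit_normative_model(sim$features, sim$subjects, restarts = 1, seed = 1)
  far <- sim$subjects[1, ]
  far$pma_scan <- m$pma_range[2] + 3
  expect_warning(predict(m, far), "outside training range")
  empty <- predict(m, sim$subjects[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("a serialized model reconstructs to identical predictions", {
  sim <- tiny_sim(16, 0, parcels = 7, seed = 19)
  m <- fit_normative_model(sim$features, sim$subjects, restarts = 1, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_normative_model(m, f)
  back <- read_normative_model(f, sim$features, sim$subjects)
  new <- sim$subjects[1:4, ]
  expect_equal(predict(back, new), predict(m, new), tolerance = 1e-9)
  expect_error(read_normative_model(f, sim$features, sim$subjects[-1, ]),
               class = "io_error")
})

test_that("hold-out MAE behaves as the half-normal identity predicts", {
  # pure noise: MAE of the (flat) normative prediction tends to s*sqrt(2/pi)
  set.seed(21)
  s <- 0.3
  pma_tr <- runif(100, 38, 44)
  m <- fit_normative_model(one_cell_features(rnorm(100, 1, s)),
                           one_cell_subjects(pma_tr),
                           restarts = 2, seed = 3)
  pma_ho <- runif(500, 38, 44)
  ho_subj <- one_cell_subjects(pma_ho)
  ho_subj$subject_id <- sprintf("h%03d", 1:500)
  ho_feat <- one_cell_features(rnorm(500, 1, s))
  ho_feat$subject_id <- ho_subj$subject_id
  mae <- evaluate_mae(m, ho_feat, ho_subj)
  expect_equal(mae$mae, s * sqrt(2 / pi), tolerance = 0.1)

  # a single hold-out subject gives the absolute residual exactly
  one <- evaluate_mae(m, ho_feat[1, ], ho_subj[1, ])
  pr <- predict(m, ho_subj[1, ])
  expect_equal(one$mae, abs(ho_feat$value[1] - pr$mean))

  # overlapping subjects are refused
  tr_subj <- one_cell_subjects(pma_tr)
  expect_error(evaluate_mae(m, one_cell_features(rnorm(100)), tr_subj),
               class = "invalid_argument")
})
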