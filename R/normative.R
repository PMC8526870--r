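# ---- internal: long feature table <-> subjects x cells matrix -------------

# cell key order: metric blocks in cortical_metrics order, parcels ascending
.cell_grid <- function(parcel_ids, metrics = cortical_metrics) {
  tibble(metric = rep(metrics, each = length(parcel_ids)),
         parcel_id = rep(sort(parcel_ids), length(metrics)))
}

.feature_matrix <- function(features, subject_ids = NULL, cells = NULL) {
  .check_metric_names(features$metric)
  if (is.null(subject_ids)) subject_ids <- sort(unique(features$subject_id))
  if (is.null(cells)) {
    cells <- .cell_grid(unique(features$parcel_id),
                        metrics = intersect(cortical_metrics,
                                            unique(features$metric)))
  }
  key <- paste(cells$metric, cells$parcel_id)
  i <- match(features$subject_id, subject_ids)
  j <- match(paste(features$metric, features$parcel_id), key)
  keep <- !is.na(i) & !is.na(j)
  Y <- matrix(NA_real_, length(subject_ids), nrow(cells),
              dimnames = list(subject_ids, key))
  Y[cbind(i[keep], j[keep])] <- features$value[keep]
  if (anyNA(Y)) {
    abort("feature table does not cover all subject x parcel x metric cells",
          class = "schema_error")
  }
  list(Y = Y, cells = cells, subject_ids = subject_ids)
}

# ---- train/hold-out split ---------------------------------------------------

#' Split term-born subjects into training and hold-out samples
#'
#' Stratifies by PMA-at-scan quartile so the two partitions have matching age
#' distributions, and allocates the hold-out count per stratum by largest
#' remainder so the total is `round(holdout_fraction * n)` exactly.
#'
#' @param subjects Subject tibble; if a `group` column is present only
#'   term-born subjects are partitioned.
#' @param holdout_fraction Hold-out proportion in (0, 1); default 0.25.
#' @param seed Integer seed.
#' @return Tibble `subject_id`, `split` (`"train"` / `"holdout"`).
#' @export
split_cohort <- function(subjects, holdout_fraction = 0.25, seed = 1L) {
  .assert_fraction(holdout_fraction, "holdout_fraction")
  seed <- .assert_count(seed, "seed")
  if ("group" %in% names(subjects)) {
    subjects <- filter(subjects, .data$group == "term")
  }
  n <- nrow(subjects)
  if (n < 8L) abort("need at least 8 term subjects", class = "invalid_argument")
  set.seed(seed)

  qs <- quantile(subjects$pma_scan, c(0.25, 0.5, 0.75), type = 7)
  stratum <- findInterval(subjects$pma_scan, qs) + 1L
  n_hold_total <- round(holdout_fraction * n)
  sizes <- tabulate(stratum, nbins = 4L)
  raw <- sizes * n_hold_total / n
  take <- floor(raw)
  rem <- n_hold_total - sum(take)
  if (rem > 0) {
    ord <- order(raw - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  split <- rep("train", n)
  for (s in 1:4) {
    idx <- which(stratum == s)
    if (take[s] > 0) split[sample(idx, take[s])] <- "holdout"
  }
  tibble(subject_id = subjects$subject_id, split = split)
}

# ---- GP marginal likelihood (RBF + linear + white noise) -------------------

# negative log marginal likelihood and gradient in log-parameter space.
# lp = log(rbf_variance, rbf_lengthscale, linear_variance, noise_variance).
# D2: squared-distance matrix, XP: inner-product matrix of the covariates.
.gp_nll <- function(lp, D2, XP, y, want_grad = TRUE) {
  sr <- exp(lp[1]); ls <- exp(lp[2]); sl <- exp(lp[3]); sn <- exp(lp[4])
  n <- length(y)
  Kr <- sr * exp(-D2 / (2 * ls^2))
  K <- Kr + sl * XP
  diag(K) <- diag(K) + sn
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = rep(0, 4)))
  a <- backsolve(L, forwardsolve(t(L), y))
  val <- 0.5 * sum(y * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!want_grad) return(list(value = val))
  A <- tcrossprod(a) - chol2inv(L)   # d loglik/d theta = 0.5 tr(A dK/d theta)
  list(value = val, grad = c(
    -0.5 * sum(A * Kr),
    -0.5 * sum(A * (Kr * D2 / ls^2)),
    -0.5 * sum(A * XP) * sl,
    -0.5 * sum(diag(A)) * sn
  ))
}

.gp_fit_cell <- function(D2, XP, y, inits, noise_floor = 1e-8) {
  fn <- function(lp) .gp_nll(lp, D2, XP, y, want_grad = FALSE)$value
  gr <- function(lp) .gp_nll(lp, D2, XP, y)$grad
  # the lengthscale lower bound keeps the RBF identifiable: below the typical
  # covariate spacing it degenerates into a second white-noise component
  # (same marginal likelihood, pathological predictions)
  lower <- log(c(1e-10, 0.1, 1e-10, noise_floor))
  upper <- log(c(1e3, 1e3, 1e3, 1e3))
  best <- NULL
  init_vals <- numeric(nrow(inits))
  for (i in seq_len(nrow(inits))) {
    lp0 <- pmin(pmax(log(inits[i, ]), lower), upper)
    init_vals[i] <- fn(lp0)
    o <- tryCatch(
      optim(lp0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e9, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) return(NULL)
  list(params = exp(best$par), lml = -best$value,
       convergence = best$convergence, init_lml = -init_vals)
}

.gp_inits <- function(restarts) {
  # deterministic first start: variance shared across components, unit
  # lengthscale on standardized covariates
  inits <- matrix(c(1 / 3, 1, 1 / 3, 1 / 3), nrow = 1)
  if (restarts > 1L) {
    ls_grid <- rep_len(c(0.5, 1, 2), restarts - 1L)
    more <- cbind(exp(runif(restarts - 1L, log(0.05), log(2))),
                  ls_grid * exp(runif(restarts - 1L, -0.2, 0.2)),
                  exp(runif(restarts - 1L, log(0.05), log(2))),
                  exp(runif(restarts - 1L, log(0.05), log(1))))
    inits <- rbind(inits, more)
  }
  inits
}

#' Fit per-(parcel, metric) Gaussian-process normative models
#'
#' For every parcel x metric cell, fits a GP regression of the feature on
#' standardized PMA at scan and binary sex, with covariance
#' `k(x, x') = rbf_variance * exp(-||x - x'||^2 / (2 * lengthscale^2)) +
#'  linear_variance * x.x' + noise_variance * I`,
#' maximising the log marginal likelihood by multi-start L-BFGS on the log
#' parameters. Outputs are standardized per cell before fitting; constant
#' outputs fall back to a noise-only model. Cells whose covariance cannot be
#' factorised even after jitter escalation are flagged `failed` and skipped
#' downstream.
#'
#' @param features Long feature tibble (`subject_id`, `parcel_id`, `metric`,
#'   `value`) for the training subjects.
#' @param subjects Training subject tibble (typically the term-born training
#'   split).
#' @param restarts Number of optimizer starts per cell (first start is
#'   deterministic); default 5.
#' @param seed Integer seed for the random restarts.
#' @param noise_floor Lower bound on the noise variance, as a fraction of the
#'   (standardized) output variance.
#' @param df_correction Inflate predictive variances by `n / (n - nu)`,
#'   where `nu` is the effective degrees of freedom of the fitted GP
#'   smoother (`nu = n - noise_variance * tr((K + noise_variance I)^-1)`).
#'   Plug-in ML predictive variances are optimistic by this factor — the
#'   analogue of dividing residual sums of squares by `n - p` rather than
#'   `n` in ordinary regression — and without the correction hold-out
#'   Z-scores are over-dispersed by about `nu / n`. The residual degrees of
#'   freedom `n - nu` are also exported (`t_df`) so that
#'   [compute_z_scores()] can refer studentized deviations to their t
#'   reference distribution. Default `TRUE`.
#' @return Object of class `normative_model`; see [tidy.normative_model()]
#'   for the per-cell hyperparameters.
#' @export
fit_normative_model <- function(features, subjects, restarts = 5L, seed = 1L,
                                noise_floor = 1e-8, df_correction = TRUE) {
  restarts <- .assert_count(restarts, "restarts", min = 1L)
  seed <- .assert_count(seed, "seed")
  if (nrow(subjects) < 10L) {
    abort("need at least 10 training subjects", class = "invalid_argument")
  }
  set.seed(seed)

  fm <- .feature_matrix(features, subject_ids = subjects$subject_id)
  Y <- fm$Y
  n <- nrow(Y); C <- ncol(Y)

  pma_mean <- mean(subjects$pma_scan)
  pma_sd <- sd(subjects$pma_scan)
  if (!is.finite(pma_sd) || pma_sd <= 0) pma_sd <- 1
  X <- cbind(pma = (subjects$pma_scan - pma_mean) / pma_sd,
             sex = subjects$sex)
  D2 <- as.matrix(dist(X))^2
  XP <- tcrossprod(X)

  inits <- .gp_inits(restarts)
  y_mean <- colMeans(Y)
  y_sd <- apply(Y, 2, sd)

  params <- matrix(NA_real_, C, 4)
  lml <- rep(NA_real_, C)
  convergence <- rep(NA_integer_, C)
  status <- rep("ok", C)
  alpha <- matrix(0, n, C)
  var_inflation <- rep(1, C)
  t_df <- rep(Inf, C)
  Ystd <- Y

  for (j in seq_len(C)) {
    if (!is.finite(y_sd[j]) || y_sd[j] < 1e-12) {
      status[j] <- "constant"
      params[j, ] <- c(0, 1, 0, noise_floor)
      Ystd[, j] <- 0
      next
    }
    ys <- (Y[, j] - y_mean[j]) / y_sd[j]
    Ystd[, j] <- ys
    fit <- .gp_fit_cell(D2, XP, ys, inits, noise_floor = noise_floor)
    if (is.null(fit)) { status[j] <- "failed"; next }
    params[j, ] <- fit$params
    lml[j] <- fit$lml
    convergence[j] <- fit$convergence
    # cache alpha = (K + sn I)^{-1} y for fast predictive means
    ch <- .cell_chol(fit$params, D2, XP)
    if (is.null(ch$L)) { status[j] <- "failed"; next }
    if (ch$jitter > 0) status[j] <- "jittered"
    alpha[, j] <- backsolve(ch$L, forwardsolve(t(ch$L), ys))
    if (df_correction) {
      # effective dof of the GP smoother; the variance correction mirrors
      # n/(n-p) in OLS, and n - nu doubles as the t reference df for
      # studentized Z-scores
      nu <- n - fit$params[4] * sum(diag(chol2inv(ch$L)))
      var_inflation[j] <- min(n / max(n - nu, 2), 2)
      t_df[j] <- max(n - nu, 2)
    }
  }

  structure(list(
    cells = bind_cols(fm$cells, tibble(
      rbf_variance = params[, 1], rbf_lengthscale = params[, 2],
      linear_variance = params[, 3], noise_variance = params[, 4],
      log_marginal_likelihood = lml, convergence = convergence,
      status = status, y_mean = y_mean, y_sd = y_sd,
      var_inflation = var_inflation, t_df = t_df)),
    X = X, alpha = alpha, Ystd = Ystd, D2 = D2, XP = XP,
    pma_mean = pma_mean, pma_sd = pma_sd,
    train_subjects = subjects$subject_id,
    pma_range = range(subjects$pma_scan),
    restarts = restarts, seed = seed, noise_floor = noise_floor
  ), class = "normative_model")
}

#' Exact GP posterior for fixed kernel hyperparameters
#'
#' Computes the Gaussian-process posterior mean and variance (observation
#' noise included) under the RBF + linear + white covariance at given, fixed
#' hyperparameters — no fitting and no degrees-of-freedom correction, so the
#' result is the textbook conditional Gaussian. With `rbf_variance = 0` this
#' is exactly Bayesian linear regression with prior variance
#' `linear_variance` on the weights.
#'
#' @param X Training covariate matrix (n x d).
#' @param y Training outputs (length n).
#' @param Xstar Test covariate matrix (m x d).
#' @param rbf_variance,rbf_lengthscale,linear_variance,noise_variance Kernel
#'   hyperparameters (all non-negative; `noise_variance` > 0).
#' @return List with `mean` and `variance` (length m).
#' @export
gp_posterior <- function(X, y, Xstar, rbf_variance, rbf_lengthscale,
                         linear_variance, noise_variance) {
  X <- as.matrix(X); Xstar <- as.matrix(Xstar)
  p <- c(rbf_variance, rbf_lengthscale, linear_variance, noise_variance)
  D2 <- as.matrix(dist(X))^2
  XP <- tcrossprod(X)
  ch <- .cell_chol(p, D2, XP)
  if (is.null(ch$L)) abort("covariance is not positive definite")
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), as.vector(y)))
  cross_d2 <- outer(rowSums(X^2), rep(1, nrow(Xstar))) +
    outer(rep(1, nrow(X)), rowSums(Xstar^2)) - 2 * X %*% t(Xstar)
  ks <- p[1] * exp(-pmax(cross_d2, 0) / (2 * p[2]^2)) + p[3] * X %*% t(Xstar)
  v <- forwardsolve(t(ch$L), ks)
  kss <- p[1] + p[3] * rowSums(Xstar^2)
  list(mean = as.vector(crossprod(ks, alpha)),
       variance = as.vector(pmax(kss - colSums(v^2), 0) + p[4]))
}

# Cholesky of the training covariance with jitter escalation
.cell_chol <- function(p, D2, XP, max_jitter = 1e-4) {
  K <- p[1] * exp(-D2 / (2 * p[2]^2)) + p[3] * XP
  diag(K) <- diag(K) + p[4]
  jitter <- 0
  repeat {
    L <- tryCatch(chol(K + diag(jitter, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jitter))
    jitter <- if (jitter == 0) 1e-8 else jitter * 10
    if (jitter > max_jitter) return(list(L = NULL, jitter = jitter))
  }
}

#' Serialize / reconstruct a normative model
#'
#' `write_normative_model()` stores the per-cell hyperparameters (in
#' standardized space), standardization constants and training references as
#' JSON. `read_normative_model()` rebuilds the full model from that file
#' plus the training feature and subject tables it references, recomputing
#' the cached solves; predictions from the reconstructed model are identical
#' to the original's.
#'
#' @param model A `normative_model`.
#' @param path JSON file path.
#' @export
write_normative_model <- function(model, path) {
  cells <- model$cells
  cells$t_df[!is.finite(cells$t_df)] <- NA_real_  # JSON has no Inf
  jsonlite::write_json(list(
    cells = cells,
    pma_mean = model$pma_mean, pma_sd = model$pma_sd,
    pma_range = model$pma_range,
    train_subjects = model$train_subjects,
    restarts = model$restarts, seed = model$seed,
    noise_floor = model$noise_floor),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normative_model
#' @param features,subjects The training tables the stored model references.
#' @export
read_normative_model <- function(path, features, subjects) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing_train <- setdiff(raw$train_subjects, subjects$subject_id)
  if (length(missing_train)) {
    abort(paste("training subjects absent from supplied table:",
                paste(head(missing_train, 5), collapse = ", ")),
          class = "io_error")
  }
  subjects <- subjects[match(raw$train_subjects, subjects$subject_id), ]
  cells <- as_tibble(raw$cells)
  if (!"t_df" %in% names(cells)) cells$t_df <- NA_real_
  cells$t_df[is.na(cells$t_df)] <- Inf
  fm <- .feature_matrix(features, subject_ids = subjects$subject_id,
                        cells = cells[, c("metric", "parcel_id")])
  X <- cbind(pma = (subjects$pma_scan - raw$pma_mean) / raw$pma_sd,
             sex = subjects$sex)
  D2 <- as.matrix(dist(X))^2
  XP <- tcrossprod(X)
  n <- nrow(X)
  Ystd <- sweep(sweep(fm$Y, 2, cells$y_mean, `-`), 2,
                ifelse(cells$status == "constant", 1, cells$y_sd), `/`)
  alpha <- matrix(0, n, nrow(cells))
  P <- as.matrix(cells[, c("rbf_variance", "rbf_lengthscale",
                           "linear_variance", "noise_variance")])
  for (j in seq_len(nrow(cells))) {
    if (cells$status[j] %in% c("constant", "failed")) next
    ch <- .cell_chol(P[j, ], D2, XP)
    if (is.null(ch$L)) { cells$status[j] <- "failed"; next }
    alpha[, j] <- backsolve(ch$L, forwardsolve(t(ch$L), Ystd[, j]))
  }
  structure(list(
    cells = cells, X = X, alpha = alpha, Ystd = Ystd, D2 = D2, XP = XP,
    pma_mean = raw$pma_mean, pma_sd = raw$pma_sd,
    train_subjects = raw$train_subjects,
    pma_range = raw$pma_range,
    restarts = raw$restarts, seed = raw$seed,
    noise_floor = raw$noise_floor
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Gaussian-process normative model\n")
  cat(sprintf("  %d training subjects, %d (parcel, metric) cells\n",
              length(x$train_subjects), nrow(x$cells)))
  cat(sprintf("  cell status: %s\n",
              paste(names(table(x$cells$status)), table(x$cells$status),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Predictive distribution of a normative model for new subjects
#'
#' Standard GP posterior per cell, de-standardized to metric units. The
#' predictive variance includes the fitted noise variance, so Z-scores of
#' new observations against this distribution are calibrated. Subjects whose
#' PMA falls more than one week outside the training range trigger a warning
#' (never a refusal).
#'
#' @param object A `normative_model`.
#' @param newdata Subject tibble with `subject_id`, `pma_scan`, `sex`.
#' @param ... Unused.
#' @return Tibble `subject_id`, `parcel_id`, `metric`, `mean`, `variance`.
#' @export
predict.normative_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0L) {
    return(tibble(subject_id = character(), parcel_id = integer(),
                  metric = character(), mean = numeric(),
                  variance = numeric()))
  }
  out_band <- newdata$pma_scan < object$pma_range[1] - 1 |
    newdata$pma_scan > object$pma_range[2] + 1
  if (any(out_band)) {
    warn(sprintf("PMA more than 1 week outside training range for: %s",
                 paste(newdata$subject_id[out_band], collapse = ", ")))
  }
  failed <- object$cells$status == "failed"
  if (any(failed)) {
    bad <- object$cells[failed, c("parcel_id", "metric")]
    abort(paste0("unfitted (failed) cells: ",
                 paste(sprintf("(%s, %s)", bad$parcel_id, bad$metric),
                       collapse = ", ")),
          class = "unfitted_cell")
  }
  Xn <- cbind(pma = (newdata$pma_scan - object$pma_mean) / object$pma_sd,
              sex = newdata$sex)
  Xt <- object$X
  m <- nrow(Xn); n <- nrow(Xt); C <- nrow(object$cells)
  # cross squared distances and inner products, shared across cells
  cross_d2 <- outer(rowSums(Xt^2), rep(1, m)) +
    outer(rep(1, n), rowSums(Xn^2)) - 2 * Xt %*% t(Xn)
  cross_d2 <- pmax(cross_d2, 0)
  cross_xp <- Xt %*% t(Xn)
  diag_xn <- rowSums(Xn^2)

  mu <- matrix(NA_real_, m, C)
  va <- matrix(NA_real_, m, C)
  P <- as.matrix(object$cells[, c("rbf_variance", "rbf_lengthscale",
                                  "linear_variance", "noise_variance")])
  for (j in seq_len(C)) {
    if (object$cells$status[j] == "constant") {
      mu[, j] <- 0
      va[, j] <- P[j, 4]
      next
    }
    p <- P[j, ]
    ks <- p[1] * exp(-cross_d2 / (2 * p[2]^2)) + p[3] * cross_xp
    ch <- .cell_chol(p, object$D2, object$XP)
    v <- forwardsolve(t(ch$L), ks)
    mu[, j] <- crossprod(ks, object$alpha[, j])
    kss <- p[1] + p[3] * diag_xn
    va[, j] <- (pmax(kss - colSums(v^2), 0) + p[4] + ch$jitter) *
      object$cells$var_inflation[j]
  }
  # de-standardize
  y_sd <- object$cells$y_sd
  y_sd[object$cells$status == "constant"] <- 1
  mu <- sweep(sweep(mu, 2, y_sd, `*`), 2, object$cells$y_mean, `+`)
  va <- sweep(va, 2, y_sd^2, `*`)

  tibble(
    subject_id = rep(newdata$subject_id, times = C),
    parcel_id = rep(object$cells$parcel_id, each = m),
    metric = rep(object$cells$metric, each = m),
    mean = as.vector(mu),
    variance = as.vector(va),
    t_df = rep(object$cells$t_df, each = m)
  )
}

#' Hold-out mean absolute error of a normative model
#'
#' @param model A `normative_model`.
#' @param features Long feature tibble for the hold-out subjects.
#' @param subjects Hold-out subject tibble; must be disjoint from the
#'   training subjects.
#' @return Tibble `parcel_id`, `metric`, `mae`, `n`, in metric units.
#' @export
evaluate_mae <- function(model, features, subjects) {
  overlap <- intersect(subjects$subject_id, model$train_subjects)
  if (length(overlap)) {
    abort(paste("hold-out overlaps training set:",
                paste(head(overlap, 5), collapse = ", ")),
          class = "invalid_argument")
  }
  pred <- predict(model, subjects)
  inner_join(features, pred, by = c("subject_id", "parcel_id", "metric")) |>
    group_by(.data$parcel_id, .data$metric) |>
    summarise(mae = mean(abs(.data$value - .data$mean)), n = n(),
              .groups = "drop")
}

#' @rdname tidy.normative_model
#' @export
glance.normative_model <- function(x, ...) {
  tibble(
    n_train = length(x$train_subjects),
    n_cells = nrow(x$cells),
    n_ok = sum(x$cells$status %in% c("ok", "jittered")),
    n_constant = sum(x$cells$status == "constant"),
    n_failed = sum(x$cells$status == "failed"),
    mean_log_marginal_likelihood =
      mean(x$cells$log_marginal_likelihood, na.rm = TRUE)
  )
}

#' Tidy per-cell summaries of a normative model
#'
#' `tidy()` returns one row per (parcel, metric) cell with the optimized
#' kernel hyperparameters. Variances are reported in squared metric units
#' (de-standardized by the per-cell output SD); the lengthscale is in
#' standardized covariate units. `glance()` gives one-row fit diagnostics.
#'
#' @param x A `normative_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.normative_model <- function(x, ...) {
  s2 <- x$cells$y_sd^2
  s2[x$cells$status == "constant"] <- 1
  x$cells |>
    mutate(rbf_variance = .data$rbf_variance * s2,
           linear_variance = .data$linear_variance * s2,
           noise_variance = .data$noise_variance * s2) |>
    select("parcel_id", "metric", "rbf_variance", "rbf_lengthscale",
           "linear_variance", "noise_variance",
           "log_marginal_likelihood", "convergence", "status")
}
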