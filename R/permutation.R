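# sentinel for infinite t-statistics (zero residual variance)
.t_cap <- 1e6

# map a design term name to a numeric column
.design_column <- function(subjects, name) {
  switch(name,
    intercept = rep(1, nrow(subjects)),
    group = as.numeric(subjects$group == "preterm"),
    pma_scan = subjects$pma_scan - mean(subjects$pma_scan),
    group_x_pma = as.numeric(subjects$group == "preterm") *
      (subjects$pma_scan - mean(subjects$pma_scan)),
    {
      if (!name %in% names(subjects)) {
        abort(sprintf("unknown design term `%s`", name),
              class = "invalid_argument")
      }
      v <- subjects[[name]]
      if (!is.numeric(v)) abort(sprintf("design term `%s` is not numeric", name),
                                class = "invalid_argument")
      v
    })
}

# build (tested x, nuisance Z incl. intercept) and check rank
.build_design <- function(subjects, tested, nuisance) {
  if (tested %in% nuisance) {
    abort("tested column cannot also be nuisance", class = "invalid_argument")
  }
  Z <- do.call(cbind, c(list(intercept = rep(1, nrow(subjects))),
                        lapply(setNames(nuisance, nuisance),
                               function(nm) .design_column(subjects, nm))))
  x <- .design_column(subjects, tested)
  X <- cbind(Z, tested = x)
  colnames(X) <- c("intercept", nuisance, tested)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    coll <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    abort(paste("design matrix is rank deficient; collinear column(s):",
                paste(coll, collapse = ", ")),
          class = "rank_error")
  }
  if (nrow(X) < ncol(X) + 1L) {
    abort("need more subjects than design columns (df >= 1)",
          class = "invalid_argument")
  }
  list(x = x, Z = Z, names = colnames(X))
}

# t-statistics of the tested coefficient for residualized data.
# x_res: nuisance-residualized tested covariate; Yr: nuisance-residualized
# data matrix (n x cells); df: n - ncol(full design).
.tested_tstats <- function(x_res, Yr, df) {
  bx <- sum(x_res^2)
  beta <- as.vector(crossprod(x_res, Yr)) / bx
  rss <- pmax(colSums(Yr^2) - beta^2 * bx, 0)
  se <- sqrt(rss / df / bx)
  t <- ifelse(se > 0, beta / se, sign(beta) * .t_cap)
  unname(pmin(pmax(t, -.t_cap), .t_cap))
}

.grab_value_col <- function(table) {
  if ("value" %in% names(table)) return(table)
  if ("z" %in% names(table)) return(rename(table, value = "z"))
  abort("table must carry a `value` (or `z`) column", class = "schema_error")
}

#' Per-parcel GLM t-statistics for a tested covariate
#'
#' Ordinary least squares per (parcel, metric) with the tested column and
#' nuisance covariates (plus intercept); returns the t-statistic of the
#' tested coefficient for both one-sided contrasts, together with the simple
#' bivariate Pearson correlation between the tested covariate and the
#' feature. Cells with zero residual variance get a capped sentinel
#' t-statistic of `1e6`.
#'
#' @param table Long tibble with `subject_id`, `parcel_id`, `metric` and a
#'   `value` (or `z`) column.
#' @param subjects Subject tibble aligned by `subject_id`.
#' @param tested Name of the tested term: a numeric subject column,
#'   `"group"` (preterm indicator), `"pma_scan"` (centred) or
#'   `"group_x_pma"`.
#' @param nuisance Character vector of nuisance terms (same vocabulary).
#' @param partial_r If `TRUE`, report the partial correlation (residualized
#'   on nuisance) instead of the bivariate one.
#' @return Tibble `parcel_id`, `metric`, `contrast`, `t`, `r`, `df`, where
#'   `t` is signed for the contrast (`positive`: tested effect > 0).
#' @export
fit_glm <- function(table, subjects, tested,
                    nuisance = c("pma_scan", "sex"), partial_r = FALSE) {
  table <- .grab_value_col(table)
  fm <- .feature_matrix(table, subject_ids = subjects$subject_id)
  d <- .build_design(subjects, tested, nuisance)
  qz <- qr(d$Z)
  x_res <- qr.resid(qz, d$x)
  Yr <- qr.resid(qz, fm$Y)
  df <- nrow(fm$Y) - ncol(d$Z) - 1L
  t_obs <- .tested_tstats(x_res, Yr, df)
  r <- if (partial_r) {
    as.vector(cor(x_res, Yr))
  } else {
    as.vector(cor(d$x, fm$Y))
  }
  bind_rows(
    bind_cols(fm$cells, tibble(contrast = "positive", t = t_obs, r = r, df = df)),
    bind_cols(fm$cells, tibble(contrast = "negative", t = -t_obs, r = r, df = df))
  )
}

#' Max-statistic permutation inference with joint FWE correction
#'
#' Freedman-Lane scheme: the data are residualized on the nuisance
#' covariates, the residuals are permuted, and the full model is refitted
#' per permutation. Each permutation records the maximum |t| over all
#' parcels x metrics, and both one-sided contrasts are referred to this
#' single max-|t| distribution, giving family-wise error control jointly
#' across parcels, the 8 modalities and the two contrasts. The corrected
#' p-value uses the +1/+1 convention (`p = (1 + #\{max >= t\}) / (1 +
#' n_perm)`, the identity permutation standing in for the observed data), so
#' p is never zero and the test is exact under exchangeability.
#'
#' @inheritParams fit_glm
#' @param n_perm Number of random permutations (at least 100; the tail is
#'   unstable below that).
#' @param seed Integer seed for the permutations.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Object of class `perm_glm`; `tidy()` gives `parcel_id`, `metric`,
#'   `contrast`, `t`, `r`, `p_mcfwe`, `significant`.
#' @export
permutation_test <- function(table, subjects, tested,
                             nuisance = c("pma_scan", "sex"),
                             n_perm = 1000L, seed = 1L, alpha = 0.05,
                             partial_r = FALSE) {
  n_perm <- .assert_count(n_perm, "n_perm", min = 1L)
  if (n_perm < 100L) {
    abort("n_perm must be at least 100 (permutation tail too unstable)",
          class = "invalid_argument")
  }
  seed <- .assert_count(seed, "seed")
  table <- .grab_value_col(table)
  fm <- .feature_matrix(table, subject_ids = subjects$subject_id)
  d <- .build_design(subjects, tested, nuisance)
  qz <- qr(d$Z)
  x_res <- qr.resid(qz, d$x)
  Yr <- qr.resid(qz, fm$Y)
  n <- nrow(fm$Y)
  df <- n - ncol(d$Z) - 1L
  t_obs <- .tested_tstats(x_res, Yr, df)

  set.seed(seed)
  max_stat <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    W <- Yr[sample.int(n), , drop = FALSE]
    Wr <- qr.resid(qz, W)   # refit: re-residualize permuted data on nuisance
    max_stat[b] <- max(abs(.tested_tstats(x_res, Wr, df)))
  }

  p_pos <- (1 + vapply(t_obs, function(t) sum(max_stat >= t), 0)) / (1 + n_perm)
  p_neg <- (1 + vapply(-t_obs, function(t) sum(max_stat >= t), 0)) / (1 + n_perm)
  r <- as.vector(cor(d$x, fm$Y))

  stat_map <- bind_rows(
    bind_cols(fm$cells, tibble(contrast = "positive", t = t_obs, r = r,
                               p_mcfwe = p_pos)),
    bind_cols(fm$cells, tibble(contrast = "negative", t = -t_obs, r = r,
                               p_mcfwe = p_neg))
  ) |> mutate(significant = .data$p_mcfwe < alpha)

  structure(list(stat_map = stat_map, max_stat = max_stat, df = df,
                 n_perm = n_perm, seed = seed, alpha = alpha,
                 tested = tested, nuisance = nuisance,
                 design_names = d$names),
            class = "perm_glm")
}

#' Group-by-age interaction permutation test
#'
#' Tests whether developmental slopes differ between groups: the tested
#' column is the product of the preterm indicator and centred PMA at scan,
#' with group, PMA and sex as nuisance. PMA is centred before the product is
#' formed.
#'
#' @inheritParams permutation_test
#' @return A `perm_glm` object (see [permutation_test()]).
#' @export
interaction_test <- function(table, subjects, n_perm = 1000L, seed = 1L,
                             alpha = 0.05) {
  permutation_test(table, subjects, tested = "group_x_pma",
                   nuisance = c("group", "pma_scan", "sex"),
                   n_perm = n_perm, seed = seed, alpha = alpha)
}

#' @export
print.perm_glm <- function(x, ...) {
  n_sig <- sum(x$stat_map$significant)
  cat(sprintf(paste0("Max-statistic permutation GLM (Freedman-Lane)\n",
                     "  tested: %s | nuisance: %s\n",
                     "  %d permutations, seed %d, df %d\n",
                     "  %d significant (parcel, metric, contrast) cells at ",
                     "alpha = %g\n"),
              x$tested, paste(x$nuisance, collapse = ", "),
              x$n_perm, x$seed, x$df, n_sig, x$alpha))
  invisible(x)
}

#' Tidy a permutation GLM result
#'
#' @param x A `perm_glm` object.
#' @param ... Unused.
#' @return `tidy()`: the corrected statistic map (one row per parcel, metric
#'   and contrast). `glance()`: one-row summary.
#' @export
tidy.perm_glm <- function(x, ...) x$stat_map

#' @rdname tidy.perm_glm
#' @export
glance.perm_glm <- function(x, ...) {
  tibble(tested = x$tested, n_perm = x$n_perm, seed = x$seed,
         alpha = x$alpha, df = x$df,
         n_significant = sum(x$stat_map$significant),
         min_p_mcfwe = min(x$stat_map$p_mcfwe))
}
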