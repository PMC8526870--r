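# brute-force Kendall tau-b oracle over all pairs
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

indices_from <- function(values, metric = "MD") {
  tibble::tibble(subject_id = sprintf("s%02d", seq_along(values)),
                 metric = metric, pos_index = values, neg_index = 0)
}

subjects_from <- function(ga, group = "preterm") {
  tibble::tibble(subject_id = sprintf("s%02d", seq_along(ga)),
                 group = group, ga_birth = ga, pma_scan = 40,
                 sex = rep_len(0:1, length(ga)))
}

test_that("Kendall correlations match a brute-force pair enumeration", {
  # perfectly concordant / discordant
  r1 <- index_correlation(indices_from(1:6), subjects_from(1:6), "ga_birth")
  expect_equal(r1$kendall_tau[r1$index_sign == "pos_index"], 1)
  r2 <- index_correlation(indices_from(6:1), subjects_from(1:6), "ga_birth")
  expect_equal(r2$kendall_tau[r2$index_sign == "pos_index"], -1)

  # partly discordant, with ties: compare against the enumeration oracle
  y <- c(1, 3, 2, 4, 4, 6)
  r3 <- index_correlation(indices_from(y), subjects_from(1:6), "ga_birth")
  expect_equal(r3$kendall_tau[r3$index_sign == "pos_index"],
               tau_b_oracle(1:6, y), tolerance = 1e-12)

  # the classic 4-point example: tau = 2/3
  expect_equal(tau_b_oracle(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  r4 <- index_correlation(indices_from(c(1, 3, 2, 4, 5)),
                          subjects_from(1:5), "ga_birth")
  expect_equal(r4$kendall_tau[r4$index_sign == "pos_index"],
               tau_b_oracle(1:5, c(1, 3, 2, 4, 5)), tolerance = 1e-12)

  # an all-tied index is reported as missing with a reason
  r5 <- index_correlation(indices_from(rep(2, 6)), subjects_from(1:6),
                          "ga_birth")
  expect_true(is.na(r5$kendall_tau[r5$index_sign == "pos_index"]))
  expect_equal(r5$note[r5$index_sign == "pos_index"], "all tied")
})

test_that("tau is invariant under strictly monotone transforms", {
  set.seed(8)
  v <- runif(12, 0, 20)
  ga <- runif(12, 23, 37)
  a <- index_correlation(indices_from(v), subjects_from(ga), "ga_birth")
  b <- index_correlation(indices_from(v^3 + 1), subjects_from(ga), "ga_birth")
  expect_equal(a$kendall_tau, b$kendall_tau)
})

test_that("Mann-Whitney group tests match exact enumeration on a toy", {
  idx <- indices_from(c(1, 2, 3, 4, 5, 6))
  subj <- subjects_from(1:6)
  subj$group <- rep(c("preterm", "term"), each = 3)
  # preterm (1,2,3) vs term (4,5,6): U = 0, exact two-sided p = 2/20
  res <- index_group_test(idx, subj)
  row <- res[res$index_sign == "pos_index", ]
  expect_equal(row$mann_whitney_U, 0)
  expect_equal(row$p_raw, 0.1)
  expect_true(all(res$p_fdr >= res$p_raw - 1e-12))

  # identical groups: p close to 1
  idx2 <- indices_from(rep(c(1, 2, 3), 2))
  res2 <- index_group_test(idx2, subj)
  expect_gt(min(res2$p_raw[res2$index_sign == "pos_index"]), 0.9)

  expect_error(index_group_test(idx, dplyr::mutate(subj, group = "preterm")),
               class = "invalid_argument")
})

test_that("U is invariant under strictly monotone transforms", {
  set.seed(9)
  idx <- indices_from(runif(14, 0, 30))
  subj <- subjects_from(runif(14, 23, 42))
  subj$group <- rep(c("preterm", "term"), 7)
  u1 <- index_group_test(idx, subj)
  idx2 <- idx; idx2$pos_index <- exp(idx2$pos_index / 10)
  u2 <- index_group_test(idx2, subj)
  expect_equal(u1$mann_whitney_U, u2$mann_whitney_U)
})

test_that("BH adjustment applies the step-up rule with monotonicity", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.011, 0.02, 0.04, 0.13)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "invalid_argument")
})

test_that("Z-covariate maps refuse constant covariates and recover GA signal", {
  sim <- tiny_sim(30, 12, parcels = 7, seed = 21)
  const <- dplyr::mutate(sim$subjects, ga_birth = 30)
  z <- sim$features |> dplyr::rename(z = value)
  expect_error(z_covariate_map(z, const, "ga_birth", n_perm = 100, seed = 1),
               class = "invalid_argument")

  # GA-graded MD effect in preterm subjects should surface as significant
  cfg <- tiny_config(seed = 22)
  cfg$preterm_effect["MD", ] <- 1.5  # strong, GA-scaled
  sim2 <- simulate_cohort(0, 60, n_parcels_per_hemisphere = 7,
                          config = cfg, seed = 22)
  # deviations relative to a flat reference: use raw values as pseudo-Z
  zz <- sim2$features |> dplyr::rename(z = value)
  res <- z_covariate_map(zz, sim2$subjects, "ga_birth", nuisance = "sex",
                         n_perm = 300, seed = 2)
  md <- dplyr::filter(tidy(res), metric == "MD", contrast == "negative")
  expect_gt(mean(md$significant), 0.8)
})
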