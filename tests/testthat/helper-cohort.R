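# small cohort builders shared across test files

tiny_config <- function(seed = 1L, ...) {
  default_effect_config(seed = seed, extreme_rate = 0, ...)
}

tiny_sim <- function(n_term = 30, n_preterm = 10, parcels = 8, seed = 1L,
                     config = tiny_config(seed)) {
  simulate_cohort(n_term, n_preterm, n_parcels_per_hemisphere = parcels,
                  config = config, seed = seed)
}

# single-cell feature table from explicit values (one parcel, one metric)
one_cell_features <- function(y, metric = "FA", parcel_id = 0L) {
  tibble::tibble(subject_id = sprintf("s%03d", seq_along(y)),
                 parcel_id = parcel_id, metric = metric, value = y)
}

one_cell_subjects <- function(pma, sex = rep(0L, length(pma))) {
  tibble::tibble(subject_id = sprintf("s%03d", seq_along(pma)),
                 group = "term", ga_birth = 40, pma_scan = pma, sex = sex)
}

# closed-form Bayesian linear regression oracle: y = X w + e,
# w ~ N(0, prior_var I), e ~ N(0, noise_var); returns predictive mean and
# variance (noise included) at Xs.
blr_oracle <- function(X, y, Xs, prior_var, noise_var) {
  S <- solve(crossprod(X) / noise_var + diag(1 / prior_var, ncol(X)))
  mu <- Xs %*% S %*% crossprod(X, y) / noise_var
  va <- rowSums((Xs %*% S) * Xs) + noise_var
  list(mean = as.vector(mu), variance = as.vector(va))
}
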