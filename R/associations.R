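#' Parcel-wise association between Z-scores and a subject covariate
#'
#' Permutation GLM (see [permutation_test()]) with the covariate as tested
#' column, run on the deviation Z-scores of a chosen sample — typically the
#' preterm group, the term hold-out group, or both combined.
#'
#' @param z Z-score tibble from [compute_z_scores()].
#' @param subjects Subject tibble covering the scored subjects.
#' @param covariate Tested covariate: `"ga_birth"` or one of the outcome
#'   scores (`"bsid_motor"`, `"bsid_language"`, `"bsid_cognitive"`).
#' @param nuisance Nuisance terms; default sex only (Z already accounts for
#'   PMA through the normative model).
#' @inheritParams permutation_test
#' @return A `perm_glm` object.
#' @export
z_covariate_map <- function(z, subjects, covariate = "ga_birth",
                            nuisance = "sex", n_perm = 1000L, seed = 1L,
                            alpha = 0.05) {
  v <- .design_column(subjects, covariate)
  if (sd(v) == 0) {
    abort(sprintf("covariate `%s` is constant", covariate),
          class = "invalid_argument")
  }
  subjects <- filter(subjects, .data$subject_id %in% unique(z$subject_id))
  permutation_test(z, subjects, tested = covariate, nuisance = nuisance,
                   n_perm = n_perm, seed = seed, alpha = alpha)
}

#' Rank correlation between atypicality indices and a covariate
#'
#' Kendall tau-b (tie-corrected; exact p where the data permit, normal
#' approximation otherwise) between each per-metric atypicality index and a
#' subject covariate, with Benjamini-Hochberg FDR over the full family of
#' (metric x index sign x covariate) hypotheses tested in the call.
#'
#' @param indices Atypicality tibble from [atypicality_indices()].
#' @param subjects Subject tibble.
#' @param covariates Character vector of covariate columns (e.g.
#'   `"ga_birth"`, `"bsid_motor"`).
#' @return Tibble `covariate`, `metric`, `index_sign`, `kendall_tau`,
#'   `p_raw`, `p_fdr`, `n`, `note`.
#' @export
index_correlation <- function(indices, subjects, covariates = "ga_birth") {
  long <- indices |>
    select("subject_id", "metric", "pos_index", "neg_index") |>
    pivot_longer(c("pos_index", "neg_index"),
                 names_to = "index_sign", values_to = "index") |>
    inner_join(subjects, by = "subject_id")
  if (n_distinct(long$subject_id) < 5L) {
    abort("need at least 5 subjects", class = "invalid_argument")
  }
  res <- crossing(covariate = covariates,
                  metric = unique(indices$metric),
                  index_sign = c("pos_index", "neg_index")) |>
    mutate(row = purrr::pmap(list(.data$covariate, .data$metric,
                                  .data$index_sign), function(cv, m, s) {
      d <- long[long$metric == m & long$index_sign == s, ]
      x <- d[[cv]]
      y <- d$index
      keep <- is.finite(x) & is.finite(y)
      x <- x[keep]; y <- y[keep]
      if (length(unique(y)) < 2L || length(unique(x)) < 2L) {
        return(tibble(kendall_tau = NA_real_, p_raw = NA_real_,
                      n = length(x), note = "all tied"))
      }
      ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
      tibble(kendall_tau = unname(ct$estimate), p_raw = ct$p.value,
             n = length(x), note = NA_character_)
    })) |>
    tidyr::unnest("row")
  res$p_fdr <- NA_real_
  ok <- !is.na(res$p_raw)
  res$p_fdr[ok] <- bh_fdr(res$p_raw[ok])
  res
}

#' Group comparison of atypicality indices
#'
#' Two-sided Mann-Whitney U tests (exact where sample sizes and ties permit,
#' tie-corrected normal approximation otherwise) comparing each per-metric
#' index between two groups, with BH-FDR over metrics x index signs.
#'
#' @param indices Atypicality tibble.
#' @param subjects Subject tibble with a `group` column.
#' @param groups Length-2 character vector naming the two compared groups;
#'   U is reported for the first.
#' @return Tibble `metric`, `index_sign`, `mann_whitney_U`, `p_raw`, `p_fdr`,
#'   `n1`, `n2`.
#' @export
index_group_test <- function(indices, subjects,
                             groups = c("preterm", "term")) {
  long <- indices |>
    select("subject_id", "metric", "pos_index", "neg_index") |>
    pivot_longer(c("pos_index", "neg_index"),
                 names_to = "index_sign", values_to = "index") |>
    inner_join(select(subjects, "subject_id", "group"), by = "subject_id") |>
    filter(.data$group %in% groups)
  n_by <- long |> distinct(.data$subject_id, .data$group) |> count(.data$group)
  if (nrow(n_by) < 2L || any(n_by$n < 2L)) {
    abort("both groups need at least 2 subjects", class = "invalid_argument")
  }
  res <- crossing(metric = unique(indices$metric),
                  index_sign = c("pos_index", "neg_index")) |>
    mutate(row = purrr::map2(.data$metric, .data$index_sign, function(m, s) {
      d <- long[long$metric == m & long$index_sign == s, ]
      x <- d$index[d$group == groups[1]]
      y <- d$index[d$group == groups[2]]
      wt <- suppressWarnings(wilcox.test(x, y, exact = NULL))
      # fully tied samples make the normal approximation degenerate (p = NA);
      # there is no evidence against the null in that case
      p <- if (is.finite(wt$p.value)) wt$p.value else 1
      tibble(mann_whitney_U = unname(wt$statistic), p_raw = p,
             n1 = length(x), n2 = length(y))
    })) |>
    tidyr::unnest("row")
  res$p_fdr <- bh_fdr(res$p_raw)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, as implemented by
#' [stats::p.adjust()] with `method = "BH"`; input validation rejects
#' p-values outside `[0, 1]`.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) ||
      any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    abort("p-values must lie in [0, 1]", class = "invalid_argument")
  }
  p.adjust(p_values, method = "BH")
}
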