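#' Individual deviation Z-scores against a normative prediction
#'
#' `Z = (observed - predictive mean) / sqrt(predictive variance)`, so a
#' positive Z means the observation lies above the normative curve. The
#' reverse orientation (prediction minus observation) is available via
#' `sign = "pred_minus_obs"`.
#'
#' When the prediction carries a `t_df` column (as
#' [predict.normative_model()] emits when fitted with `df_correction =
#' TRUE`), the ratio is additionally mapped through its t reference
#' distribution onto the standard-normal scale,
#' `Z = qnorm(pt(ratio, t_df))`: with an estimated residual scale the raw
#' ratio is a studentized residual and t-distributed rather than normal, and
#' without the mapping the nominal tail probability of a threshold like 3.1
#' is overshot. The mapping is the identity for infinite `t_df` and can be
#' disabled with `calibrate = FALSE`.
#'
#' @param pred Predictive tibble from [predict.normative_model()].
#' @param observed Long feature tibble aligned on subject/parcel/metric.
#' @param sign Orientation of the deviation; default `"obs_minus_pred"`.
#' @param calibrate Apply the studentized-to-normal mapping when `t_df` is
#'   available (default `TRUE`).
#' @return Tibble `subject_id`, `parcel_id`, `metric`, `z`.
#' @export
compute_z_scores <- function(pred, observed,
                             sign = c("obs_minus_pred", "pred_minus_obs"),
                             calibrate = TRUE) {
  sign <- match.arg(sign)
  bad <- pred$variance <= 0
  if (any(bad)) {
    abort(paste0("non-positive predictive variance at: ",
                 paste(sprintf("(%s, %s, %s)", pred$subject_id[bad],
                               pred$parcel_id[bad], pred$metric[bad])[
                                 seq_len(min(5, sum(bad)))],
                       collapse = ", ")),
          class = "invalid_argument")
  }
  z <- inner_join(observed, pred, by = c("subject_id", "parcel_id", "metric"))
  if (nrow(z) != nrow(pred) || nrow(z) != nrow(observed)) {
    abort("predictions and observations are not aligned",
          class = "invalid_argument")
  }
  flip <- if (sign == "obs_minus_pred") 1 else -1
  z <- z |>
    mutate(z = flip * (.data$value - .data$mean) / sqrt(.data$variance))
  if (calibrate && "t_df" %in% names(z)) {
    z$z <- .studentized_to_normal(z$z, z$t_df)
  }
  select(z, "subject_id", "parcel_id", "metric", "z")
}

# map a studentized ratio through its t reference distribution onto the
# standard-normal scale; identity for infinite df, tail-safe via log.p
.studentized_to_normal <- function(x, df) {
  df <- ifelse(is.na(df), Inf, df)
  out <- x
  finite <- is.finite(df) & is.finite(x)
  if (any(finite)) {
    lx <- pt(-abs(x[finite]), df[finite], log.p = TRUE)
    out[finite] <- -sign(x[finite]) * qnorm(lx, log.p = TRUE)
  }
  out
}

#' Classify extreme deviations
#'
#' Three-way labelling with strict inequalities: `+1` where `z > threshold`,
#' `-1` where `z < -threshold`, `0` otherwise (so `|z|` exactly at the
#' threshold is normative). The default threshold 3.1 corresponds to a
#' one-sided normal tail probability below 0.001.
#'
#' @param z Z-score tibble from [compute_z_scores()].
#' @param threshold Positive deviation threshold (default 3.1).
#' @return The input tibble with an integer `label` column.
#' @export
classify_extremes <- function(z, threshold = 3.1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("threshold must be a single positive number",
          class = "invalid_argument")
  }
  z |>
    mutate(label = (.data$z > threshold) - (.data$z < -threshold)) |>
    mutate(label = as.integer(.data$label))
}

#' One-sided normal tail probability of the extreme-deviation threshold
#'
#' @param threshold Deviation threshold on the Z scale (default 3.1).
#' @return `P(Z > threshold)` for standard-normal Z.
#' @examples
#' extreme_threshold_tail_prob(3.1) # < 0.001
#' @export
extreme_threshold_tail_prob <- function(threshold = 3.1) {
  pnorm(threshold, lower.tail = FALSE)
}

#' Group overlap map of extreme deviations
#'
#' For each parcel and metric, the percentage of the group's infants with an
#' extreme positive (resp. negative) deviation there. The denominator is the
#' total number of scored infants in the group, not a per-parcel count.
#'
#' @param mask Labelled tibble from [classify_extremes()].
#' @param group_subjects Character vector of subject ids defining the group.
#' @return Tibble of class `overlap_map`: `parcel_id`, `metric`,
#'   `percent_pos`, `percent_neg`, `n_group`.
#' @export
overlap_map <- function(mask, group_subjects) {
  group_subjects <- unique(group_subjects)
  if (length(group_subjects) == 0L) {
    abort("group is empty", class = "invalid_argument")
  }
  n_group <- length(group_subjects)
  out <- mask |>
    filter(.data$subject_id %in% group_subjects) |>
    group_by(.data$parcel_id, .data$metric) |>
    summarise(percent_pos = 100 * sum(.data$label == 1L) / n_group,
              percent_neg = 100 * sum(.data$label == -1L) / n_group,
              .groups = "drop") |>
    mutate(n_group = n_group)
  class(out) <- c("overlap_map", class(out))
  out
}

#' Whole-cortex atypicality indices
#'
#' For each subject and metric, the percentage of parcels with extreme
#' positive (resp. negative) deviations out of the total parcel count; an
#' infant with 29 extreme-negative parcels out of 286 has a negative index of
#' 10.14% (10% rounded). Parcels missing from the mask (e.g. failed normative
#' fits) count as normative; the denominator is always `n_parcels`.
#'
#' @param mask Labelled tibble from [classify_extremes()].
#' @param n_parcels Total parcel count; defaults to the number of distinct
#'   parcels in `mask`.
#' @return Tibble of class `atypicality`: `subject_id`, `metric`,
#'   `pos_index`, `neg_index`, plus integer-rounded companions
#'   `pos_index_rounded`, `neg_index_rounded`.
#' @export
atypicality_indices <- function(mask, n_parcels = dplyr::n_distinct(mask$parcel_id)) {
  n_parcels <- .assert_count(n_parcels, "n_parcels", min = 1L)
  out <- mask |>
    group_by(.data$subject_id, .data$metric) |>
    summarise(pos_index = 100 * sum(.data$label == 1L) / n_parcels,
              neg_index = 100 * sum(.data$label == -1L) / n_parcels,
              .groups = "drop") |>
    mutate(pos_index_rounded = as.integer(round(.data$pos_index)),
           neg_index_rounded = as.integer(round(.data$neg_index)))
  class(out) <- c("atypicality", class(out))
  out
}
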