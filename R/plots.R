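#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_ribbon geom_tile
#' @importFrom ggplot2 geom_boxplot geom_abline facet_wrap facet_grid labs
#' @importFrom ggplot2 scale_fill_gradient2 scale_fill_viridis_c theme_minimal
#' @importFrom ggplot2 coord_equal
NULL

#' Plot a spherical parcellation
#'
#' Projects the parcel seed coordinates onto the x-y plane, coloured by
#' region and faceted by hemisphere.
#'
#' @param object A `parcel_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parcel_set <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, colour = .data$region)) +
    geom_point(size = 2) +
    facet_wrap(~hemisphere) +
    coord_equal() +
    theme_minimal() +
    labs(title = "Cortical parcellation (dome projection)",
         x = NULL, y = NULL)
}

#' Plot an extreme-deviation overlap map
#'
#' Heatmap of the percentage of infants with extreme positive and negative
#' deviations per parcel and metric.
#'
#' @param object An `overlap_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_map <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("percent_pos", "percent_neg"),
                        names_to = "direction", values_to = "percent") |>
    mutate(direction = ifelse(.data$direction == "percent_pos",
                              "positive", "negative"))
  ggplot(long, aes(x = .data$parcel_id, y = .data$metric,
                   fill = .data$percent)) +
    geom_tile() +
    facet_wrap(~direction, ncol = 1) +
    scale_fill_viridis_c(name = "% of infants") +
    theme_minimal() +
    labs(title = "Spatial overlap of extreme deviations",
         x = "parcel", y = NULL)
}

#' Plot a permutation GLM statistic map
#'
#' t-statistics per parcel and metric for the positive contrast, with
#' FWE-significant cells highlighted.
#'
#' @param object A `perm_glm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_glm <- function(object, ...) {
  pos <- filter(object$stat_map, .data$contrast == "positive")
  ggplot(pos, aes(x = .data$parcel_id, y = .data$metric, fill = .data$t)) +
    geom_tile() +
    geom_point(data = filter(object$stat_map, .data$significant),
               aes(x = .data$parcel_id, y = .data$metric),
               inherit.aes = FALSE, shape = 4, size = 1) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    theme_minimal() +
    labs(title = sprintf("Permutation GLM: %s (x = p_mcfwe < %g)",
                         object$tested, object$alpha),
         x = "parcel", y = NULL)
}

#' Plot atypicality indices by group
#'
#' @param indices An `atypicality` tibble.
#' @param subjects Subject tibble with a `group` column.
#' @return A ggplot with one box per group, metric and index sign.
#' @export
plot_atypicality <- function(indices, subjects) {
  long <- indices |>
    select("subject_id", "metric", "pos_index", "neg_index") |>
    tidyr::pivot_longer(c("pos_index", "neg_index"),
                        names_to = "index_sign", values_to = "index") |>
    inner_join(select(subjects, "subject_id", "group"), by = "subject_id")
  ggplot(long, aes(x = .data$metric, y = .data$index, fill = .data$group)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~index_sign, ncol = 1) +
    theme_minimal() +
    labs(title = "Whole-cortex atypicality indices",
         x = NULL, y = "% of parcels")
}

#' Plot corrected age predictions against true age
#'
#' @param object An `age_pred_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.age_pred_report <- function(object, ...) {
  ggplot(object$predictions,
         aes(x = .data$true_pma, y = .data$corrected_pred)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point() +
    theme_minimal() +
    labs(title = sprintf("Age prediction (MAE %.2f wk, rho %.2f)",
                         object$mae, object$spearman_rho),
         x = "true PMA (weeks)", y = "bias-corrected prediction (weeks)")
}

#' Plot a normative trajectory for one parcel and metric
#'
#' Shows the observed training values against PMA together with the GP
#' predictive mean and a 95% band (including observation noise), at a fixed
#' sex.
#'
#' @param model A `normative_model`.
#' @param features,subjects The training data used to fit the model.
#' @param parcel_id,metric Cell to display.
#' @param sex Sex (0/1) at which the normative curve is evaluated.
#' @return A ggplot.
#' @export
plot_normative_fit <- function(model, features, subjects, parcel_id, metric,
                               sex = 0) {
  grid <- tibble(
    subject_id = sprintf("grid-%03d", 1:60),
    pma_scan = seq(model$pma_range[1], model$pma_range[2], length.out = 60),
    sex = sex)
  pred <- predict(model, grid) |>
    filter(.data$parcel_id == !!parcel_id, .data$metric == !!metric) |>
    inner_join(grid, by = "subject_id")
  obs <- features |>
    filter(.data$parcel_id == !!parcel_id, .data$metric == !!metric) |>
    inner_join(subjects, by = "subject_id")
  ggplot(pred, aes(x = .data$pma_scan)) +
    geom_ribbon(aes(ymin = .data$mean - 1.96 * sqrt(.data$variance),
                    ymax = .data$mean + 1.96 * sqrt(.data$variance)),
                fill = "steelblue", alpha = 0.2) +
    geom_line(aes(y = .data$mean), colour = "steelblue") +
    geom_point(data = obs, aes(y = .data$value), size = 1) +
    theme_minimal() +
    labs(title = sprintf("Normative trajectory: %s, parcel %d", metric,
                         parcel_id),
         x = "PMA at scan (weeks)", y = metric)
}
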