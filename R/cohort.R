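# inverse-CDF truncated normal, deterministic under set.seed
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Sample term and preterm neonatal demographics
#'
#' Draws subject records mimicking a term-equivalent-age neonatal imaging
#' cohort: gestational age (GA) at birth within 37-42.14 weeks for term and
#' 23-36.86 weeks for preterm infants, postmenstrual age (PMA) at scan drawn
#' from a common scan window independent of group (the groups are
#' age-matched at scan), roughly 46% females, and 18-month composite outcome
#' scores with population mean 100 and SD 15.
#'
#' @param n_term,n_preterm Number of term-born / preterm subjects.
#' @param seed Integer seed.
#' @param outcome_ga_coupling Slope (score points per week of GA) linking
#'   outcome scores to GA at birth; 0 (default) makes outcomes independent
#'   of prematurity so that association stages can be tested under the null.
#' @param scan_window Two-element PMA window (weeks) for the scan.
#' @return Tibble with columns `subject_id`, `group`, `ga_birth`, `pma_scan`,
#'   `sex` (0 = female, 1 = male), `bsid_motor`, `bsid_language`,
#'   `bsid_cognitive`.
#' @examples
#' demo <- sample_demographics(20, 8, seed = 7)
#' table(demo$group)
#' @export
sample_demographics <- function(n_term, n_preterm, seed = 1L,
                                outcome_ga_coupling = 0,
                                scan_window = c(37, 45.14)) {
  n_term <- .assert_count(n_term, "n_term")
  n_preterm <- .assert_count(n_preterm, "n_preterm")
  if (n_term + n_preterm < 1L) {
    abort("need at least one subject", class = "invalid_argument")
  }
  seed <- .assert_count(seed, "seed")
  set.seed(seed)

  n <- n_term + n_preterm
  group <- c(rep("term", n_term), rep("preterm", n_preterm))
  ga <- c(.rtruncnorm(n_term, 40.1, 1.2, 37, 42.14),
          .rtruncnorm(n_preterm, 32.0, 3.5, 23, 36.86))
  # scanned at term-equivalent age, never before birth
  pma <- .rtruncnorm(n, 40.9, 1.8, pmax(scan_window[1], ga), scan_window[2])
  sex <- rbinom(n, 1L, 0.54)  # 46% female (sex = 0)
  outc <- function() {
    pmin(pmax(100 + outcome_ga_coupling * (ga - 40) + rnorm(n, 0, 15), 55), 145)
  }
  tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    group = group,
    ga_birth = ga,
    pma_scan = pma,
    sex = sex,
    bsid_motor = outc(),
    bsid_language = outc(),
    bsid_cognitive = outc()
  )
}

#' Constant metric-by-region effect matrix
#'
#' Convenience constructor for the 8 metric x 7 region matrices used in an
#' [default_effect_config()] (baselines, slopes, group effects, noise SDs).
#'
#' @param value Fill value (recycled).
#' @return An 8 x 7 matrix with metric row names and region column names.
#' @examples
#' no_effect <- metric_region_matrix(0)
#' @export
metric_region_matrix <- function(value = 0) {
  matrix(value, nrow = length(cortical_metrics),
         ncol = length(cortical_regions),
         dimnames = list(cortical_metrics, cortical_regions))
}

.mr_matrix <- metric_region_matrix

#' Generative effect configuration for the synthetic cohort
#'
#' Bundles the ground-truth generative model: per metric x region baselines,
#' linear PMA slopes (per week, PMA centred at 40 weeks), additive sex
#' effects, preterm effects at maximal prematurity (scaled linearly by
#' `max(0, 37 - GA)/14` so GA 23 receives the full effect), iid Gaussian
#' noise SDs, and sparse extreme-deviation injection. Values are in metric
#' units (MD um^2/ms, thickness mm, SA mm^2, others dimensionless).
#'
#' Defaults encode the qualitative maturational pattern of the late third
#' trimester: strong surface expansion everywhere, cortical thickening,
#' falling FA posteriorly, falling MD centrally, rising orientation
#' dispersion widespread, rising neurite density anteriorly/insular, deeper
#' sulci in the cingulate; preterm birth raises MD and lowers fICVF
#' posteriorly, thickens anterior cortex, and raises FA / lowers ODI in the
#' insula. A cortical thickness baseline of 1.1 mm reflects the neonatal
#' cortical sheet.
#'
#' @param seed Integer seed used by [generate_features()].
#' @param extreme_rate Probability per (subject, metric) of injecting an
#'   extreme deviation (in 1 to `extreme_parcels_max` parcels).
#' @param extreme_magnitude_range Offset magnitude range in multiples of the
#'   local noise SD; the lower bound must exceed 3.1.
#' @param extreme_sign_fidelity Probability that an injected offset follows
#'   the metric's configured preterm direction (else the sign is flipped).
#' @param extreme_subjects `"preterm"` (default) or `"all"`.
#' @param extreme_parcels_max Maximum parcels hit by one injection event.
#' @param prematurity_scaling If `FALSE`, preterm effects are applied at full
#'   strength for every preterm subject instead of scaling with GA.
#' @param group_effect_parcels Optional tibble (`metric`, `parcel_id`,
#'   `effect`) of parcel-targeted group effects added on top of (or instead
#'   of) the region-level `preterm_effect`.
#' @param ... Named overrides for any stored component (`baseline`,
#'   `age_slope`, `sex_effect`, `preterm_effect`, `noise_sd`,
#'   `preterm_direction`, `pma_support`).
#' @return A list of class `effect_config`.
#' @export
default_effect_config <- function(seed = 1L,
                                  extreme_rate = 0.10,
                                  extreme_magnitude_range = c(4, 8),
                                  extreme_sign_fidelity = 0.75,
                                  extreme_subjects = c("preterm", "all"),
                                  extreme_parcels_max = 3L,
                                  prematurity_scaling = TRUE,
                                  group_effect_parcels = NULL,
                                  ...) {
  posterior <- c("parietal", "temporal", "occipital", "somatosensory")

  baseline <- .mr_matrix(0)
  baseline["FA", ] <- 0.15;  baseline["MD", ] <- 1.10
  baseline["ODI", ] <- 0.40; baseline["fICVF", ] <- 0.50
  baseline["thickness", ] <- 1.1; baseline["SA", ] <- 120
  baseline["curvature", ] <- 0.30; baseline["sulcation", ] <- 0.50

  age_slope <- .mr_matrix(0)
  age_slope["FA", posterior] <- -0.004
  age_slope["MD", c("somatosensory", "insula")] <- -0.020
  age_slope["ODI", ] <- 0.008
  age_slope["fICVF", c("insula", "frontal")] <- 0.008
  age_slope["thickness", ] <- 0.015
  age_slope["SA", ] <- 4.0
  age_slope["sulcation", "cingulate"] <- 0.010

  sex_effect <- setNames(numeric(8), cortical_metrics)
  sex_effect["SA"] <- 3; sex_effect["thickness"] <- 0.01
  sex_effect["MD"] <- -0.005

  preterm_effect <- .mr_matrix(0)
  preterm_effect["MD", posterior] <- 0.06
  preterm_effect["fICVF", posterior] <- -0.06
  preterm_effect["thickness", c("frontal", "insula", "parietal")] <- 0.12
  preterm_effect["FA", "insula"] <- 0.015
  preterm_effect["ODI", "insula"] <- -0.03

  noise_sd <- .mr_matrix(0)
  noise_sd["FA", ] <- 0.015; noise_sd["MD", ] <- 0.04
  noise_sd["ODI", ] <- 0.03; noise_sd["fICVF", ] <- 0.04
  noise_sd["thickness", ] <- 0.08; noise_sd["SA", ] <- 10
  noise_sd["curvature", ] <- 0.02; noise_sd["sulcation", ] <- 0.05

  preterm_direction <- setNames(
    c(1, 1, -1, -1, 1, -1, -1, 1), cortical_metrics)

  cfg <- list(
    baseline = baseline, age_slope = age_slope, sex_effect = sex_effect,
    preterm_effect = preterm_effect, noise_sd = noise_sd,
    preterm_direction = preterm_direction,
    extreme_rate = extreme_rate,
    extreme_magnitude_range = extreme_magnitude_range,
    extreme_sign_fidelity = extreme_sign_fidelity,
    extreme_subjects = match.arg(extreme_subjects),
    extreme_parcels_max = as.integer(extreme_parcels_max),
    prematurity_scaling = isTRUE(prematurity_scaling),
    group_effect_parcels = group_effect_parcels,
    pma_support = c(35, 47),
    seed = .assert_count(seed, "seed")
  )
  cfg <- modifyList(cfg, list(...))
  class(cfg) <- "effect_config"
  validate_effect_config(cfg)
  cfg
}

#' Validate an effect configuration
#'
#' @param config An `effect_config` list.
#' @return The config, invisibly; aborts with class `config_error` on an
#'   incomplete or inconsistent configuration.
#' @export
validate_effect_config <- function(config) {
  need <- c("baseline", "age_slope", "sex_effect", "preterm_effect",
            "noise_sd", "extreme_rate", "extreme_magnitude_range", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    abort(paste("effect config missing:", paste(miss, collapse = ", ")),
          class = "config_error")
  }
  for (nm in c("baseline", "age_slope", "preterm_effect", "noise_sd")) {
    m <- config[[nm]]
    if (!is.matrix(m) ||
        !setequal(rownames(m), cortical_metrics) ||
        !setequal(colnames(m), cortical_regions)) {
      abort(sprintf("config `%s` must be an 8 metric x 7 region matrix", nm),
            class = "config_error")
    }
  }
  if (any(config$noise_sd <= 0)) {
    abort("noise_sd must be strictly positive everywhere",
          class = "config_error")
  }
  if (config$extreme_rate < 0 || config$extreme_rate > 1) {
    abort("extreme_rate must lie in [0, 1]", class = "config_error")
  }
  r <- config$extreme_magnitude_range
  if (length(r) != 2L || r[1] > r[2] || r[1] <= 3.1) {
    abort("extreme_magnitude_range lower bound must exceed 3.1",
          class = "config_error")
  }
  invisible(config)
}

#' Generate parcel-wise cortical features with known ground truth
#'
#' Builds the subjects x parcels x metrics feature table from the generative
#' model
#' `value = baseline + slope * (PMA - 40) + sex_effect * sex +
#'  preterm_effect * g(GA) * I(preterm) + extreme_offset + noise`,
#' with `g(GA) = max(0, 37 - GA)/14` so maximal prematurity (GA 23) receives
#' the full configured effect. Extreme offsets are injected per
#' (subject, metric) with probability `extreme_rate` at a small random parcel
#' subset, with magnitude uniform in `extreme_magnitude_range` times the
#' local noise SD and sign following the metric's preterm direction with
#' probability `extreme_sign_fidelity`. FA/ODI/fICVF are clipped to `[0, 1]`
#' and MD/thickness/SA floored at a small positive value; clipping events are
#' returned in `clip_log`.
#'
#' @param subjects Tibble from [sample_demographics()].
#' @param parcels Tibble from [generate_parcellation()].
#' @param config An [default_effect_config()] list.
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with `features` (long tibble: `subject_id`, `parcel_id`,
#'   `metric`, `value`), `ground_truth` (list with `extremes` — one row per
#'   injected offset with its sign — and `effect_parcels` — parcels carrying
#'   a nonzero group effect per metric), and `clip_log`.
#' @export
generate_features <- function(subjects, parcels, config = default_effect_config(),
                              seed = config$seed) {
  validate_effect_config(config)
  bad_pma <- subjects$pma_scan < config$pma_support[1] |
    subjects$pma_scan > config$pma_support[2]
  if (any(bad_pma)) {
    abort(sprintf("PMA outside configured support [%g, %g] for: %s",
                  config$pma_support[1], config$pma_support[2],
                  paste(subjects$subject_id[bad_pma], collapse = ", ")),
          class = "invalid_argument")
  }
  set.seed(.assert_count(seed, "seed"))

  n <- nrow(subjects)
  p <- nrow(parcels)
  region <- parcels$region
  pma_c <- subjects$pma_scan - 40
  prem <- pmax(0, 37 - subjects$ga_birth) / 14
  if (!config$prematurity_scaling) prem <- as.numeric(prem > 0)
  is_pre <- as.numeric(subjects$group == "preterm")

  ext_targets <- switch(config$extreme_subjects,
                        preterm = which(subjects$group == "preterm"),
                        all = seq_len(n))

  vals <- vector("list", length(cortical_metrics))
  gt <- list()
  clip_log <- list()
  for (mi in seq_along(cortical_metrics)) {
    m <- cortical_metrics[mi]
    base_p <- unname(config$baseline[m, region])
    slope_p <- unname(config$age_slope[m, region])
    pre_p <- unname(config$preterm_effect[m, region])
    sd_p <- unname(config$noise_sd[m, region])

    V <- matrix(base_p, n, p, byrow = TRUE) +
      outer(pma_c, slope_p) +
      config$sex_effect[m] * subjects$sex +
      outer(prem * is_pre, pre_p)

    gep <- config$group_effect_parcels
    if (!is.null(gep)) {
      g <- gep[gep$metric == m, , drop = FALSE]
      if (nrow(g)) {
        idx <- match(g$parcel_id, parcels$parcel_id)
        V[, idx] <- V[, idx] +
          outer(prem * is_pre, g$effect)
      }
    }

    # sparse individual extreme deviations
    if (config$extreme_rate > 0 && length(ext_targets)) {
      hit <- ext_targets[runif(length(ext_targets)) < config$extreme_rate]
      for (si in hit) {
        k <- sample.int(config$extreme_parcels_max, 1L)
        pj <- sample.int(p, k)
        mag <- runif(k, config$extreme_magnitude_range[1],
                     config$extreme_magnitude_range[2])
        sgn <- ifelse(runif(k) < config$extreme_sign_fidelity,
                      config$preterm_direction[m],
                      -config$preterm_direction[m])
        off <- sgn * mag * sd_p[pj]
        V[si, pj] <- V[si, pj] + off
        gt[[length(gt) + 1L]] <- tibble(
          subject_id = subjects$subject_id[si],
          parcel_id = parcels$parcel_id[pj],
          metric = m, sign = as.integer(sgn),
          magnitude_sd = mag, offset = off)
      }
    }

    V <- V + matrix(rnorm(n * p, 0, rep(sd_p, each = n)), n, p)

    if (m %in% .bounded_metrics) {
      n_clip <- sum(V < 0 | V > 1)
      if (n_clip) clip_log[[m]] <- n_clip
      V <- pmin(pmax(V, 0), 1)
    } else if (m %in% .positive_metrics) {
      n_clip <- sum(V <= 0)
      if (n_clip) clip_log[[m]] <- n_clip
      V <- pmax(V, 1e-6)
    }

    vals[[mi]] <- tibble(
      subject_id = rep(subjects$subject_id, times = p),
      parcel_id = rep(parcels$parcel_id, each = n),
      metric = m,
      value = as.vector(V))
  }

  effect_parcels <- bind_rows(
    tibble(metric = rep(cortical_metrics,
                        each = length(region)),
           parcel_id = rep(parcels$parcel_id, length(cortical_metrics)),
           effect = as.vector(t(config$preterm_effect[, region]))) |>
      filter(.data$effect != 0),
    if (!is.null(config$group_effect_parcels)) config$group_effect_parcels
  ) |> distinct(.data$metric, .data$parcel_id, .keep_all = TRUE)

  list(
    features = bind_rows(vals) |> arrange(.data$subject_id, .data$parcel_id),
    ground_truth = list(
      extremes = if (length(gt)) bind_rows(gt) else
        tibble(subject_id = character(), parcel_id = integer(),
               metric = character(), sign = integer(),
               magnitude_sd = numeric(), offset = numeric()),
      effect_parcels = effect_parcels),
    clip_log = clip_log
  )
}

#' Simulate a complete term/preterm cohort
#'
#' Convenience wrapper chaining [generate_parcellation()],
#' [sample_demographics()] and [generate_features()] under one seed.
#'
#' @inheritParams sample_demographics
#' @param n_parcels_per_hemisphere Parcels per hemisphere (default 143).
#' @param config Effect configuration; its seed is replaced by `seed + 2`.
#' @param seed Master seed (parcellation uses `seed`, demographics
#'   `seed + 1`, features `seed + 2`).
#' @return List with `parcels`, `subjects`, `features`, `ground_truth`,
#'   `clip_log`, `config`.
#' @examples
#' sim <- simulate_cohort(12, 5, n_parcels_per_hemisphere = 8, seed = 1)
#' head(sim$features)
#' @export
simulate_cohort <- function(n_term, n_preterm,
                            n_parcels_per_hemisphere = 143L,
                            config = default_effect_config(),
                            seed = 1L, ...) {
  seed <- .assert_count(seed, "seed")
  parcels <- generate_parcellation(n_parcels_per_hemisphere, seed = seed)
  subjects <- sample_demographics(n_term, n_preterm, seed = seed + 1L, ...)
  fg <- generate_features(subjects, parcels, config, seed = seed + 2L)
  list(parcels = parcels, subjects = subjects, features = fg$features,
       ground_truth = fg$ground_truth, clip_log = fg$clip_log,
       config = config)
}
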