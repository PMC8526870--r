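# ---- TSV contracts ---------------------------------------------------------

.read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(paste("file not found:", path), class = "io_error")
  }
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

#' Read and validate a long feature table
#'
#' Expects a TSV/CSV with header `subject_id`, `parcel_id`, `metric`,
#' `value`; metric names must come from the fixed eight-name vocabulary,
#' values must be numeric and (subject, parcel, metric) keys unique.
#'
#' @param path Path to a TSV (or CSV if the extension is `.csv`).
#' @return Validated tibble.
#' @export
read_feature_table <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  tab <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  need <- c("subject_id", "parcel_id", "metric", "value")
  if (!identical(names(tab)[seq_along(need)], need)) {
    abort(paste("expected header", paste(need, collapse = ", "),
                "- got:", paste(names(tab), collapse = ", ")),
          class = "schema_error")
  }
  .check_metric_names(tab$metric)
  val <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(val)) {
    rows <- which(is.na(val))
    abort(paste("non-numeric value at row(s):",
                paste(head(rows, 5), collapse = ", ")),
          class = "schema_error")
  }
  pid <- suppressWarnings(as.integer(tab$parcel_id))
  if (anyNA(pid)) {
    abort("non-integer parcel_id", class = "schema_error")
  }
  key <- paste(tab$subject_id, pid, tab$metric)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    abort(paste("duplicate (subject, parcel, metric) key:", d),
          class = "schema_error")
  }
  tibble(subject_id = tab$subject_id, parcel_id = pid,
         metric = tab$metric, value = val)
}

#' @rdname read_feature_table
#' @param features Long feature tibble to write.
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features[, c("subject_id", "parcel_id", "metric", "value")],
                   path)
  invisible(path)
}

#' Read a subject table written by [write_cohort()]
#'
#' @param path Path to `subjects.tsv`.
#' @return Tibble with typed demographic columns.
#' @export
read_subject_table <- function(path) {
  .read_tsv_strict(path, readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    ga_birth = readr::col_double(),
    pma_scan = readr::col_double(),
    sex = readr::col_integer(),
    .default = readr::col_double()))
}

#' Read a parcel table written by [write_cohort()]
#'
#' @param path Path to `parcels.tsv`.
#' @return A `parcel_set` tibble.
#' @export
read_parcel_table <- function(path) {
  out <- .read_tsv_strict(path, readr::cols(
    parcel_id = readr::col_integer(),
    hemisphere = readr::col_character(),
    region = readr::col_character(),
    .default = readr::col_double()))
  class(out) <- c("parcel_set", class(out))
  out
}

#' Write a simulated cohort to a directory
#'
#' Writes `subjects.tsv`, `features.tsv`, `parcels.tsv` and
#' `ground_truth.tsv` (UTF-8, tab-separated, `.` decimal separator).
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$subjects, file.path(dir, "subjects.tsv"))
  write_feature_table(sim$features, file.path(dir, "features.tsv"))
  readr::write_tsv(sim$parcels, file.path(dir, "parcels.tsv"))
  readr::write_tsv(sim$ground_truth$extremes, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

# ---- run configuration -----------------------------------------------------

#' Pipeline run configuration
#'
#' Scalar settings for a full pipeline run. The generative effect
#' configuration itself is reconstructed from [default_effect_config()] with
#' the run seed, keeping the config losslessly serializable to YAML.
#'
#' @param n_term,n_preterm Cohort sizes (defaults give a small demonstration
#'   cohort).
#' @param n_parcels_per_hemisphere Parcels per hemisphere.
#' @param holdout_fraction Term hold-out fraction for normative training.
#' @param restarts GP optimizer restarts per cell.
#' @param n_perm Permutations for every permutation stage.
#' @param threshold Extreme-deviation Z threshold.
#' @param alpha Family-wise significance level.
#' @param n_estimators Random-forest tree count.
#' @param seed Master seed; stage seeds are derived as small offsets.
#' @param stages Named logical vector toggling pipeline stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_term = 60L, n_preterm = 20L,
                       n_parcels_per_hemisphere = 30L,
                       holdout_fraction = 0.25, restarts = 3L,
                       n_perm = 500L, threshold = 3.1, alpha = 0.05,
                       n_estimators = 1000L, seed = 1L,
                       stages = c(simulate = TRUE, split = TRUE,
                                  normative = TRUE, deviations = TRUE,
                                  group_stats = TRUE, age_predict = TRUE,
                                  associations = TRUE)) {
  cfg <- list(
    n_term = .assert_count(n_term, "n_term", 1L),
    n_preterm = .assert_count(n_preterm, "n_preterm"),
    n_parcels_per_hemisphere =
      .assert_count(n_parcels_per_hemisphere, "n_parcels_per_hemisphere", 7L),
    holdout_fraction = .assert_fraction(holdout_fraction, "holdout_fraction"),
    restarts = .assert_count(restarts, "restarts", 1L),
    n_perm = .assert_count(n_perm, "n_perm", 100L),
    threshold = threshold,
    alpha = alpha,
    n_estimators = .assert_count(n_estimators, "n_estimators", 1L),
    seed = .assert_count(seed, "seed"),
    stages = stages
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$stages <- as.list(out$stages)  # yaml drops names of atomic vectors
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$stages <- unlist(raw$stages)
  do.call(run_config, raw)
}

# ---- full pipeline ---------------------------------------------------------

.stage_files <- list(
  simulate = c("subjects.tsv", "features.tsv", "parcels.tsv",
               "ground_truth.tsv"),
  split = "split.tsv",
  normative = c("normative_model.json", "holdout_mae.tsv"),
  deviations = c("z_scores.tsv", "extreme_mask.tsv", "overlap_map.tsv",
                 "atypicality.tsv"),
  group_stats = c("stat_map_age.tsv", "stat_map_group.tsv",
                  "stat_map_interaction.tsv", "perm_meta.json"),
  age_predict = c("age_predictions.tsv", "age_report.json",
                  "importance_summary.tsv"),
  associations = c("stat_map_ga_z.tsv", "index_associations.tsv",
                   "index_group_tests.tsv")
)

#' Run the full normative-modelling pipeline
#'
#' Executes simulate -> split -> fit-normative -> deviations -> group
#' statistics (age association, group difference, group x PMA interaction)
#' -> age prediction -> outcome associations, writing every stage's outputs
#' as TSV/JSON under `out_dir`. Each stage re-reads its inputs from the
#' files written by earlier stages, so a stage can be toggled off in the
#' config when its outputs already exist. A manifest with the config hash,
#' per-file MD5 hashes and per-stage wall-clock time is written to
#' `manifest.json` and returned.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = unclass(config),
    config_hash = .hash_object(unclass(config)),
    package_version = as.character(utils::packageVersion("corticonorm")),
    stages = list()
  )
  done <- character()
  path <- function(f) file.path(out_dir, f)
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    t0 <- Sys.time()
    tryCatch(fun(), error = function(e) {
      manifest$stages <<- c(manifest$stages, list(list(
        stage = name, status = "failed", error = conditionMessage(e))))
      .write_manifest(manifest, path("manifest.json"))
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "stage_failure")
    })
    files <- .stage_files[[name]]
    manifest$stages <<- c(manifest$stages, list(list(
      stage = name, status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      outputs = as.list(unname(tools::md5sum(path(files)))),
      files = as.list(files))))
    done <<- c(done, name)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    sim <- simulate_cohort(
      config$n_term, config$n_preterm,
      n_parcels_per_hemisphere = config$n_parcels_per_hemisphere,
      config = default_effect_config(seed = config$seed + 2L),
      seed = config$seed)
    write_cohort(sim, out_dir)
  })

  run_stage("split", function() {
    subjects <- read_subject_table(path("subjects.tsv"))
    split <- split_cohort(subjects, config$holdout_fraction,
                          seed = config$seed + 10L)
    readr::write_tsv(split, path("split.tsv"))
  })

  run_stage("normative", function() {
    subjects <- read_subject_table(path("subjects.tsv"))
    features <- read_feature_table(path("features.tsv"))
    split <- .read_tsv_strict(path("split.tsv"), readr::cols(
      subject_id = readr::col_character(), split = readr::col_character()))
    train_ids <- split$subject_id[split$split == "train"]
    hold_ids <- split$subject_id[split$split == "holdout"]
    model <- fit_normative_model(
      filter(features, .data$subject_id %in% train_ids),
      filter(subjects, .data$subject_id %in% train_ids),
      restarts = config$restarts, seed = config$seed + 20L)
    mae <- evaluate_mae(model,
                        filter(features, .data$subject_id %in% hold_ids),
                        filter(subjects, .data$subject_id %in% hold_ids))
    readr::write_tsv(mae, path("holdout_mae.tsv"))
    write_normative_model(model, path("normative_model.json"))
  })

  run_stage("deviations", function() {
    subjects <- read_subject_table(path("subjects.tsv"))
    features <- read_feature_table(path("features.tsv"))
    split <- .read_tsv_strict(path("split.tsv"), readr::cols(
      subject_id = readr::col_character(), split = readr::col_character()))
    hold_ids <- split$subject_id[split$split == "holdout"]
    model <- read_normative_model(path("normative_model.json"),
                                  features, subjects)
    scored <- filter(subjects, .data$group == "preterm" |
                       .data$subject_id %in% hold_ids)
    pred <- predict(model, scored)
    z <- compute_z_scores(pred,
                          filter(features,
                                 .data$subject_id %in% scored$subject_id))
    mask <- classify_extremes(z, threshold = config$threshold)
    pre_ids <- scored$subject_id[scored$group == "preterm"]
    omap <- bind_rows(
      mutate(overlap_map(mask, pre_ids), group = "preterm"),
      mutate(overlap_map(mask, intersect(scored$subject_id, hold_ids)),
             group = "term_holdout"))
    at <- atypicality_indices(mask,
                              n_parcels = 2L * config$n_parcels_per_hemisphere)
    readr::write_tsv(z, path("z_scores.tsv"))
    readr::write_tsv(mask, path("extreme_mask.tsv"))
    readr::write_tsv(omap, path("overlap_map.tsv"))
    readr::write_tsv(at, path("atypicality.tsv"))
  })

  run_stage("group_stats", function() {
    subjects <- read_subject_table(path("subjects.tsv"))
    features <- read_feature_table(path("features.tsv"))
    term <- filter(subjects, .data$group == "term")
    age <- permutation_test(
      filter(features, .data$subject_id %in% term$subject_id), term,
      tested = "pma_scan", nuisance = "sex",
      n_perm = config$n_perm, seed = config$seed + 30L, alpha = config$alpha)
    grp <- permutation_test(features, subjects, tested = "group",
                            nuisance = c("pma_scan", "sex"),
                            n_perm = config$n_perm, seed = config$seed + 31L,
                            alpha = config$alpha)
    inter <- interaction_test(features, subjects, n_perm = config$n_perm,
                              seed = config$seed + 32L, alpha = config$alpha)
    readr::write_tsv(tidy(age), path("stat_map_age.tsv"))
    readr::write_tsv(tidy(grp), path("stat_map_group.tsv"))
    readr::write_tsv(tidy(inter), path("stat_map_interaction.tsv"))
    jsonlite::write_json(list(
      n_perm = config$n_perm, alpha = config$alpha,
      seeds = config$seed + 30:32,
      designs = list(age = glance(age), group = glance(grp),
                     interaction = glance(inter))),
      path("perm_meta.json"), auto_unbox = TRUE, digits = NA)
  })

  run_stage("age_predict", function() {
    subjects <- read_subject_table(path("subjects.tsv"))
    features <- read_feature_table(path("features.tsv"))
    split <- .read_tsv_strict(path("split.tsv"), readr::cols(
      subject_id = readr::col_character(), split = readr::col_character()))
    train <- filter(subjects, .data$subject_id %in%
                      split$subject_id[split$split == "train"])
    hold <- filter(subjects, .data$subject_id %in%
                     split$subject_id[split$split == "holdout"])
    model <- train_age_model(
      filter(features, .data$subject_id %in% train$subject_id), train,
      config = age_pred_config(n_estimators = config$n_estimators,
                               seed = config$seed + 40L))
    raw_train <- predict(model,
                         filter(features,
                                .data$subject_id %in% train$subject_id),
                         train)
    corr <- fit_bias_correction(raw_train$raw_pred, raw_train$true_pma)
    report <- evaluate_age_model(
      model, corr, filter(features, .data$subject_id %in% hold$subject_id),
      hold)
    readr::write_tsv(tidy(report), path("age_predictions.tsv"))
    jsonlite::write_json(c(as.list(glance(report)),
                           list(bias_a = corr$a, bias_b = corr$b)),
                         path("age_report.json"), auto_unbox = TRUE,
                         digits = NA)
    readr::write_tsv(summarize_importance(model),
                     path("importance_summary.tsv"))
  })

  run_stage("associations", function() {
    subjects <- read_subject_table(path("subjects.tsv"))
    z <- .read_tsv_strict(path("z_scores.tsv"), readr::cols(
      subject_id = readr::col_character(), parcel_id = readr::col_integer(),
      metric = readr::col_character(), z = readr::col_double()))
    at <- .read_tsv_strict(path("atypicality.tsv"), readr::cols(
      subject_id = readr::col_character(), metric = readr::col_character(),
      .default = readr::col_double()))
    scored <- filter(subjects, .data$subject_id %in% unique(z$subject_id))
    ga_map <- z_covariate_map(z, scored, covariate = "ga_birth",
                              n_perm = config$n_perm,
                              seed = config$seed + 50L, alpha = config$alpha)
    assoc <- bind_rows(
      mutate(index_correlation(at, filter(scored, .data$group == "preterm"),
                               covariates = "ga_birth"), sample = "preterm"),
      mutate(index_correlation(at, scored, covariates = "ga_birth"),
             sample = "combined"))
    gtest <- index_group_test(at, scored)
    readr::write_tsv(tidy(ga_map), path("stat_map_ga_z.tsv"))
    readr::write_tsv(assoc, path("index_associations.tsv"))
    readr::write_tsv(gtest, path("index_group_tests.tsv"))
  })

  manifest$completed <- done
  .write_manifest(manifest, path("manifest.json"))
  invisible(manifest)
}

.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

.write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
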