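#' Run configuration for the full phantom pipeline
#'
#' @param n_patients Phantom cohort size.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param image_types Image types to extract and classify.
#' @param combinations Optional list of image-type subsets to evaluate
#'   jointly (each entry a character vector); default: the single set
#'   `image_types`.
#' @param penalty,grid,fraction,inner_folds,normalization Passed to
#'   [cv_config()].
#' @param drift_amplitude T2w drift amplitude for the phantom.
#' @param contrast Class-contrast multiplier for [default_class_models()].
#' @param lesion_counts Optional per-patient lesion counts.
#' @param low_fraction Fraction of lesions labeled low (-1); keep it large
#'   enough that at least 3 lesions carry the minority label, or LPOCV
#'   rounds holding out two minority lesions become degenerate.
#' @param aggregation Texture aggregation mode.
#' @param fit_maps If TRUE, fit parametric maps from the simulated 4D
#'   series (slow); if FALSE (default) texture extraction reads the
#'   ground-truth parameter fields.
#' @param fit_grid_coarsen Multiplier applied to the fitting start-grid
#'   steps when `fit_maps = TRUE` (the objective is smooth, so a coarser
#'   multistart loses little).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_patients = 8, seed = 1L,
                       image_types = c("ADCk", "K", "T2w"),
                       combinations = NULL,
                       penalty = "l1", grid = c(0.001, 0.01, 0.1, 1, 10),
                       fraction = 0.01, inner_folds = 10L,
                       normalization = "training",
                       drift_amplitude = 0.3, contrast = 1,
                       lesion_counts = NULL, low_fraction = 0.2,
                       aggregation = "pooled_median",
                       fit_maps = FALSE, fit_grid_coarsen = 10) {
  cfg <- list(n_patients = n_patients, seed = as.integer(seed),
              image_types = image_types,
              combinations = if (is.null(combinations)) list(image_types) else combinations,
              penalty = penalty, grid = grid, fraction = fraction,
              inner_folds = inner_folds, normalization = normalization,
              drift_amplitude = drift_amplitude, contrast = contrast,
              lesion_counts = lesion_counts, low_fraction = low_fraction,
              aggregation = aggregation,
              fit_maps = fit_maps, fit_grid_coarsen = fit_grid_coarsen)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full phantom pipeline
#'
#' Simulation, (optional) parametric-map fitting, T2w standardization,
#' texture extraction, table assembly, univariate ROC analysis, and
#' leave-pair-out cross-validated classification, in that order. The
#' report mirrors the structure of a radiomics study summary: per-feature
#' univariate AUCs (best texture and best statistical feature per image
#' type), LPOCV AUC with CI per image-type combination, and the final
#' model's selected features.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_report` with elements `config`,
#'   `config_hash`, `cohort_summary`, `standard_scale`, `univariate`
#'   (data.frame), `models` (data.frame of per-combination AUCs and CIs),
#'   `final_model`, and `table` (the assembled [feature_table()]).
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$n_patients,
                            class_models = default_class_models(config$contrast),
                            drift_amplitude = config$drift_amplitude,
                            seed = config$seed,
                            lesion_counts = config$lesion_counts,
                            low_fraction = config$low_fraction)
  # T2w standardization on the prostate masks
  t2w_imgs <- lapply(cohort$cases, `[[`, "t2w")
  t2w_masks <- lapply(cohort$cases, function(cs) cs$masks$t2w$prostate)
  scale <- learn_standard_scale(t2w_imgs, t2w_masks)
  std_t2w <- mapply(standardize_image, t2w_imgs, t2w_masks,
                    MoreArgs = list(standard_scale = scale), SIMPLIFY = FALSE)
  fitted_maps <- NULL
  if (config$fit_maps) {
    fitted_maps <- lapply(cohort$cases, function(cs) {
      lesion_union <- Reduce(`|`, cs$masks$dwi$lesions)
      km <- fit_volume(cs$dwi, lesion_union, "kurtosis",
                       cohort$protocol$b_values,
                       adc_step = 0.1 * config$fit_grid_coarsen,
                       k_step = 0.2 * config$fit_grid_coarsen, n_refine = 3L)
      mm <- fit_volume(cs$dwi, lesion_union, "mono", cohort$protocol$b_values,
                       grid_step = 0.01 * config$fit_grid_coarsen, n_refine = 3L)
      tm <- fit_volume(cs$t2_series, Reduce(`|`, cs$masks$t2$lesions), "t2",
                       cohort$protocol$echo_times)
      list(ADCk = km$ADCk, K = km$K, ADCm = mm$ADCm, T2 = tm$T2)
    })
  }
  vol_fn <- function(case, type) {
    if (type == "T2w") return(std_t2w[[case$patient_id]])
    if (!is.null(fitted_maps)) {
      m <- fitted_maps[[case$patient_id]][[type]]
      if (!is.null(m)) { m[is.nan(m)] <- 0; return(m) }
    }
    switch(type, ADCk = case$truth$ADCk, ADCm = case$truth$ADCk,
           K = case$truth$K, T2 = case$truth$T2)
  }
  qr <- default_quant_ranges(t2w_upper = max(scale$standard))
  table <- extract_cohort_features(cohort, config$image_types,
                                   volumes = vol_fn, quant_ranges = qr,
                                   aggregation = config$aggregation)
  # univariate ROC analysis per feature; best texture + best statistical
  aucs <- .col_aucs(table$features, table$label)
  uni <- do.call(rbind, lapply(config$image_types, function(tp) {
    cols <- which(table$image_type == tp)
    is_stat <- grepl(":stats\\(", colnames(table$features)[cols])
    bt <- cols[!is_stat][which.max(aucs[cols[!is_stat]])]
    bs <- cols[is_stat][which.max(aucs[cols[is_stat]])]
    data.frame(image_type = tp,
               best_texture = colnames(table$features)[bt],
               best_texture_auc = aucs[bt],
               best_statistical = colnames(table$features)[bs],
               best_statistical_auc = aucs[bs], stringsAsFactors = FALSE)
  }))
  rownames(uni) <- NULL
  # LPOCV per image-type combination
  models <- do.call(rbind, lapply(config$combinations, function(types) {
    sub <- subset_by_image_types(table, types)
    cfg <- cv_config(penalty = config$penalty, grid = config$grid,
                     fraction = config$fraction,
                     inner_folds = config$inner_folds, seed = config$seed,
                     normalization = config$normalization)
    res <- run_lpocv(sub, cfg)
    data.frame(image_types = paste(types, collapse = "+"),
               n_features = ncol(sub$features),
               n_selected = if (identical(config$fraction, "all"))
                 ncol(sub$features) else floor(config$fraction * ncol(sub$features)),
               auc = res$auc, ci_low = res$ci[1], ci_high = res$ci[2],
               stringsAsFactors = FALSE)
  }))
  rownames(models) <- NULL
  final <- train_final_model(table, cv_config(
    penalty = config$penalty, grid = config$grid, fraction = config$fraction,
    inner_folds = config$inner_folds, seed = config$seed,
    normalization = config$normalization))
  structure(list(
    config = config,
    config_hash = config_hash(config),
    cohort_summary = list(n_patients = config$n_patients,
                          n_lesions = length(table$label),
                          n_low = sum(table$label == -1),
                          n_high = sum(table$label == 1)),
    standard_scale = scale$standard,
    univariate = uni, models = models, final_model = final,
    table = table), class = "pipeline_report")
}

#' Deterministic hash of a run configuration
#'
#' A short hex digest (a polynomial rolling hash over the serialized
#' configuration bytes) embedded in every report so outputs can be matched
#' to the exact configuration that produced them.
#'
#' @param config Any R object.
#' @return Character scalar of 8 hex digits.
#' @export
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report [config ", x$config_hash, "]\n", sep = "")
  cat(sprintf("cohort: %d patients, %d lesions (%d low / %d high)\n",
              x$cohort_summary$n_patients, x$cohort_summary$n_lesions,
              x$cohort_summary$n_low, x$cohort_summary$n_high))
  cat("\nunivariate best features:\n")
  print(x$univariate, row.names = FALSE)
  cat("\nLPOCV models:\n")
  print(x$models, row.names = FALSE)
  cat("\nfinal model features:",
      paste(utils::head(x$final_model$selected_features, 5), collapse = ", "),
      if (length(x$final_model$selected_features) > 5) "..." else "", "\n")
  invisible(x)
}
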