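#' Pipeline configuration
#'
#' Aggregates every stage's settings behind one object that fully determines
#' a run: analysis grid (3 mm isotropic), 64-bin discretization, alpha/beta
#' of 3 Gy, filter scales, ADASYN, selection, CV and gate parameters, plus a
#' single global seed that fans out to per-stage seeds via [stage_seed()].
#' Round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param cohort A [cohort_config()] (the synthetic cohort to simulate), or
#'   `NULL` when features are supplied externally.
#' @param target_spacing Analysis voxel spacing in mm (default 3).
#' @param n_bins Discretization bins (default 64).
#' @param alpha_beta Alpha/beta in Gy (default 3).
#' @param filter_scales Named list of filter scales (see [extract_all()]).
#' @param adasyn An [adasyn_params()].
#' @param selection A [selection_spec()].
#' @param max_vars_scan Integer vector of `max_vars` values to scan
#'   (default `4:8`).
#' @param cv A [cv_spec()].
#' @param gate A [gate_spec()].
#' @param trainer_budget Hyperparameter budget per trainer.
#' @param seed Global seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            target_spacing = c(3, 3, 3),
                            n_bins = 64L,
                            alpha_beta = 3,
                            filter_scales = list(gaussian = 3, log = 3,
                                                 median = 1),
                            adasyn = adasyn_params(),
                            selection = selection_spec(),
                            max_vars_scan = 4:8,
                            cv = cv_spec(repeats = 50L),
                            gate = gate_spec(),
                            trainer_budget = 9L,
                            seed = 1L) {
  structure(list(cohort = cohort, target_spacing = target_spacing,
                 n_bins = as.integer(n_bins), alpha_beta = alpha_beta,
                 filter_scales = filter_scales, adasyn = adasyn,
                 selection = selection, max_vars_scan = as.integer(max_vars_scan),
                 cv = cv, gate = gate, trainer_budget = trainer_budget,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param file YAML path.
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(config_to_list(config), file, precision = 12L)
  invisible(file)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(file) {
  l <- yaml::read_yaml(file)
  pipeline_config(
    cohort = if (is.null(l$cohort)) NULL else do.call(cohort_config, c(
      l$cohort[setdiff(names(l$cohort), c("scheme_mix", "effect_coefficients"))],
      list(scheme_mix = as.data.frame(l$cohort$scheme_mix),
           effect_coefficients = unlist(l$cohort$effect_coefficients)))),
    target_spacing = l$target_spacing, n_bins = l$n_bins,
    alpha_beta = l$alpha_beta, filter_scales = l$filter_scales,
    adasyn = do.call(adasyn_params, l$adasyn),
    selection = do.call(selection_spec, l$selection),
    max_vars_scan = l$max_vars_scan,
    cv = do.call(cv_spec, l$cv),
    gate = do.call(gate_spec, l$gate),
    trainer_budget = l$trainer_budget, seed = l$seed)
}

config_to_list <- function(config) {
  l <- unclass(config)
  if (!is.null(l$cohort)) {
    ch <- unclass(l$cohort)
    ch$scheme_mix <- as.list(ch$scheme_mix)
    ch$effect_coefficients <- as.list(ch$effect_coefficients)
    l$cohort <- ch
  }
  l$adasyn <- unclass(l$adasyn)
  l$selection <- unclass(l$selection)
  l$cv <- unclass(l$cv)
  l$gate <- unclass(l$gate)
  l
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, extract the full feature catalog per
#' patient, augment with ADASYN, select features by cross-validated
#' deviance for each `max_vars` in the scan, train the SVM, ensemble and
#' naive-Bayes families, evaluate each with repeated cross-validation, vet
#' monotonicity against a BED feature, and apply the acceptance gate.
#' Artifacts (feature table, augmented table, metrics, reports) are written
#' under `out_dir` together with the resolved configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param feature_table Optional precomputed feature table (skips simulation
#'   and extraction); must contain `label` and feature columns.
#' @param catalog Feature catalog for extraction (default full catalog).
#' @return List with `features`, `augmented`, `metrics` (one row per
#'   family x max_vars), `models`, `reports`, `gate_results`.
#' @export
run_pipeline <- function(config, out_dir, feature_table = NULL,
                         catalog = feature_catalog()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))

  # stage 1: cohort features
  if (is.null(feature_table)) {
    if (is.null(config$cohort)) stop("no cohort config and no feature table")
    cohort <- config$cohort
    cohort$seed <- stage_seed(config$seed, "simulate")
    patients <- lapply(seq_len(cohort$n_patients) - 1L,
                       function(i) generate_phantom(cohort, i))
    rows <- lapply(patients, function(p) {
      ct <- resample(p$ct, config$target_spacing)
      red <- hu_to_red(ct)
      bed <- dose_to_bed(resample(p$dose, config$target_spacing), p$scheme)
      breast <- resample(p$breast_mask, config$target_spacing)
      ptv <- resample(p$ptv_mask, config$target_spacing)
      extract_all(red, bed, breast, ptv, catalog, config$n_bins,
                  config$filter_scales)
    })
    feat <- as.data.frame(do.call(rbind, rows))
    outc <- assign_outcome(feat, cohort)
    feature_table <- cbind(
      data.frame(patient_id = vapply(patients, `[[`, "", "patient_id"),
                 label = outc$label),
      feat)
  }
  utils::write.csv(feature_table, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  # stage 2: augmentation
  ap <- config$adasyn
  ap$seed <- stage_seed(config$seed, "augment")
  augmented <- adasyn(feature_table, ap)
  utils::write.csv(augmented, file.path(out_dir, "augmented.csv"),
                   row.names = FALSE)

  # stage 3-5: selection scan, training, evaluation
  families <- c("svm", "eml", "nb")
  metrics <- list(); models <- list(); reports <- list()
  for (mv in config$max_vars_scan) {
    sel_spec <- config$selection
    sel_spec$max_vars <- mv
    sel_spec$seed <- stage_seed(config$seed, paste0("select", mv))
    feats <- stepwise_forward_select(augmented, sel_spec)
    if (length(feats) == 0L) feats <- feature_columns(augmented)[1]
    for (fam in families) {
      key <- sprintf("%s_%d", fam, mv)
      recipe <- cv_recipe(fam, features = feats, adasyn = config$adasyn,
                          budget = config$trainer_budget)
      cv <- config$cv
      cv$seed <- stage_seed(config$seed, paste0("cv_", key))
      rep_ <- repeated_cv(feature_table, recipe, cv)
      model <- switch(fam,
        svm = train_svm(augmented, feats,
                        seed = stage_seed(config$seed, paste0("train_", key)),
                        budget = config$trainer_budget),
        eml = train_ensemble(augmented, feats,
                             seed = stage_seed(config$seed, paste0("train_", key)),
                             budget = config$trainer_budget),
        nb = train_nb(augmented, feats,
                      seed = stage_seed(config$seed, paste0("train_", key))))
      orig <- evaluate_on_original(model, feature_table)
      bed_feats <- grep("^bed_", feats, value = TRUE)
      mono <- if (length(bed_feats) > 0) {
        monotonicity_vetting(model, bed_feats[1], feature_table)$verdict
      } else {
        NA_character_
      }
      gate_res <- model_gate(rep_, config$gate, monotonicity = mono)
      metrics[[key]] <- data.frame(
        family = fam, n_vars = length(feats),
        sensitivity = rep_$sensitivity$mean,
        sensitivity_lo = rep_$sensitivity$ci[1],
        sensitivity_hi = rep_$sensitivity$ci[2],
        specificity = rep_$specificity$mean,
        specificity_lo = rep_$specificity$ci[1],
        specificity_hi = rep_$specificity$ci[2],
        auc = rep_$auc$mean, auc_lo = rep_$auc$ci[1], auc_hi = rep_$auc$ci[2],
        orig_sensitivity = orig["sensitivity"],
        orig_specificity = orig["specificity"], orig_auc = orig["auc"],
        monotonicity = mono %||% NA_character_,
        accepted = gate_res$accepted)
      models[[key]] <- model
      reports[[key]] <- rep_
    }
  }
  metrics <- do.call(rbind, c(metrics, list(make.row.names = FALSE)))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(list(features = feature_table, augmented = augmented,
                 metrics = metrics, models = models, reports = reports))
}
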