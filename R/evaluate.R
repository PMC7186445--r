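#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Fraction of positive-negative pairs in which the positive scores higher,
#' with ties counted 1/2 — identical to the normalized rank-sum statistic and
#' to trapezoidal ROC integration.
#'
#' @param scores Numeric scores (higher = positive).
#' @param labels Binary 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

sens_spec <- function(pred, labels) {
  labels <- as.integer(labels)
  c(sensitivity = if (sum(labels == 1L) > 0) {
    mean(pred[labels == 1L] == 1L)
  } else NA_real_,
    specificity = if (sum(labels == 0L) > 0) {
      mean(pred[labels == 0L] == 0L)
    } else NA_real_)
}

#' Repeated cross-validation specification
#'
#' @param folds CV folds (default 5).
#' @param repeats Number of repeats (the reference procedure used 500; scale
#'   down for exploratory runs).
#' @param seed Integer seed.
#' @param leakage_mode `"augment_first"` augments the whole table once and
#'   cross-validates on the augmented rows (the protocol commonly reported
#'   with oversampling, which lets synthetic neighbours of test points into
#'   training: optimistic); `"safe"` folds the original rows and augments
#'   only inside each training fold.
#' @return A `cv_spec` object.
#' @export
cv_spec <- function(folds = 5L, repeats = 500L, seed = 1L,
                    leakage_mode = c("augment_first", "safe")) {
  if (folds < 2L) stop("folds must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 leakage_mode = match.arg(leakage_mode)),
            class = "cv_spec")
}

#' Selection + training recipe for cross-validated evaluation
#'
#' @param trainer One of `"svm"`, `"eml"`, `"nb"`.
#' @param features Fixed feature set, or `NULL` to run selection within each
#'   training set.
#' @param selection A [selection_spec()] used when `features` is `NULL`.
#' @param adasyn An [adasyn_params()] or `NULL` for no augmentation.
#' @param budget Hyperparameter search budget passed to the trainer.
#' @return A `cv_recipe` object.
#' @export
cv_recipe <- function(trainer = c("svm", "eml", "nb"), features = NULL,
                      selection = selection_spec(), adasyn = NULL,
                      budget = 9L) {
  trainer <- match.arg(trainer)
  structure(list(trainer = trainer, features = features,
                 selection = selection, adasyn = adasyn, budget = budget),
            class = "cv_recipe")
}

train_recipe <- function(recipe, table, seed, augment = NULL) {
  feats <- recipe$features
  if (is.null(feats)) {
    sel_spec <- recipe$selection
    sel_spec$seed <- seed
    sel_tab <- if (is.null(augment)) table else augment(table, 0L)
    feats <- stepwise_forward_select(sel_tab, sel_spec)
    if (length(feats) == 0L) feats <- feature_columns(table)[1]
  }
  switch(recipe$trainer,
    svm = train_svm(table, feats, seed = seed, budget = recipe$budget,
                    augment = augment),
    eml = train_ensemble(table, feats, seed = seed, budget = recipe$budget,
                         augment = augment),
    nb = train_nb(table, feats, seed = seed, augment = augment))
}

#' Repeated stratified cross-validation of a modelling recipe
#'
#' Per repeat: a seeded stratified k-fold split; models trained on the
#' training folds (optionally after in-fold ADASYN in `"safe"` mode; in
#' `"augment_first"` mode the table is augmented once up front and folded
#' as-is);
#' pooled out-of-fold predictions give one sensitivity, specificity and AUC
#' per repeat. Reports means with empirical 2.5/97.5 percentile intervals.
#'
#' @param table Feature table (original, un-augmented).
#' @param recipe A [cv_recipe()].
#' @param spec A [cv_spec()].
#' @return An `eval_report`: list of per-metric mean/CI plus per-repeat
#'   values.
#' @export
repeated_cv <- function(table, recipe, spec = cv_spec()) {
  stopifnot(inherits(recipe, "cv_recipe"), inherits(spec, "cv_spec"))
  work <- table
  if (spec$leakage_mode == "augment_first" && !is.null(recipe$adasyn)) {
    work <- adasyn(table, recipe$adasyn)
  }
  y_work <- as.integer(work$label)
  mets <- matrix(NA_real_, spec$repeats, 3,
                 dimnames = list(NULL, c("sensitivity", "specificity", "auc")))
  for (rep_i in seq_len(spec$repeats)) {
    rep_seed <- stage_seed(spec$seed, paste0("cv_rep", rep_i))
    fold <- local_seed(rep_seed, stratified_folds(y_work, spec$folds))
    scores <- rep(NA_real_, nrow(work))
    preds <- rep(NA_integer_, nrow(work))
    for (f in seq_len(spec$folds)) {
      tr_tab <- work[fold != f, , drop = FALSE]
      aug_hook <- NULL
      if (spec$leakage_mode == "safe" && !is.null(recipe$adasyn)) {
        # augmentation happens inside the trainer's folds, never touching
        # the held-out rows (or their synthetic copies)
        aug_hook <- local({
          base_seed <- stage_seed(rep_seed, paste0("adasyn_fold", f))
          ap0 <- recipe$adasyn
          function(tt, inner_f) {
            ap <- ap0
            ap$seed <- stage_seed(base_seed, paste0("inner", inner_f))
            adasyn(tt, ap)
          }
        })
      }
      model <- train_recipe(recipe, tr_tab,
                            seed = stage_seed(rep_seed, paste0("fold", f)),
                            augment = aug_hook)
      te <- which(fold == f)
      s <- predict(model, work[te, , drop = FALSE])
      scores[te] <- s
      preds[te] <- as.integer(s >= model$threshold)
    }
    mets[rep_i, ] <- c(sens_spec(preds, y_work), auc(scores, y_work))
  }
  report <- lapply(colnames(mets), function(m) {
    v <- mets[, m]
    list(mean = mean(v),
         ci = stats::quantile(v, c(0.025, 0.975), names = FALSE),
         values = v)
  })
  names(report) <- colnames(mets)
  structure(c(report, list(spec = spec, recipe_trainer = recipe$trainer)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report:%s> %d-fold CV x %d repeats (%s mode)\n",
              x$recipe_trainer %||% "?", x$spec$folds, x$spec$repeats,
              x$spec$leakage_mode))
  for (m in c("sensitivity", "specificity", "auc")) {
    cat(sprintf("  %-11s %.2f (%.2f-%.2f)\n", m, x[[m]]$mean,
                x[[m]]$ci[1], x[[m]]$ci[2]))
  }
  invisible(x)
}

#' Resubstitution metrics of a final model on the original table
#'
#' Scores the original (non-augmented) rows with the final model and returns
#' sensitivity, specificity and AUC at the model threshold.
#'
#' @param model A `trained_model`.
#' @param original The original feature table with `label`.
#' @return Named numeric vector.
#' @export
evaluate_on_original <- function(model, original) {
  s <- predict(model, original)
  y <- as.integer(original$label)
  c(sens_spec(as.integer(s >= model$threshold), y), auc = auc(s, y))
}

#' Univariate association tests against the outcome
#'
#' Chi-square test of independence on the variable-by-outcome contingency
#' table for categorical variables; two-sided Wilcoxon-Mann-Whitney for
#' continuous variables (exact when both groups have < 15 untied
#' observations, normal approximation with tie correction otherwise). A
#' warning string is attached when any expected cell count is below 1.
#'
#' @param table Data frame of variables (features and/or covariates).
#' @param labels Binary 0/1 outcome vector.
#' @param variables Columns to test (default: all except metadata).
#' @return Data frame with `variable`, `type`, `p_value`, `warning`.
#' @export
univariate_tests <- function(table, labels, variables = NULL) {
  labels <- as.integer(labels)
  if (is.null(variables)) {
    variables <- setdiff(names(table), c("patient_id", "label", "is_synthetic",
                                         "latent_score"))
  }
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    warn <- ""
    if (is.numeric(x) && length(unique(x)) > 5L) {
      exact <- min(table(labels)) < 15L && !any(duplicated(x))
      p <- suppressWarnings(
        stats::wilcox.test(x[labels == 1L], x[labels == 0L],
                           exact = exact, correct = TRUE)$p.value)
      type <- "wilcoxon"
    } else {
      tab <- table(factor(x), factor(labels, levels = 0:1))
      if (nlevels(factor(x)) < 2L) {
        return(data.frame(variable = v, type = "chisq", p_value = NA_real_,
                          warning = "single level"))
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 1)) warn <- "expected cell count < 1"
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      type <- "chisq"
    }
    data.frame(variable = v, type = type, p_value = p, warning = warn)
  })
  do.call(rbind, rows)
}

#' Monotonic dose-response vetting of a model
#'
#' A biologically plausible toxicity model must not predict lower risk at
#' higher dose. The model score is evaluated on a 100-point grid spanning
#' the observed range of a BED-derived feature, holding every other selected
#' feature fixed at a profile (cohort means by default, or a supplied named
#' vector, e.g. the averages of extreme-score subsets). The verdict is
#' `"pass"` iff the curve is non-decreasing up to a tolerance of `1e-6`
#' times the curve's score range.
#'
#' @param model A `trained_model`.
#' @param bed_feature Name of the dose feature to sweep (must be among the
#'   model's selected features).
#' @param table Feature table supplying the observed feature range and the
#'   default profile.
#' @param profile `"mean"` or a named numeric vector of values for the
#'   non-swept selected features.
#' @param n_grid Grid resolution (default 100).
#' @return List with `verdict` (`"pass"`/`"fail"`), `curve` (data frame
#'   `x`, `score`), and `first_decrease` (grid x where the first violating
#'   decrease starts, or `NA`).
#' @export
monotonicity_vetting <- function(model, bed_feature, table, profile = "mean",
                                 n_grid = 100L) {
  feats <- model$selected_features
  if (!bed_feature %in% feats) {
    stop("bed_feature must be one of the model's selected features")
  }
  x <- table[[bed_feature]]
  if (is.null(x)) stop("table lacks column ", bed_feature)
  rng <- range(x)
  if (diff(rng) == 0) stop("zero observed range for ", bed_feature)
  grid <- seq(rng[1], rng[2], length.out = n_grid)

  others <- setdiff(feats, bed_feature)
  base <- if (identical(profile, "mean")) {
    vapply(others, function(nm) mean(table[[nm]]), 0)
  } else {
    miss <- setdiff(others, names(profile))
    if (length(miss) > 0) {
      stop("profile lacks values for: ", paste(miss, collapse = ", "))
    }
    profile[others]
  }
  newdata <- as.data.frame(matrix(rep(base, each = n_grid), nrow = n_grid))
  names(newdata) <- others
  newdata[[bed_feature]] <- grid
  s <- predict(model, newdata)
  eps <- 1e-6 * max(diff(range(s)), .Machine$double.eps)
  drops <- which(diff(s) < -eps)
  list(verdict = if (length(drops) == 0L) "pass" else "fail",
       curve = data.frame(x = grid, score = s),
       first_decrease = if (length(drops) == 0L) NA_real_ else grid[drops[1]])
}

#' Gate specification for model acceptance
#'
#' @param min_sensitivity,min_specificity Minimum mean classifier
#'   sensitivity/specificity (default 0.75).
#' @param min_auc Minimum mean AUC of the score function (default 0.85).
#' @return A `gate_spec` object.
#' @export
gate_spec <- function(min_sensitivity = 0.75, min_specificity = 0.75,
                      min_auc = 0.85) {
  stopifnot(min_sensitivity >= 0, min_sensitivity <= 1,
            min_specificity >= 0, min_specificity <= 1,
            min_auc >= 0, min_auc <= 1)
  structure(list(min_sensitivity = min_sensitivity,
                 min_specificity = min_specificity, min_auc = min_auc),
            class = "gate_spec")
}

#' Accept or reject a model against the performance gate
#'
#' Accepts iff mean sensitivity, specificity and AUC meet their thresholds
#' (`>=` semantics) and, when a monotonicity verdict is supplied, it is
#' `"pass"`. Reasons enumerate every failed requirement.
#'
#' @param report An `eval_report` from [repeated_cv()], or a named list/vector
#'   with `sensitivity`, `specificity`, `auc` means.
#' @param gate A [gate_spec()].
#' @param monotonicity `"pass"`, `"fail"`, or `NA` to skip the requirement.
#' @return List with `accepted` (logical) and `reasons` (character).
#' @export
model_gate <- function(report, gate = gate_spec(), monotonicity = NA) {
  get_mean <- function(m) {
    v <- report[[m]]
    if (is.list(v)) v$mean else as.numeric(v)
  }
  sens <- get_mean("sensitivity"); spec <- get_mean("specificity")
  a <- get_mean("auc")
  reasons <- character(0)
  if (sens < gate$min_sensitivity) {
    reasons <- c(reasons, sprintf("sensitivity %.3f < %.2f", sens,
                                  gate$min_sensitivity))
  }
  if (spec < gate$min_specificity) {
    reasons <- c(reasons, sprintf("specificity %.3f < %.2f", spec,
                                  gate$min_specificity))
  }
  if (a < gate$min_auc) {
    reasons <- c(reasons, sprintf("AUC %.3f < %.2f", a, gate$min_auc))
  }
  if (!is.na(monotonicity) && !identical(monotonicity, "pass")) {
    reasons <- c(reasons, "non-monotonic dose response")
  }
  list(accepted = length(reasons) == 0L, reasons = reasons)
}

#' Feature profiles of extreme-score patients
#'
#' Returns the selected-feature values of the lowest-scoring fraction of
#' outcome-negative patients and the highest-scoring fraction of
#' outcome-positive patients (default 5% each, ceiling rounding), plus
#' per-group averages — the patients a score-based model is most confident
#' about, used to interpret what the features encode.
#'
#' @param scores Model scores.
#' @param labels Binary 0/1 labels.
#' @param table Feature table (selected features as columns).
#' @param features Columns to profile (default: all feature columns).
#' @param fraction Fraction per group (default 0.05).
#' @return List with data frames `low_risk`, `high_risk`; each carries an
#'   `"average"` attribute with the per-feature group means.
#' @export
extreme_patients <- function(scores, labels, table, features = NULL,
                             fraction = 0.05) {
  labels <- as.integer(labels)
  if (is.null(features)) features <- feature_columns(table)
  if (length(unique(scores)) == 1L) {
    warning("all scores equal; extreme subsets fall back to stable row order")
  }
  pick <- function(idx, decreasing) {
    k <- max(1L, ceiling(fraction * length(idx)))
    ord <- idx[order(scores[idx], decreasing = decreasing)]
    sel <- ord[seq_len(min(k, length(ord)))]
    df <- table[sel, features, drop = FALSE]
    df <- cbind(data.frame(score = scores[sel]), df)
    attr(df, "average") <- colMeans(df)
    df
  }
  list(low_risk = pick(which(labels == 0L), decreasing = FALSE),
       high_risk = pick(which(labels == 1L), decreasing = TRUE))
}
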