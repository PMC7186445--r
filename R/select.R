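#' Selection specification for stepwise wrapper selection
#'
#' @param max_vars Maximum number of selected features (the study scanned
#'   4 to 8).
#' @param folds Cross-validation folds (default 5).
#' @param allow_backward Also attempt single removals after each addition.
#' @param seed Seed fixing the fold assignment.
#' @return A `selection_spec` object.
#' @export
selection_spec <- function(max_vars = 4L, folds = 5L, allow_backward = FALSE,
                          seed = 1L) {
  if (max_vars < 1L) stop("max_vars must be >= 1")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(max_vars = as.integer(max_vars), folds = as.integer(folds),
                 allow_backward = isTRUE(allow_backward),
                 seed = as.integer(seed)),
            class = "selection_spec")
}

# mean out-of-fold binomial deviance of logistic GLM with columns `vars`
cv_deviance <- function(X, y, vars, fold) {
  k <- max(fold)
  dev <- 0
  eps <- 1e-12
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    df_tr <- data.frame(y = y[tr], X[tr, vars, drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                  family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    p <- tryCatch(
      suppressWarnings(stats::predict(
        fit, newdata = data.frame(X[te, vars, drop = FALSE]),
        type = "response")),
      error = function(e) NULL)
    if (is.null(p) || any(!is.finite(p))) return(Inf)
    p <- pmin(pmax(p, eps), 1 - eps)
    dev <- dev - 2 * sum(y[te] * log(p) + (1 - y[te]) * log(1 - p))
  }
  dev / length(y)
}

#' Stepwise forward feature selection by cross-validated GLM deviance
#'
#' Wrapper selection: starting from the empty model, each step evaluates
#' every unused candidate by the mean out-of-fold test deviance of a
#' logistic GLM (current set + candidate) under a seeded stratified k-fold
#' split that is held fixed across candidates within a step (paired
#' comparison), and adds the minimizer. Stops when no candidate improves the
#' criterion or `max_vars` is reached. Ties break lexicographically by
#' feature name. Candidates whose GLM fails to converge are assigned an
#' infinite criterion.
#'
#' @param table Data frame with `label` and numeric feature columns.
#' @param spec A [selection_spec()].
#' @return Character vector of selected feature names, in selection order,
#'   with attribute `"criterion"` (deviance trace).
#' @export
stepwise_forward_select <- function(table, spec = selection_spec()) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  y <- as.integer(table$label)
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  if (min(table(y)) < 2L * spec$folds) {
    stop("need >= 2*folds rows per class")
  }
  fold <- local_seed(spec$seed, stratified_folds(y, spec$folds))

  selected <- character(0)
  crit_trace <- numeric(0)
  best_crit <- cv_deviance(X, y, character(0), fold)
  repeat {
    cands <- sort(setdiff(feats, selected))
    if (length(cands) == 0L || length(selected) >= spec$max_vars) break
    scores <- vapply(cands, function(cn) {
      cv_deviance(X, y, c(selected, cn), fold)
    }, 0)
    j <- which.min(scores)  # first minimum = lexicographic tie-break
    if (!is.finite(scores[j]) || scores[j] >= best_crit) break
    selected <- c(selected, cands[j])
    best_crit <- scores[j]
    crit_trace <- c(crit_trace, best_crit)

    if (spec$allow_backward && length(selected) > 2L) {
      improved <- TRUE
      while (improved && length(selected) > 1L) {
        improved <- FALSE
        for (drop_nm in utils::head(selected, -1L)) {
          cand_set <- setdiff(selected, drop_nm)
          sc <- cv_deviance(X, y, cand_set, fold)
          if (sc < best_crit) {
            selected <- cand_set
            best_crit <- sc
            improved <- TRUE
            break
          }
        }
      }
    }
  }
  attr(selected, "criterion") <- crit_trace
  selected
}
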