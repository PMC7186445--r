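# shared: standardization parameters for the selected features
standardize_params <- function(table, features) {
  X <- as.matrix(table[, features, drop = FALSE])
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  list(center = mu, scale = sd_)
}

apply_standardize <- function(X, std) {
  sweep(sweep(as.matrix(X), 2, std$center), 2, std$scale, `/`)
}

new_trained_model <- function(family, features, std, threshold, hyper, fit,
                              score_fun) {
  structure(list(family = family, selected_features = features,
                 standardization = std, threshold = threshold,
                 hyperparameters = hyper, fit = fit, score_fun = score_fun),
            class = "trained_model")
}

#' Score new data with a trained model
#'
#' @param object A `trained_model`.
#' @param newdata Data frame (original feature units) containing the model's
#'   selected features.
#' @param type `"score"` (continuous, higher = positive class) or `"class"`
#'   (0/1 at the model threshold).
#' @param ... Unused.
#' @return Numeric vector of scores or 0/1 labels.
#' @export
predict.trained_model <- function(object, newdata, type = c("score", "class"),
                                  ...) {
  type <- match.arg(type)
  miss <- setdiff(object$selected_features, colnames(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks model features: ", paste(miss, collapse = ", "))
  }
  Z <- apply_standardize(newdata[, object$selected_features, drop = FALSE],
                         object$standardization)
  s <- object$score_fun(object$fit, Z)
  if (type == "score") s else as.integer(s >= object$threshold)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model:%s> %d features: %s\n", x$family,
              length(x$selected_features),
              paste(x$selected_features, collapse = ", ")))
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

check_training_input <- function(table, features) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  miss <- setdiff(features, names(table))
  if (length(miss) > 0) stop("missing features: ", paste(miss, collapse = ", "))
  y <- as.integer(table$label)
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  y
}

# Hyperparameter search harness shared by the three trainers.
#
# Candidates are compared by 5-fold cross-validated balanced error (mean of
# the two class-conditional misclassification rates; identical to plain
# misclassification on class-balanced data but robust to imbalance). When an
# `augment` hook is supplied, each training fold is augmented inside the
# fold and the held-out fold stays un-augmented, so synthetic near-copies of
# validation points can never leak into training during model selection; the
# winning candidate is refit on the augmented full table.
tune_by_cv <- function(table, y, candidates, fit_cand, seed, augment = NULL) {
  fold <- local_seed(seed, stratified_folds(y, 5L))
  tr_tabs <- lapply(seq_len(5L), function(f) {
    tt <- table[fold != f, , drop = FALSE]
    if (is.null(augment)) tt else augment(tt, f)
  })
  best <- NULL
  for (ci in seq_along(candidates)) {
    wrong <- c(0, 0); seen <- c(0, 0)
    failed <- FALSE
    for (f in seq_len(5L)) {
      val <- table[fold == f, , drop = FALSE]
      if (nrow(val) == 0L ||
          length(unique(tr_tabs[[f]]$label)) < 2L) next
      # a candidate that cannot be fit or scored gets an infinite criterion
      pred <- tryCatch({
        model <- fit_cand(candidates[[ci]], tr_tabs[[f]])
        predict(model, val, type = "class")
      }, error = function(e) NULL)
      if (is.null(pred)) { failed <- TRUE; break }
      for (cl in 0:1) {
        selr <- y[fold == f] == cl
        seen[cl + 1] <- seen[cl + 1] + sum(selr)
        wrong[cl + 1] <- wrong[cl + 1] + sum(pred[selr] != cl)
      }
    }
    err <- if (failed || all(seen == 0)) Inf else {
      mean((wrong / pmax(seen, 1))[seen > 0])
    }
    if (is.null(best) || err < best$err) best <- list(err = err, index = ci)
  }
  if (!is.finite(best$err)) {
    best$index <- 1L  # all candidates failed in CV; fall back to the first
  }
  final_tab <- if (is.null(augment)) table else augment(table, 0L)
  model <- fit_cand(candidates[[best$index]], final_tab)
  model$hyperparameters$cv_error <- best$err
  model
}

#' Train an RBF-kernel support vector machine
#'
#' Features are z-scored; the box constraint C and kernel scale gamma are
#' chosen on a seeded log-spaced grid by 5-fold cross-validated balanced
#' misclassification (see [cv_recipe()] for how augmentation interacts with
#' the inner folds). The model score is the signed decision value (positive
#' = toxicity side of the hyperplane), thresholded at 0.
#'
#' @param table Data frame with `label` and feature columns.
#' @param features Feature names to use.
#' @param seed Integer seed (fold assignment).
#' @param budget Number of (C, gamma) grid points, laid out as a
#'   `sqrt(budget) x sqrt(budget)` log grid over `10^-3..10^3` (default 25).
#' @param augment Optional function `(table, fold_index) -> table` applied to
#'   training folds during hyperparameter selection and to the full table
#'   before the final fit (used for leakage-safe in-fold ADASYN).
#' @return A `trained_model`.
#' @export
train_svm <- function(table, features, seed = 1L, budget = 25L,
                      augment = NULL) {
  y <- check_training_input(table, features)
  ng <- max(2L, floor(sqrt(budget)))
  grid_vals <- 10^seq(-3, 3, length.out = ng)
  candidates <- unname(split(expand.grid(C = grid_vals, gamma = grid_vals),
                             seq_len(ng * ng)))

  svm_score <- function(fit, Znew) {
    dv <- attr(stats::predict(fit, Znew, decision.values = TRUE),
               "decision.values")
    as.numeric(dv) * fit$dv_sign
  }
  fit_cand <- function(cand, tab) {
    std <- standardize_params(tab, features)
    Z <- apply_standardize(tab[, features, drop = FALSE], std)
    ytr <- as.integer(tab$label)
    fit <- e1071::svm(Z, factor(ytr, levels = c(0, 1)), kernel = "radial",
                      cost = cand$C, gamma = cand$gamma, scale = FALSE)
    # orient decision values so positives score higher
    dv <- as.numeric(attr(stats::predict(fit, Z, decision.values = TRUE),
                          "decision.values"))
    fit$dv_sign <- if (mean(dv[ytr == 1]) >= mean(dv[ytr == 0])) 1 else -1
    new_trained_model("svm", features, std, threshold = 0,
                      hyper = list(cost = cand$C, gamma = cand$gamma),
                      fit = fit, score_fun = svm_score)
  }
  tune_by_cv(table, y, candidates, fit_cand, seed, augment)
}

#' Train a naive-Bayes classifier
#'
#' Per-feature class-conditional densities, either Gaussian or kernel
#' (Gaussian KDE with a searched bandwidth multiplier); the distribution
#' type is chosen by seeded 5-fold cross-validated balanced
#' misclassification. Score = posterior probability of the positive class
#' under empirical priors, threshold 0.5. Zero-variance features within a
#' class fall back to a minimum-bandwidth kernel density.
#'
#' @inheritParams train_svm
#' @return A `trained_model`.
#' @export
train_nb <- function(table, features, seed = 1L, augment = NULL) {
  y <- check_training_input(table, features)
  candidates <- list(list(dist = "gaussian", bw_mult = NA),
                     list(dist = "kernel", bw_mult = 0.5),
                     list(dist = "kernel", bw_mult = 1),
                     list(dist = "kernel", bw_mult = 2))
  nb_score <- function(fit, Znew) nb_posterior(fit, Znew)
  fit_cand <- function(cand, tab) {
    std <- standardize_params(tab, features)
    Z <- apply_standardize(tab[, features, drop = FALSE], std)
    fit <- nb_fit(Z, as.integer(tab$label), cand$dist, cand$bw_mult)
    new_trained_model("nb", features, std, threshold = 0.5,
                      hyper = list(distribution = cand$dist,
                                   bw_mult = cand$bw_mult),
                      fit = fit, score_fun = nb_score)
  }
  tune_by_cv(table, y, candidates, fit_cand, seed, augment)
}

nb_fit <- function(X, y, dist, bw_mult) {
  classes <- c(0L, 1L)
  prior <- vapply(classes, function(cl) mean(y == cl), 0)
  per_class <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(X)), function(j) {
      xj <- Xc[, j]
      s <- stats::sd(xj)
      if (dist == "gaussian" && (is.na(s) || s < 1e-10)) {
        # degenerate: minimum-bandwidth kernel instead of a zero-sd Gaussian
        list(type = "kernel", x = xj, bw = 1e-3)
      } else if (dist == "gaussian") {
        list(type = "gaussian", mean = mean(xj), sd = s)
      } else {
        bw <- stats::bw.nrd0(xj)
        if (!is.finite(bw) || bw < 1e-3) bw <- 1e-3
        list(type = "kernel", x = xj, bw = bw * bw_mult)
      }
    })
  })
  list(prior = prior, per_class = per_class, p = ncol(X))
}

nb_posterior <- function(fit, Znew) {
  Znew <- as.matrix(Znew)
  loglik <- matrix(log(fit$prior), nrow(Znew), 2, byrow = TRUE)
  for (cl in 1:2) {
    for (j in seq_len(fit$p)) {
      dens <- fit$per_class[[cl]][[j]]
      lj <- if (dens$type == "gaussian") {
        stats::dnorm(Znew[, j], dens$mean, dens$sd, log = TRUE)
      } else {
        # Gaussian KDE evaluated at the query points
        log(pmax(vapply(Znew[, j], function(q) {
          mean(stats::dnorm(q, dens$x, dens$bw))
        }, 0), 1e-300))
      }
      loglik[, cl] <- loglik[, cl] + lj
    }
  }
  mx <- pmax(loglik[, 1], loglik[, 2])
  exp(loglik[, 2] - mx) / (exp(loglik[, 1] - mx) + exp(loglik[, 2] - mx))
}
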