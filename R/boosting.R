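# Tree-ensemble engine: random forest plus four boosting variants with
# rpart weak learners (AdaBoost.M1, LogitBoost, GentleBoost, RUSBoost).
# Scores are aggregated margins (boosting) or vote fractions (forest).

boost_tree_control <- function(min_leaf) {
  rpart::rpart.control(maxdepth = 3, minbucket = min_leaf, minsplit = 2,
                       cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0)
}

# classification stump/shallow tree returning the class-weighted fit
fit_weak_classifier <- function(X, y01, w, min_leaf) {
  df <- data.frame(y = factor(y01, levels = c(0, 1)), X, check.names = FALSE)
  rpart::rpart(y ~ ., data = df, weights = w / mean(w), method = "class",
               control = boost_tree_control(min_leaf))
}

# regression tree on a working response (Logit/GentleBoost)
fit_weak_regressor <- function(X, z, w, min_leaf) {
  df <- data.frame(z = z, X, check.names = FALSE)
  rpart::rpart(z ~ ., data = df, weights = w / mean(w), method = "anova",
               control = boost_tree_control(min_leaf))
}

predict_weak_class <- function(tree, X) {
  p <- stats::predict(tree, data.frame(X, check.names = FALSE))
  # column "1" = probability of class 1
  ifelse(p[, "1"] >= 0.5, 1, -1)
}

predict_weak_reg <- function(tree, X) {
  stats::predict(tree, data.frame(X, check.names = FALSE))
}

fit_boosted <- function(X, y, algorithm, n_cycles, learn_rate, min_leaf) {
  n <- nrow(X)
  ys <- ifelse(y == 1L, 1, -1)  # {-1, +1}
  trees <- vector("list", n_cycles)
  alphas <- numeric(n_cycles)
  kind <- character(n_cycles)
  Fx <- rep(0, n)
  w <- rep(1 / n, n)
  used <- 0L
  for (t in seq_len(n_cycles)) {
    if (algorithm %in% c("adaboost", "rusboost")) {
      if (algorithm == "rusboost") {
        # undersample the majority class at each iteration
        i_pos <- which(y == 1L); i_neg <- which(y == 0L)
        if (length(i_pos) <= length(i_neg)) {
          keep <- c(i_pos, sample(i_neg, length(i_pos)))
        } else {
          keep <- c(i_neg, sample(i_pos, length(i_neg)))
        }
        tree <- fit_weak_classifier(X[keep, , drop = FALSE], y[keep],
                                    w[keep], min_leaf)
      } else {
        tree <- fit_weak_classifier(X, y, w, min_leaf)
      }
      h <- predict_weak_class(tree, X)
      err <- sum(w[h != ys]) / sum(w)
      if (err >= 0.5 || err <= 0) {
        if (err <= 0) {  # perfect learner: keep with a capped weight
          used <- used + 1L
          trees[[used]] <- tree; alphas[used] <- learn_rate * 5
          kind[used] <- "class"
        }
        break
      }
      a <- learn_rate * 0.5 * log((1 - err) / err)
      used <- used + 1L
      trees[[used]] <- tree; alphas[used] <- a; kind[used] <- "class"
      w <- w * exp(-a * ys * h)
      w <- w / sum(w)
    } else if (algorithm == "logitboost") {
      p <- 1 / (1 + exp(-2 * Fx))
      wt <- pmax(p * (1 - p), 1e-6)
      z <- (as.numeric(y == 1L) - p) / wt
      z <- pmin(pmax(z, -4), 4)
      tree <- fit_weak_regressor(X, z, wt, min_leaf)
      f <- predict_weak_reg(tree, X)
      used <- used + 1L
      trees[[used]] <- tree; alphas[used] <- learn_rate * 0.5
      kind[used] <- "reg"
      Fx <- Fx + alphas[used] * f
    } else if (algorithm == "gentleboost") {
      wt <- exp(-ys * Fx)
      wt <- wt / sum(wt)
      tree <- fit_weak_regressor(X, ys, wt, min_leaf)
      f <- predict_weak_reg(tree, X)
      used <- used + 1L
      trees[[used]] <- tree; alphas[used] <- learn_rate
      kind[used] <- "reg"
      Fx <- Fx + alphas[used] * f
    } else {
      stop("unknown boosting algorithm: ", algorithm)
    }
  }
  list(trees = trees[seq_len(used)], alphas = alphas[seq_len(used)],
       kind = kind[seq_len(used)], algorithm = algorithm)
}

predict_boosted <- function(fit, X) {
  if (length(fit$trees) == 0L) return(rep(0, nrow(X)))
  s <- rep(0, nrow(X))
  for (t in seq_along(fit$trees)) {
    h <- if (fit$kind[t] == "class") {
      predict_weak_class(fit$trees[[t]], X)
    } else {
      predict_weak_reg(fit$trees[[t]], X)
    }
    s <- s + fit$alphas[t] * h
  }
  s
}

#' Train a tree-ensemble classifier with algorithm search
#'
#' Decision trees are the weak learners. A seeded random search over the
#' ensemble algorithm (random forest / bagging, AdaBoost, LogitBoost,
#' GentleBoost, RUSBoost) and its hyperparameters (number of learning
#' cycles, learning rate, minimum leaf size) picks the combination with the
#' lowest 5-fold cross-validated misclassification. The score is the
#' aggregated margin (boosting, threshold 0) or the positive-vote fraction
#' (forest, threshold 0.5), rescaled to a common margin convention.
#'
#' @inheritParams train_svm
#' @param budget Number of random search draws (default 20).
#' @return A `trained_model`.
#' @export
train_ensemble <- function(table, features, seed = 1L, budget = 20L,
                           augment = NULL) {
  y <- check_training_input(table, features)
  algorithms <- c("rf", "adaboost", "logitboost", "gentleboost", "rusboost")
  draws <- local_seed(stage_seed(seed, "ensemble_draws"), unique(data.frame(
    algorithm = sample(algorithms, budget, replace = TRUE),
    n_cycles = sample(c(30L, 60L, 120L), budget, replace = TRUE),
    learn_rate = sample(c(0.1, 0.5, 1), budget, replace = TRUE),
    min_leaf = sample(c(1L, 5L, 10L), budget, replace = TRUE)
  )))
  candidates <- unname(split(draws, seq_len(nrow(draws))))

  fit_cand <- function(dr, tab) {
    std <- standardize_params(tab, features)
    Z <- apply_standardize(tab[, features, drop = FALSE], std)
    colnames(Z) <- features
    ytr <- as.integer(tab$label)
    fit <- local_seed(stage_seed(seed, paste0("ensemble_fit", nrow(tab))), {
      if (dr$algorithm == "rf") {
        list(rf = randomForest::randomForest(
          Z, factor(ytr, levels = c(0, 1)), ntree = dr$n_cycles,
          nodesize = dr$min_leaf), algorithm = "rf")
      } else {
        fit_boosted(Z, ytr, dr$algorithm, dr$n_cycles, dr$learn_rate,
                    dr$min_leaf)
      }
    })
    new_trained_model("eml", features, std, threshold = 0,
                      hyper = list(algorithm = dr$algorithm,
                                   n_cycles = dr$n_cycles,
                                   learn_rate = dr$learn_rate,
                                   min_leaf = dr$min_leaf),
                      fit = fit,
                      score_fun = function(f, Xn) ensemble_score(f, Xn))
  }
  tune_by_cv(table, y, candidates, fit_cand, seed, augment)
}

ensemble_score <- function(fit, X) {
  if (identical(fit$algorithm, "rf")) {
    # vote fraction mapped to a margin centred at 0
    p <- stats::predict(fit$rf, X, type = "prob")[, "1"]
    2 * p - 1
  } else {
    predict_boosted(fit, X)
  }
}
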