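test_that("a strongly separated feature is chosen first almost always", {
  hits <- vapply(1:20, function(s) {
    tab <- generate_feature_table(30, 30, n_features = 10, shift = c(3),
                                  seed = s)
    f1 <- setdiff(names(tab), c("patient_id", "label"))[1]
    sel <- stepwise_forward_select(tab, selection_spec(max_vars = 2, seed = s))
    identical(sel[1], f1)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("selection matches an exhaustive single-feature deviance scan", {
  tab <- generate_feature_table(40, 40, n_features = 8, shift = c(2), seed = 3)
  feats <- setdiff(names(tab), c("patient_id", "label"))
  spec <- selection_spec(max_vars = 1, seed = 5)
  sel <- stepwise_forward_select(tab, spec)
  expect_length(sel, 1)
  # oracle: same fold split, scan each single feature with plain glm
  y <- tab$label
  fold <- bedomics:::local_seed(spec$seed,
                                bedomics:::stratified_folds(y, spec$folds))
  devs <- vapply(feats, function(fn) {
    dev <- 0
    for (f in 1:5) {
      fit <- suppressWarnings(
        stats::glm(y ~ ., data.frame(y = y, tab[fn])[fold != f, ],
                   family = stats::binomial()))
      p <- suppressWarnings(
        stats::predict(fit, newdata = tab[fold == f, fn, drop = FALSE],
                       type = "response"))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      yt <- y[fold == f]
      dev <- dev - 2 * sum(yt * log(p) + (1 - yt) * log(1 - p))
    }
    dev / length(y)
  }, 0)
  expect_identical(sel[1], names(which.min(devs)))
})

test_that("max_vars caps the selection size", {
  tab <- generate_feature_table(40, 40, n_features = 10,
                                shift = c(2, 1.5, 1, 1), seed = 4)
  sel <- stepwise_forward_select(tab, selection_spec(max_vars = 1, seed = 1))
  expect_length(sel, 1)
  sel3 <- stepwise_forward_select(tab, selection_spec(max_vars = 3, seed = 1))
  expect_lte(length(sel3), 3)
})

test_that("a duplicated column is never selected after its twin", {
  tab <- generate_feature_table(40, 40, n_features = 6, shift = c(2.5), seed = 5)
  feats <- setdiff(names(tab), c("patient_id", "label"))
  tab$zz_twin <- tab[[feats[1]]]  # exact duplicate, sorts last
  sel <- stepwise_forward_select(tab, selection_spec(max_vars = 4, seed = 2))
  if (feats[1] %in% sel) {
    expect_false("zz_twin" %in% sel)
  }
})

test_that("selection is invariant to feature column order", {
  tab <- generate_feature_table(40, 40, n_features = 8, shift = c(2, 1),
                                seed = 6)
  meta <- c("patient_id", "label")
  feats <- setdiff(names(tab), meta)
  tab_shuffled <- tab[, c(meta, rev(feats))]
  s1 <- stepwise_forward_select(tab, selection_spec(max_vars = 3, seed = 3))
  s2 <- stepwise_forward_select(tab_shuffled, selection_spec(max_vars = 3,
                                                            seed = 3))
  expect_identical(as.character(s1), as.character(s2))
})

test_that("the SVM solves linearly separable and XOR problems", {
  set.seed(7)
  n <- 60
  sep <- data.frame(label = rep(c(0, 1), each = n),
                    f1 = c(rnorm(n, -3, 0.3), rnorm(n, 3, 0.3)),
                    f2 = rnorm(2 * n))
  m <- train_svm(sep, c("f1", "f2"), seed = 1, budget = 16)
  expect_equal(m$hyperparameters$cv_error, 0)
  # orientation: positive-class training scores higher on average
  s <- predict(m, sep)
  expect_gt(mean(s[sep$label == 1]), mean(s[sep$label == 0]))

  xor_tab <- data.frame(
    f1 = c(rnorm(n, -2, 0.4), rnorm(n, 2, 0.4), rnorm(n, -2, 0.4),
           rnorm(n, 2, 0.4)),
    f2 = c(rnorm(n, -2, 0.4), rnorm(n, 2, 0.4), rnorm(n, 2, 0.4),
           rnorm(n, -2, 0.4)),
    label = rep(c(1, 1, 0, 0), each = n))
  m_rbf <- train_svm(xor_tab, c("f1", "f2"), seed = 2, budget = 16)
  expect_lt(m_rbf$hyperparameters$cv_error, 0.1)  # CV accuracy > 0.9
  # a linear model cannot separate XOR: logistic regression stays ~ chance
  glm_fit <- stats::glm(label ~ f1 + f2, xor_tab, family = stats::binomial())
  acc_lin <- mean((stats::predict(glm_fit) > 0) == (xor_tab$label == 1))
  expect_lt(abs(acc_lin - 0.5), 0.12)
})

test_that("SVM training is deterministic and scores are finite", {
  tab <- generate_feature_table(40, 60, n_features = 4, shift = c(1.5), seed = 8)
  feats <- setdiff(names(tab), c("patient_id", "label"))[1:2]
  m1 <- train_svm(tab, feats, seed = 5, budget = 9)
  m2 <- train_svm(tab, feats, seed = 5, budget = 9)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(predict(m1, tab), predict(m2, tab))
  expect_true(all(is.finite(predict(m1, tab))))
  expect_error(train_svm(tab[tab$label == 1, ], feats), "single class")
})

test_that("ensembles track the Bayes rule on a monotone step signal", {
  set.seed(9)
  n <- 150
  tab <- data.frame(f1 = c(runif(n, 0, 1), runif(n, 1.05, 2)),
                    label = rep(c(0, 1), each = n))
  m <- train_ensemble(tab, "f1", seed = 1, budget = 10)
  expect_lte(m$hyperparameters$cv_error, 0.1)  # Bayes rate is 0 here
  s <- predict(m, data.frame(f1 = c(0.2, 1.8)))
  expect_gt(s[2], s[1])
})

test_that("ensembles on pure noise stay near the majority-class rate", {
  tab <- generate_feature_table(60, 90, n_features = 4, shift = c(0), seed = 10)
  feats <- setdiff(names(tab), c("patient_id", "label"))[1:2]
  m <- train_ensemble(tab, feats, seed = 2, budget = 8)
  expect_lt(abs(m$hyperparameters$cv_error - 60 / 150), 0.1)
})

test_that("ensemble search is deterministic given the seed", {
  tab <- generate_feature_table(40, 50, n_features = 3, shift = c(1), seed = 11)
  feats <- setdiff(names(tab), c("patient_id", "label"))
  m1 <- train_ensemble(tab, feats, seed = 3, budget = 8)
  m2 <- train_ensemble(tab, feats, seed = 3, budget = 8)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(predict(m1, tab), predict(m2, tab))
})

test_that("naive Bayes recovers the midpoint boundary of two Gaussians", {
  set.seed(12)
  tab <- data.frame(label = rep(c(0, 1), each = 3000),
                    f1 = c(rnorm(3000, 0), rnorm(3000, 2)))
  m <- train_nb(tab, "f1", seed = 1)
  xs <- seq(0, 2, by = 0.002)
  post <- predict(m, data.frame(f1 = xs))
  boundary <- xs[which.min(abs(post - 0.5))]
  expect_equal(boundary, 1.0, tolerance = 0.1)
})

test_that("naive Bayes posteriors are normalized and priors dominate null data", {
  set.seed(13)
  tab <- data.frame(label = rep(c(0, 1), c(120, 40)), f1 = rnorm(160))
  m <- train_nb(tab, "f1", seed = 2)
  post <- predict(m, data.frame(f1 = seq(-2, 2, length.out = 50)))
  expect_true(all(post >= 0 & post <= 1))
  # identical class distributions: posterior tracks the class prior (0.25)
  expect_lt(abs(mean(post) - 0.25), 0.1)
  expect_true(all(post < 0.5))  # never flips to the minority class
  # complementary posterior sums to one by construction
  fit <- m$fit
  Z <- bedomics:::apply_standardize(
    data.frame(f1 = c(-1, 0, 1)), m$standardization)
  p1 <- bedomics:::nb_posterior(fit, Z)
  expect_true(all(abs((1 - p1) + p1 - 1) < 1e-12))
})

test_that("zero-variance features fall back to kernel densities", {
  tab <- data.frame(label = rep(c(0, 1), each = 20),
                    f1 = c(rep(1, 20), rnorm(20, 2)),
                    f2 = rnorm(40))
  m <- train_nb(tab, c("f1", "f2"), seed = 3)
  expect_true(all(is.finite(predict(m, tab))))
})
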