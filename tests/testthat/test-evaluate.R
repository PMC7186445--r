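# a hand-built model whose score is an arbitrary function of its features;
# used to test evaluation machinery independently of the trainers
toy_model <- function(features, fun, threshold = 0) {
  bedomics:::new_trained_model(
    "svm", features,
    std = list(center = stats::setNames(rep(0, length(features)), features),
               scale = stats::setNames(rep(1, length(features)), features)),
    threshold = threshold, hyper = list(),
    fit = fun,
    score_fun = function(fit, Z) fit(as.data.frame(Z)))
}

test_that("AUC matches pair enumeration, boundary cases and pROC", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc(rep(5, 10), rep(c(0, 1), 5)), 0.5)
  # 4 pairs: (0.35 > 0.1), (0.35 < 0.4), (0.8 > 0.1), (0.8 > 0.4) -> 3/4
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:5, rep(1, 5)), "both classes")
  set.seed(20)
  for (i in 1:20) {
    n <- 60
    s <- rnorm(n) + rep(c(0, 0.8), each = n / 2)
    if (i %% 3 == 0) s <- round(s)  # exercise ties
    y <- rep(c(0, 1), each = n / 2)
    expect_equal(auc(s, y),
                 as.numeric(suppressMessages(pROC::auc(y, s,
                                                       direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("repeated CV of random scores is centred at 0.5", {
  tab <- generate_feature_table(100, 100, n_features = 3, shift = c(0),
                                seed = 21)
  recipe <- cv_recipe("nb", features = setdiff(names(tab),
                                               c("patient_id", "label"))[1])
  rep_ <- repeated_cv(tab, recipe, cv_spec(repeats = 20, seed = 1,
                                           leakage_mode = "safe"))
  expect_gt(rep_$auc$mean, 0.44)
  expect_lt(rep_$auc$mean, 0.56)
  expect_lte(rep_$auc$ci[1], rep_$auc$mean)
  expect_gte(rep_$auc$ci[2], rep_$auc$mean)
})

test_that("a deterministic perfect signal yields unit metrics with zero-width CI", {
  set.seed(22)
  tab <- data.frame(patient_id = sprintf("p%03d", 1:80),
                    label = rep(c(0, 1), each = 40),
                    f1 = c(rnorm(40, -6, 0.3), rnorm(40, 6, 0.3)))
  recipe <- cv_recipe("svm", features = "f1", budget = 4)
  rep_ <- repeated_cv(tab, recipe, cv_spec(repeats = 5, seed = 2,
                                           leakage_mode = "safe"))
  expect_equal(rep_$sensitivity$mean, 1)
  expect_equal(rep_$specificity$mean, 1)
  expect_equal(rep_$auc$mean, 1)
  expect_equal(unname(diff(rep_$auc$ci)), 0)
})

test_that("augment-first evaluation inflates CV AUC relative to safe mode", {
  aucs <- vapply(1:8, function(s) {
    cfg <- cohort_config(n_patients = 90L, prevalence = 0.25, seed = s,
                         effect_coefficients = c(bed_gaussian_ptv_firstorder_p10 = 0.8))
    tab <- generate_cohort_features(cfg, n_noise = 2)
    recipe <- cv_recipe("nb", features = "bed_gaussian_ptv_firstorder_p10",
                        adasyn = adasyn_params(seed = s))
    a_first <- repeated_cv(tab, recipe,
                           cv_spec(repeats = 4, seed = s,
                                   leakage_mode = "augment_first"))$auc$mean
    a_safe <- repeated_cv(tab, recipe,
                          cv_spec(repeats = 4, seed = s,
                                  leakage_mode = "safe"))$auc$mean
    c(a_first, a_safe)
  }, c(0, 0))
  expect_gt(mean(aucs[1, ] - aucs[2, ]), 0)
})

test_that("percentile CIs narrow as repeats grow", {
  tab <- generate_feature_table(60, 60, n_features = 2, shift = c(1), seed = 23)
  f1 <- setdiff(names(tab), c("patient_id", "label"))[1]
  recipe <- cv_recipe("nb", features = f1)
  w <- vapply(c(10, 40), function(reps) {
    r <- repeated_cv(tab, recipe, cv_spec(repeats = reps, seed = 3,
                                          leakage_mode = "safe"))
    unname(diff(r$auc$ci))
  }, 0)
  expect_lte(w[2], w[1] * 1.5)  # no blow-up; typically narrower
})

test_that("resubstitution on an overfit memorizer gives perfect metrics", {
  # mirrors the pathology of evaluating on rows the model has memorized
  tab <- generate_feature_table(30, 60, n_features = 3, shift = c(1), seed = 24)
  lookup <- tab
  m <- toy_model(setdiff(names(tab), c("patient_id", "label")),
                 function(df) {
                   # memorize: return the training label of the nearest row
                   X0 <- as.matrix(lookup[, colnames(df)])
                   apply(as.matrix(df), 1, function(r) {
                     lookup$label[which.min(colSums((t(X0) - r)^2))]
                   })
                 }, threshold = 0.5)
  res <- evaluate_on_original(m, tab)
  expect_equal(unname(res["sensitivity"]), 1)
  expect_equal(unname(res["specificity"]), 1)
  expect_equal(unname(res["auc"]), 1)
})

test_that("a constant-score model cannot have both sensitivity and specificity", {
  tab <- generate_feature_table(20, 30, n_features = 2, shift = c(1), seed = 25)
  feats <- setdiff(names(tab), c("patient_id", "label"))
  m <- toy_model(feats, function(df) rep(1, nrow(df)), threshold = 0.5)
  res <- evaluate_on_original(m, tab)
  expect_equal(unname(res["sensitivity"]), 1)
  expect_equal(unname(res["specificity"]), 0)
})

test_that("metrics at threshold match a brute-force confusion matrix", {
  set.seed(26)
  tab <- generate_feature_table(40, 60, n_features = 2, shift = c(1.5),
                                seed = 26)
  feats <- setdiff(names(tab), c("patient_id", "label"))
  m <- train_svm(tab, feats, seed = 1, budget = 9)
  res <- evaluate_on_original(m, tab)
  s <- predict(m, tab)
  pred <- as.integer(s >= m$threshold)
  tp <- sum(pred == 1 & tab$label == 1); fn <- sum(pred == 0 & tab$label == 1)
  tn <- sum(pred == 0 & tab$label == 0); fp <- sum(pred == 1 & tab$label == 0)
  expect_equal(unname(res["sensitivity"]), tp / (tp + fn))
  expect_equal(unname(res["specificity"]), tn / (tn + fp))
})

test_that("chi-square and Wilcoxon tests match hand-derived references", {
  # 2x2 table (50,10 / 10,50): X2 = 53.3, df 1 -> p << 1e-6
  x <- rep(c("a", "a", "b", "b"), c(50, 10, 10, 50))
  y <- rep(c(0, 1, 0, 1), c(50, 10, 10, 50))
  res <- univariate_tests(data.frame(g = x), y)
  expect_equal(res$type, "chisq")
  expect_lt(res$p_value, 1e-6)
  chi_hand <- suppressWarnings(stats::chisq.test(table(x, y),
                                                 correct = FALSE)$statistic)
  expect_equal(unname(chi_hand), 53 + 1 / 3, tolerance = 1e-10)

  set.seed(27)
  v <- c(rnorm(40), rnorm(40, 2))
  lab <- rep(c(0, 1), each = 40)
  res2 <- univariate_tests(data.frame(v = v), lab)
  expect_equal(res2$type, "wilcoxon")
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$p_value,
               suppressWarnings(stats::wilcox.test(v[lab == 1],
                                                   v[lab == 0])$p.value))
})

test_that("permutation-null p-values are approximately uniform", {
  set.seed(28)
  v <- rnorm(60)
  ps <- vapply(1:400, function(i) {
    univariate_tests(data.frame(v = v), sample(rep(c(0, 1), 30)))$p_value
  }, 0)
  # rank-based p-values are discrete, so KS ties are expected
  ks <- suppressWarnings(stats::ks.test(ps, "punif")$p.value)
  expect_gt(ks, 0.01)
})

test_that("monotone scores pass vetting and unimodal scores fail with location", {
  tab <- data.frame(bed_f = seq(0, 100, length.out = 60), other = rnorm(60))
  mono <- toy_model(c("bed_f", "other"), function(df) df$bed_f)
  res <- monotonicity_vetting(mono, "bed_f", tab)
  expect_equal(res$verdict, "pass")
  expect_true(is.na(res$first_decrease))

  unim <- toy_model(c("bed_f", "other"),
                    function(df) -(df$bed_f - 50)^2)
  res2 <- monotonicity_vetting(unim, "bed_f", tab)
  expect_equal(res2$verdict, "fail")
  # the quadratic peaks at 50: the located decrease starts there
  expect_equal(res2$first_decrease, 50, tolerance = 2)
  expect_equal(nrow(res2$curve), 100)
})

test_that("vetting requires the feature and a nonzero range", {
  tab <- data.frame(bed_f = rep(1, 10), other = rnorm(10))
  m <- toy_model(c("bed_f", "other"), function(df) df$bed_f)
  expect_error(monotonicity_vetting(m, "not_there", tab), "selected features")
  expect_error(monotonicity_vetting(m, "bed_f", tab), "zero observed range")
})

test_that("the acceptance gate reproduces accept/reject patterns", {
  # accepted profile: 0.83 / 0.75 / 0.86 with monotone response
  g1 <- model_gate(list(sensitivity = 0.83, specificity = 0.75, auc = 0.86),
                   gate_spec(), monotonicity = "pass")
  expect_true(g1$accepted)
  # high-sensitivity / low-specificity profile is rejected on specificity
  g2 <- model_gate(list(sensitivity = 0.92, specificity = 0.44, auc = 0.82),
                   gate_spec(), monotonicity = "pass")
  expect_false(g2$accepted)
  expect_true(any(grepl("specificity", g2$reasons)))
  expect_true(any(grepl("AUC", g2$reasons)))
  # exact threshold values are accepted (>= semantics)
  g3 <- model_gate(list(sensitivity = 0.75, specificity = 0.75, auc = 0.85),
                   gate_spec(), monotonicity = "pass")
  expect_true(g3$accepted)
  # monotonicity failure alone rejects
  g4 <- model_gate(list(sensitivity = 0.9, specificity = 0.9, auc = 0.95),
                   gate_spec(), monotonicity = "fail")
  expect_false(g4$accepted)
  expect_true(any(grepl("monotonic", g4$reasons)))
})

test_that("extreme-patient profiling slices the score tails correctly", {
  set.seed(29)
  n <- 165
  lab <- rep(c(0, 1), c(124, 41))
  sc <- rnorm(n) + lab
  tab <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  ex <- extreme_patients(sc, lab, tab, fraction = 0.05)
  expect_equal(nrow(ex$low_risk), ceiling(0.05 * 124))  # 7
  expect_equal(nrow(ex$high_risk), ceiling(0.05 * 41))  # 3
  # oracle: sort-and-slice
  neg_idx <- which(lab == 0)
  expect_equal(sort(ex$low_risk$score),
               sort(sc[neg_idx[order(sc[neg_idx])][1:7]]))
  avg <- attr(ex$low_risk, "average")
  expect_equal(unname(avg["f1"]), mean(ex$low_risk$f1))
  expect_warning(extreme_patients(rep(1, n), lab, tab), "stable row order")
})
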