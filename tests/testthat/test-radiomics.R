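test_that("a digital ball has near-unit sphericity and a cube unit axis ratios", {
  mk <- ball_mask(10)
  sf <- shape_features(mk)
  expect_gte(sf[["sphericity"]], 0.95)
  expect_lte(sf[["sphericity"]], 1.0)
  expect_equal(sf[["voxel_count"]], sum(mk$values))
  expect_equal(sf[["max_3d_diameter"]], 20, tolerance = 0.1)

  cube <- array(FALSE, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- TRUE
  sfc <- shape_features(roi_mask(cube, c(1, 1, 1)))
  expect_equal(sfc[["elongation"]], 1, tolerance = 1e-9)
  expect_equal(sfc[["flatness"]], 1, tolerance = 1e-9)
  expect_equal(sfc[["volume_mm3"]], 1000)
})

test_that("doubling the spacing scales volume by 8 and surface by 4", {
  cube <- array(FALSE, c(12, 12, 12)); cube[3:9, 3:9, 3:9] <- TRUE
  s1 <- shape_features(roi_mask(cube, c(1, 1, 1)))
  s2 <- shape_features(roi_mask(cube, c(2, 2, 2)))
  expect_equal(s2[["volume_mm3"]] / s1[["volume_mm3"]], 8)
  expect_equal(s2[["surface_area_mm2"]] / s1[["surface_area_mm2"]], 4,
               tolerance = 1e-9)
  expect_equal(s2[["max_3d_diameter"]] / s1[["max_3d_diameter"]], 2)
})

test_that("single-voxel masks warn and use the voxel cube surface", {
  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  expect_warning(sf <- shape_features(roi_mask(sv, c(2, 2, 2))), "single-voxel")
  expect_equal(sf[["surface_area_mm2"]], 6 * 4)  # six 2x2 mm faces
})

test_that("first-order features match hand-computed values on 1..100", {
  vals <- array(1:100, c(100, 1, 1))
  v <- volume_grid(vals, c(1, 1, 1))
  m <- roi_mask(array(TRUE, c(100, 1, 1)), c(1, 1, 1))
  fo <- firstorder_features(v, m)
  expect_equal(fo[["range"]], 99)
  expect_equal(fo[["p10"]], 10.9)  # linear-interpolation percentile
  expect_equal(fo[["p90"]], 90.1)
  expect_equal(fo[["median"]], 50.5)
  expect_equal(fo[["mean"]], 50.5)
  expect_equal(fo[["minimum"]], 1)
  expect_equal(fo[["maximum"]], 100)
})

test_that("constant ROIs give zero variance/range and flagged zero kurtosis", {
  v <- volume_grid(array(7, c(3, 3, 3)), c(1, 1, 1))
  m <- roi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  fo <- firstorder_features(v, m)
  expect_equal(fo[["variance"]], 0)
  expect_equal(fo[["range"]], 0)
  expect_equal(fo[["skewness"]], 0)
  expect_equal(fo[["kurtosis"]], 0)
  expect_true(isTRUE(attr(fo, "degenerate")))
})

test_that("excess kurtosis of a large normal sample is near zero", {
  set.seed(10)
  n <- 1e5
  d <- c(50, 50, 40)
  v <- volume_grid(array(rnorm(prod(d)), d), c(1, 1, 1))
  m <- roi_mask(array(TRUE, d), c(1, 1, 1))
  fo <- firstorder_features(v, m)
  # independent moment-formula oracle on the same sample
  x <- v$values[m$values]
  k_oracle <- mean((x - mean(x))^4) / mean((x - mean(x))^2)^2 - 3
  expect_equal(fo[["kurtosis"]], k_oracle, tolerance = 1e-12)
  expect_lt(abs(fo[["kurtosis"]]), 0.1)
  expect_equal(fo[["skewness"]],
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5,
               tolerance = 1e-12)
})

test_that("uniform and symmetric patterns give zero cluster shade", {
  lev <- array(1L, c(4, 4, 4))
  expect_equal(glcm_features(make_disc(lev, 4))[["cluster_shade"]], 0)
  # checkerboard: two levels, symmetric joint histogram
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  lev2 <- array(1L + (rowSums(idx) %% 2L), c(4, 4, 4))
  expect_equal(glcm_features(make_disc(lev2, 2))[["cluster_shade"]], 0,
               tolerance = 1e-12)
})

test_that("GLCM features match brute-force pair enumeration on random grids", {
  set.seed(11)
  for (rep_i in 1:50) {
    ng <- sample(3:6, 1)
    lev <- array(sample.int(ng, 125, TRUE), c(5, 5, 5))
    if (rep_i %% 7 == 0) lev[sample(125, 30)] <- NA  # partial ROI
    disc <- make_disc(lev, ng)
    p <- glcm_matrix(disc)
    p_bf <- bf_glcm(lev, ng)
    expect_equal(p, p_bf, tolerance = 1e-12)
    f <- glcm_features(disc)
    f_bf <- bf_glcm_features(p_bf)
    for (nm in c("cluster_shade", "contrast", "inverse_variance",
                 "correlation", "joint_entropy")) {
      expect_equal(f[[nm]], f_bf[[nm]], tolerance = 1e-10)
    }
  }
})

test_that("GLRLM features match brute-force run enumeration on random grids", {
  set.seed(12)
  for (rep_i in 1:50) {
    ng <- sample(2:5, 1)
    lev <- array(sample.int(ng, 125, TRUE), c(5, 5, 5))
    if (rep_i %% 5 == 0) lev[sample(125, 25)] <- NA
    m <- glrlm_matrix(make_disc(lev, ng))
    cnt_bf <- bf_glrlm(lev)
    expect_equal(m$r[seq_len(nrow(cnt_bf)), seq_len(ncol(cnt_bf))], cnt_bf,
                 tolerance = 1e-12)
    f <- glrlm_features(make_disc(lev, ng))
    rln_bf <- bf_rln(cnt_bf)
    expect_equal(f[["run_length_nonuniformity"]], rln_bf[["rln"]],
                 tolerance = 1e-10)
    expect_equal(f[["run_length_nonuniformity_norm"]], rln_bf[["rlnn"]],
                 tolerance = 1e-10)
  }
})

test_that("degenerate run patterns behave as expected", {
  # strictly alternating grid: every run has length 1 -> run percentage 1
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  lev <- array(0L, c(4, 4, 4))
  # 8-level 3D pattern: level determined by parity per axis -> all neighbours
  # in all 13 directions differ
  lev[] <- 1L + (idx[, 1] %% 2L) + 2L * (idx[, 2] %% 2L) + 4L * (idx[, 3] %% 2L)
  f <- glrlm_features(make_disc(lev, 8))
  expect_equal(f[["run_percentage"]], 1)
  expect_equal(f[["short_run_emphasis"]], 1)

  # constant 1 x 1 x L line: 13 directions see the line; the axial one as a
  # single run, the others as length-1 runs
  line <- array(1L, c(8, 1, 1))
  m <- glrlm_matrix(make_disc(line, 1))
  expect_equal(m$r[1, 8], 1)  # one run of length 8 along the line axis
})

test_that("cluster shade flips sign when the histogram is mirrored", {
  set.seed(13)
  for (rep_i in 1:5) {
    ng <- 6
    lev <- array(sample.int(ng, 216, TRUE, prob = (1:ng)^2), c(6, 6, 6))
    cs <- glcm_features(make_disc(lev, ng))[["cluster_shade"]]
    mirrored <- array(ng + 1L - lev, dim(lev))
    cs_m <- glcm_features(make_disc(mirrored, ng))[["cluster_shade"]]
    expect_equal(cs_m, -cs, tolerance = 1e-10)
  }
})

test_that("intensity features are invariant to whole-voxel translation", {
  set.seed(14)
  base <- array(rnorm(6^3), c(6, 6, 6))
  big <- array(0, c(10, 10, 10)); big[1:6, 1:6, 1:6] <- base
  big2 <- array(0, c(10, 10, 10)); big2[3:8, 4:9, 2:7] <- base
  mk1 <- array(FALSE, c(10, 10, 10)); mk1[1:6, 1:6, 1:6] <- TRUE
  mk2 <- array(FALSE, c(10, 10, 10)); mk2[3:8, 4:9, 2:7] <- TRUE
  v1 <- volume_grid(big, c(1, 1, 1)); v2 <- volume_grid(big2, c(1, 1, 1))
  m1 <- roi_mask(mk1, c(1, 1, 1)); m2 <- roi_mask(mk2, c(1, 1, 1))
  expect_equal(firstorder_features(v1, m1), firstorder_features(v2, m2))
  d1 <- discretize(v1, m1, 16); d2 <- discretize(v2, m2, 16)
  expect_equal(glcm_features(d1), glcm_features(d2))
  expect_equal(glrlm_features(d1), glrlm_features(d2))
})

test_that("the default catalog has exactly 954 uniquely named columns", {
  cat_ <- feature_catalog()
  expect_equal(nrow(cat_), 954)
  expect_equal(nrow(cat_), 21 * 2 + 57 * 2 * 2 * 4)
  expect_false(anyDuplicated(cat_$name) > 0)
  expect_equal(sum(cat_$family == "shape"), 42)
  expect_equal(sum(cat_$family == "firstorder"), 18 * 16)
  expect_equal(sum(cat_$family == "glcm"), 25 * 16)
  expect_equal(sum(cat_$family == "glrlm"), 14 * 16)
  # every feature named in the reference signature is present
  expect_true(all(c("bed_log_breast_glcm_cluster_shade",
                    "bed_log_breast_glrlm_run_length_nonuniformity",
                    "red_none_ptv_firstorder_kurtosis",
                    "red_gaussian_ptv_firstorder_range",
                    "red_gaussian_ptv_glcm_cluster_shade",
                    "bed_gaussian_ptv_firstorder_p10",
                    "bed_log_ptv_firstorder_variance",
                    "bed_log_ptv_glcm_inverse_variance") %in% cat_$name))
})

test_that("extraction is deterministic and swapping masks swaps ROI blocks", {
  cfg <- cohort_config(grid_shape = c(32L, 32L, 24L), seed = 3)
  p <- generate_phantom(cfg, 1)
  red <- hu_to_red(resample(p$ct, c(3, 3, 3)))
  bed <- dose_to_bed(resample(p$dose, c(3, 3, 3)), p$scheme)
  breast <- resample(p$breast_mask, c(3, 3, 3))
  ptv <- resample(p$ptv_mask, c(3, 3, 3))
  cat_small <- feature_catalog(filters = c("none", "gaussian"))
  r1 <- extract_all(red, bed, breast, ptv, cat_small)
  r2 <- extract_all(red, bed, breast, ptv, cat_small)
  expect_identical(r1, r2)
  r_swap <- extract_all(red, bed, ptv, breast, cat_small)
  nm_b <- grep("_breast_", names(r1), value = TRUE)
  nm_p <- sub("_breast_", "_ptv_", nm_b)
  expect_equal(unname(r_swap[nm_p]), unname(r1[nm_b]))
})

test_that("a missing ROI is reported by name", {
  cfg <- cohort_config(grid_shape = c(32L, 32L, 24L), seed = 3)
  p <- generate_phantom(cfg, 0)
  red <- hu_to_red(resample(p$ct, c(3, 3, 3)))
  expect_error(extract_all(red, red, NULL, NULL), "breast")
})
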