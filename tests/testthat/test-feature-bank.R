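test_that("fixed-bin-width discretization follows the floor rule", {
  d <- discretize(c(0, 0.0005, 0.0012), 0.001)
  expect_equal(d$levels, c(1L, 1L, 2L))
  expect_equal(d$n_gray_levels, 2L)

  dc <- discretize(rep(4.2, 10), 0.5)
  expect_true(all(dc$levels == 1L))
  expect_equal(dc$n_gray_levels, 1L)

  # a range spanning exactly 43 widths yields 43 bins (max clamped)
  w <- 0.001
  vals <- c(seq(0, 42, by = 1) * w + w / 3, 43 * w)
  d43 <- discretize(vals, w)
  expect_equal(d43$n_gray_levels, 43L)
  expect_equal(max(d43$levels), 43L)
  expect_error(discretize(numeric(0), 1), "empty")
})

test_that("first-order features match hand values and known limits", {
  f <- first_order_features(c(1, 2, 3, 4), width = 1)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Median"]), 2.5)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Energy"]), 30)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(30 / 4))

  fc <- first_order_features(rep(2.2, 50), width = 0.1)
  expect_equal(unname(fc["Variance"]), 0)
  expect_equal(unname(fc["Entropy"]), 0)
  expect_equal(unname(fc["Uniformity"]), 1)
  expect_equal(unname(fc["Kurtosis"]), 3)

  set.seed(99)
  fn <- first_order_features(rnorm(1e5), width = 0.1)
  expect_lt(abs(fn["Kurtosis"] - 3), 0.1)
  expect_lt(abs(fn["Skewness"]), 0.05)
})

test_that("kurtosis respects the Pearson lower bound on random ROIs", {
  set.seed(5)
  for (i in 1:25) {
    vals <- switch(1 + i %% 3,
                   runif(20 + i), rexp(30), sample(c(0, 1), 25, TRUE))
    if (sd(vals) == 0) next
    expect_gte(first_order_features(vals, 0.1)["Kurtosis"], 1)
  }
})

test_that("adding a constant shifts location features and leaves dispersion, histogram and texture untouched", {
  set.seed(17)
  vals <- rnorm(200, 10, 2)
  a <- first_order_features(vals, width = 0.5)
  b <- first_order_features(vals + 3.7, width = 0.5)
  for (nm in c("Mean", "Median", "Minimum", "Maximum", "10Percentile",
               "90Percentile"))
    expect_equal(unname(b[nm] - a[nm]), 3.7, tolerance = 1e-9)
  for (nm in c("Variance", "Entropy", "Uniformity", "Range",
               "InterquartileRange", "MeanAbsoluteDeviation"))
    expect_equal(unname(b[nm]), unname(a[nm]), tolerance = 1e-9)
  # bin anchoring at the ROI minimum keeps the texture matrices identical
  grid <- array(0, c(5, 5, 5))
  mask <- array(runif(125) < 0.6, c(5, 5, 5))
  grid[mask] <- vals[1:sum(mask)]
  lev1 <- array(0L, dim(grid))
  lev2 <- array(0L, dim(grid))
  lev1[mask] <- discretize(grid[mask], 0.5)$levels
  lev2[mask] <- discretize(grid[mask] + 3.7, 0.5)$levels
  expect_identical(lev1, lev2)
})

test_that("shape elongation reflects principal-axis ratios", {
  cube <- as.matrix(expand.grid(1:5, 1:5, 1:5))
  expect_equal(shape_elongation(cube), 1)
  line <- cbind(1:10, 0, 0)
  expect_equal(shape_elongation(line), 0)
  expect_true(is.na(shape_elongation(cbind(1, 1, 1))))
  # ellipsoid with semi-axes 20:10:10 mm on a 2 mm grid
  g <- expand.grid(x = seq(-20, 20, 2), y = seq(-10, 10, 2),
                   z = seq(-10, 10, 2))
  keep <- (g$x / 20)^2 + (g$y / 10)^2 + (g$z / 10)^2 <= 1
  expect_lt(abs(shape_elongation(as.matrix(g[keep, ])) - 0.5), 0.05)
})

test_that("gray-level matrices match hand enumerations", {
  # 1-D row [1, 1, 2]: runs {level1,len2} and {level2,len1} along x, plus
  # singleton runs along all other 12 directions
  row <- array(c(1L, 1L, 2L), c(3, 1, 1))
  g <- build_gray_level_matrix(row, "GLRLM", 2)
  expect_equal(g$matrix[1, 2], 1L)       # level 1, length 2 (x direction)
  expect_equal(g$matrix[2, 1], 12L + 1L) # level 2 singletons: 12 dirs + x

  const <- array(1L, c(2, 2, 2))
  gz <- build_gray_level_matrix(const, "GLSZM", 1)
  expect_equal(sum(gz$matrix), 1L)
  expect_equal(gz$matrix[1, 8], 1L)

  gd <- build_gray_level_matrix(const, "GLDM", 1)
  expect_equal(unname(gd$matrix[1, 8]), 8L)  # each voxel has 7 equal neighbours

  expect_error(build_gray_level_matrix(array(0L, c(2, 2, 2)), "GLSZM", 1),
               "empty mask")
})

test_that("matrix builders and scalar features match brute-force oracles on random volumes", {
  set.seed(123)
  for (rep in 1:50) {
    ng <- sample(2:5, 1)
    lv <- array(sample(0:ng, 6 * 6 * 6, TRUE, prob = c(0.35, rep(0.65 / ng, ng))),
                c(6, 6, 6))
    if (!any(lv > 0)) lv[1] <- 1L
    nvox <- sum(lv > 0)
    for (kind in c("GLRLM", "GLSZM", "GLDM")) {
      g <- build_gray_level_matrix(lv, kind, ng)
      orc <- switch(kind, GLRLM = oracle_glrlm(lv, ng),
                    GLSZM = oracle_glszm(lv, ng), GLDM = oracle_gldm(lv, ng))
      got <- g$matrix[, seq_len(ncol(orc)), drop = FALSE]
      if (ncol(g$matrix) > ncol(orc))
        expect_true(all(g$matrix[, -seq_len(ncol(orc))] == 0))
      expect_equal(unname(got), unname(orc))
      sc <- texture_features(g)
      ref <- oracle_texture_scalars(g$matrix, nvox, kind)
      keys <- oracle_keys(kind)
      expect_equal(unname(sc[names(keys)]), unname(ref[keys]),
                   tolerance = 1e-10)
    }
    # structural invariants
    grl <- build_gray_level_matrix(lv, "GLRLM", ng)$matrix
    expect_equal(sum(grl * col(grl)), 13 * nvox)
    gsz <- build_gray_level_matrix(lv, "GLSZM", ng)$matrix
    expect_equal(sum(gsz * col(gsz)), nvox)
    expect_equal(sum(build_gray_level_matrix(lv, "GLDM", ng)$matrix), nvox)
  }
})

test_that("texture features are invariant to global mask translation", {
  set.seed(4)
  lv <- array(0L, c(8, 8, 8))
  lv[2:5, 2:5, 2:5] <- sample(1:3, 64, TRUE)
  sh <- array(0L, c(8, 8, 8))
  sh[4:7, 4:7, 4:7] <- lv[2:5, 2:5, 2:5]
  for (kind in c("GLRLM", "GLSZM", "GLDM"))
    expect_equal(texture_features(build_gray_level_matrix(lv, kind, 3)),
                 texture_features(build_gray_level_matrix(sh, kind, 3)))
})

test_that("degenerate texture limits behave as expected", {
  # constant ROI: one gray level, GLN equals the number of runs
  const <- array(1L, c(3, 3, 3))
  g <- build_gray_level_matrix(const, "GLRLM", 1)
  tf <- texture_features(g)
  expect_equal(unname(tf["GrayLevelNonUniformity"]), sum(g$matrix))
  expect_gt(unname(tf["LongRunEmphasis"]),
            3 * unname(tf["ShortRunEmphasis"]))
  # isolated single-voxel zones only: SmallAreaEmphasis = 1
  iso <- array(0L, c(5, 5, 5))
  iso[c(1, 13, 25, 61, 125)] <- 1L
  tz <- texture_features(build_gray_level_matrix(iso, "GLSZM", 1))
  expect_equal(unname(tz["SmallAreaEmphasis"]), 1)
  expect_error(texture_features(structure(list(kind = "GLDM",
                                               matrix = matrix(0, 2, 2),
                                               n_gray_levels = 2,
                                               n_voxels = 0),
                                          class = "gray_level_matrix")),
               "all-zero")
})

test_that("total metabolic volume counts in-mask voxels with measurable kPL", {
  d <- c(6L, 6L, 6L)
  aff <- diag(c(5, 5, 5, 1))
  kpl <- array(0, d)
  mask <- array(0L, d)
  mask[1:2, 1:2, 1:2] <- 1L
  kpl[1:2, 1:2, 1:2] <- 17
  ms <- parametric_map_set(kpl, kpl, kpl, mask, aff, c(5, 5, 5))
  expect_equal(total_metabolic_volume(ms), 1.0)  # 8 voxels x 0.125 mL
  ms0 <- parametric_map_set(kpl, kpl, kpl, array(0L, d), aff, c(5, 5, 5))
  expect_equal(total_metabolic_volume(ms0), 0)
  # ~4 mL ellipsoid with uniform positive kPL, volume kept within a voxel layer
  g <- expand.grid(x = 1:20, y = 1:20, z = 1:20)
  r <- c(12.4, 9.9, 7.9)   # semi-axes in mm -> ~4.06 mL ellipsoid
  ctr <- c(50, 50, 50)
  aff2 <- diag(c(5, 5, 5, 1))
  inside <- ((g$x - 0.5) * 5 - ctr[1])^2 / r[1]^2 +
    ((g$y - 0.5) * 5 - ctr[2])^2 / r[2]^2 +
    ((g$z - 0.5) * 5 - ctr[3])^2 / r[3]^2 <= 1
  m2 <- array(0L, c(20, 20, 20))
  m2[as.matrix(g[inside, ])] <- 1L
  k2 <- array(0, c(20, 20, 20))
  k2[m2 > 0] <- 17
  ms2 <- parametric_map_set(k2, k2, k2, m2, aff2, c(5, 5, 5))
  vol_true <- 4 / 3 * pi * prod(r) / 1000
  expect_lt(abs(total_metabolic_volume(ms2) - vol_true), 1.5)
})

test_that("patient-level extraction pools lesions and yields a stable schema", {
  d <- c(10L, 6L, 6L)
  aff <- diag(c(5, 5, 5, 1))
  mask <- array(0L, d)
  mask[1:4, 1:4, 1:4] <- 1L
  mask[7:10, 1:4, 1:4] <- 2L
  kpl <- array(0, d)
  kpl[mask == 1L] <- 10
  kpl[mask == 2L] <- 30
  auc <- array(0, d)
  auc[mask > 0] <- 1 + seq_len(sum(mask > 0)) * 0.01
  mt <- array(0, d)
  mt[mask > 0] <- 15
  ms <- parametric_map_set(kpl, auc, mt, mask, aff, c(5, 5, 5))
  fv <- extract_patient_features(ms)
  expect_equal(unname(fv["kPL_original_firstorder_Median"]), 20)

  # uniform single lesion at 17 ks^-1
  mask1 <- array(0L, d)
  mask1[2:5, 2:5, 2:5] <- 1L
  kpl1 <- array(0, d)
  kpl1[mask1 > 0] <- 17
  ms1 <- parametric_map_set(kpl1, kpl1 / 10, kpl1 / 2, mask1, aff, c(5, 5, 5))
  fv1 <- extract_patient_features(ms1)
  expect_equal(unname(fv1["kPL_original_firstorder_Median"]), 17)

  # schema contract across a generated cohort
  co <- generate_cohort(cohort_spec(n_patients = 3, seed = 21),
                        acquisition_config(matrix_size = c(10, 10, 8)))
  fm <- extract_cohort_features(co)
  expect_equal(nrow(fm), 3)
  expect_equal(ncol(fm), 197L)  # patient_id + 3 maps x 65 + TMV
  expect_false(anyNA(fm[, setdiff(names(fm), grep("shape", names(fm),
                                                  value = TRUE))]))
  expect_error(extract_patient_features(
    parametric_map_set(kpl1, kpl1, kpl1, array(0L, d), aff, c(5, 5, 5))),
    "no lesion")
})
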