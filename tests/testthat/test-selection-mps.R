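# A small clinical table with exponential PH outcomes driven by `driver`.
driven_records <- function(n, driver, rate0 = 0.08, seed = 1) {
  set.seed(seed)
  z <- (driver - mean(driver)) / sd(driver)
  t_pfs <- rexp(n, rate0 * exp(z))
  t_os <- t_pfs + rexp(n, rate0)
  make_records(round(t_pfs, 3), rep(1L, n), round(t_os, 3), rep(1L, n))
}

test_that("adjusted C-index is the stated endpoint weighting", {
  expect_equal(hpmfm:::combine_c_indices(0.813, 0.879), 0.8262)
  expect_equal(hpmfm:::combine_c_indices(0.5, 0.5), 0.5)
  cfg_pfs <- selection_config(w_pfs = 1, w_os = 0)
  set.seed(3)
  x <- rnorm(30)
  rec <- driven_records(30, x)
  c_pfs <- suppressWarnings(
    cox_fit(cbind(x = x), rec$pfs_months, rec$pfs_event)$c_index)
  expect_equal(adjusted_c_index(x, rec, cfg_pfs), c_pfs)
  expect_true(is.na(adjusted_c_index(rep(1, 30), rec)))
})

test_that("ranking retains the ceil-fraction top features with a strong driver first", {
  set.seed(21)
  n <- 60
  driver <- rnorm(n)
  rec <- driven_records(n, driver, seed = 4)
  fm <- data.frame(patient_id = rec$patient_id, drv = driver)
  for (i in 1:9) fm[[paste0("noise", i)]] <- rnorm(n)
  out <- rank_and_retain(fm, rec, selection_config(retain_fraction = 0.2))
  # 10 imaging + 3 serology = 13 candidates -> ceil(2.6) = 3 retained
  expect_equal(length(out$retained), 3)
  expect_equal(out$retained[1], "drv")
  # 10 candidates at 20% -> exactly 2
  out2 <- rank_and_retain(fm[, 1:8], rec,
                          selection_config(retain_fraction = 0.2,
                                           serology_features = character(0)))
  expect_equal(length(out2$retained), 2)
  expect_error(rank_and_retain(fm[, 1:3], rec,
                               selection_config(serology_features =
                                                  character(0))),
               "at least 5")
})

test_that("correlation-distance clustering recovers block structure and top scorers", {
  set.seed(31)
  n <- 40
  bases <- matrix(rnorm(n * 4), n, 4)
  cols <- list()
  for (b in 1:4) for (m in 1:4)
    cols[[paste0("blk", b, "_f", m)]] <- bases[, b] + rnorm(n, sd = 0.05)
  X <- do.call(cbind, cols)
  # verify the fixture: tight within blocks, loose across
  cm <- abs(cor(X))
  within <- outer(rep(1:4, each = 4), rep(1:4, each = 4), "==")
  expect_true(all(cm[within] >= 0.95))
  expect_true(all(cm[!within] <= 0.6))
  scores <- setNames(runif(16, 0.6, 0.9), colnames(X))
  sel <- cluster_and_select(X, scores, selection_config(n_clusters = 4))
  blocks <- sub("_f.*", "", colnames(X))
  expect_equal(length(unique(paste(blocks, sel$clusters))), 4)
  for (b in unique(blocks)) {
    members <- colnames(X)[blocks == b]
    expect_true(members[which.max(scores[members])] %in%
                  sel$representatives)
  }
  # the emitted correlogram reflects the absolute-correlation distance
  expect_equal(dim(sel$correlation), c(16, 16))
  expect_error(cluster_and_select(X[, 1:3], scores[1:3],
                                  selection_config(n_clusters = 4)),
               "fewer retained")
})

test_that("representative selection is invariant to feature column order", {
  set.seed(32)
  n <- 40
  bases <- matrix(rnorm(n * 4), n, 4)
  X <- do.call(cbind, lapply(1:16, function(i)
    bases[, (i - 1) %/% 4 + 1] + rnorm(n, sd = 0.05)))
  colnames(X) <- paste0("f", sprintf("%02d", 1:16))
  scores <- setNames(runif(16, 0.6, 0.9), colnames(X))
  s1 <- cluster_and_select(X, scores, selection_config(n_clusters = 4))
  perm <- sample(16)
  s2 <- cluster_and_select(X[, perm], scores[perm],
                           selection_config(n_clusters = 4))
  expect_identical(s1$representatives, s2$representatives)
})

test_that("the MPS linear score reproduces hand arithmetic", {
  expect_equal(mps_score(c(a = 1.2, b = -0.4), c(a = 0, b = 0)), 0)
  coefs <- c(kPL_median = 0.269, pyrAUC_original_shape_Elongation = -3.069,
             kPL_original_firstorder_90Percentile = 0.165, PSA = 0.0063,
             Age = -0.0874)
  vals <- c(kPL_median = 17, pyrAUC_original_shape_Elongation = 0.8,
            kPL_original_firstorder_90Percentile = 30, PSA = 13.9,
            Age = 69)
  expect_equal(mps_score(coefs, vals), 1.1248, tolerance = 1e-4 / 1.1248)
})

test_that("the fitted MPS model exposes scores, predictions and a median threshold", {
  set.seed(41)
  n <- 40
  driver <- rnorm(n)
  rec <- driven_records(n, driver, seed = 6)
  fm <- data.frame(patient_id = rec$patient_id, drv = driver)
  for (i in 1:12) fm[[paste0("noise", i)]] <- rnorm(n)
  mod <- suppressWarnings(fit_mps(fm, rec, loo = FALSE))
  expect_s3_class(mod, "mps_model")
  expect_equal(length(mod$selected_features),
               selection_config()$n_clusters)
  expect_equal(mod$threshold, median(mod$scores))
  expect_equal(predict(mod), mod$scores)
  nd <- data.frame(t(rep(1, length(coef(mod)))))
  names(nd) <- names(coef(mod))
  expect_equal(predict(mod, nd), sum(coef(mod)))
  expect_output(print(mod), "Metabolic Prognostic Score")
  # shifting one covariate leaves the patient ranking and grouping unchanged
  fm2 <- fm
  fm2$drv <- fm2$drv + 50
  mod2 <- suppressWarnings(fit_mps(fm2, rec, loo = FALSE))
  expect_identical(mod2$selected_features, mod$selected_features)
  expect_equal(order(mod2$scores), order(mod$scores))
  expect_identical(mod2$scores <= mod2$threshold,
                   mod$scores <= mod$threshold)
})

test_that("MPS fitting is deterministic on fixed inputs", {
  set.seed(51)
  n <- 30
  driver <- rnorm(n)
  rec <- driven_records(n, driver, seed = 8)
  fm <- data.frame(patient_id = rec$patient_id, drv = driver)
  for (i in 1:16) fm[[paste0("noise", i)]] <- rnorm(n)
  m1 <- suppressWarnings(fit_mps(fm, rec, loo = FALSE))
  m2 <- suppressWarnings(fit_mps(fm, rec, loo = FALSE))
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$threshold, m2$threshold)
})

test_that("leave-one-out stability reports one refit per patient and zero spread for clones", {
  # sixteen copies of one patient: every refit sees identical data
  base <- data.frame(patient_id = sprintf("P%03d", 1:16),
                     age = 70, psa = 10, ldh = 200, alp = 80,
                     pfs_months = 6, pfs_event = 1L,
                     os_months = 9, os_event = 1L)
  reps <- matrix(1, 16, 2, dimnames = list(NULL, c("f1", "f2")))
  out <- suppressWarnings(loo_stability(reps, base))
  expect_equal(out$n_refits, 16)
  expect_equal(unname(out$normalized_sd), rep(0, 3))  # f1, f2, Age
  # a real 16-patient cohort yields finite spreads
  set.seed(61)
  driver <- rnorm(16)
  rec <- driven_records(16, driver, seed = 9)
  reps2 <- cbind(drv = driver, other = rnorm(16))
  out2 <- suppressWarnings(loo_stability(reps2, rec))
  expect_equal(out2$n_refits, 16)
  expect_true(all(is.finite(out2$normalized_sd)))
  expect_true(all(out2$normalized_sd >= 0))
})

test_that("the correlogram has unit diagonal and exact extreme correlations", {
  rec <- make_records(c(2, 4, 6, 8, 10), rep(1L, 5))
  fm <- data.frame(patient_id = rec$patient_id,
                   same_as_os = rec$os_months,
                   anti_os = -rec$os_months)
  cg <- correlogram(fm, rec)
  expect_equal(unname(diag(cg)), rep(1, ncol(cg)))
  expect_equal(cg["same_as_os", "OS"], 1)
  expect_equal(cg["anti_os", "OS"], -1)
  set.seed(71)
  rec2 <- driven_records(200, rnorm(200), seed = 10)
  fm2 <- data.frame(patient_id = rec2$patient_id, indep = rnorm(200))
  expect_lt(abs(correlogram(fm2, rec2)["indep", "OS"]), 0.2)
})
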