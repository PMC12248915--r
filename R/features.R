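#' Fixed-bin-width discretization settings
#'
#' Bin widths for gray-scale discretization of the three source maps, in
#' each map's reported units (kPL in ks^-1, AUC in signal units, mean time
#' in s). Fixed bin width (rather than fixed bin count) is used throughout;
#' bins are anchored at the ROI minimum.
#'
#' @param kpl Bin width for the kPL map (ks^-1; 1 ks^-1 = 1e-3/s).
#' @param pyr_auc Bin width for the pyruvate AUC map (signal units).
#' @param mean_time Bin width for the mean pyruvate time map (s).
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(kpl = 1, pyr_auc = 0.02, mean_time = 0.1) {
  stopifnot(kpl > 0, pyr_auc > 0, mean_time > 0)
  structure(list(kpl = kpl, pyr_auc = pyr_auc, mean_time = mean_time),
            class = "discretization_config")
}

#' Discretize ROI intensities with a fixed bin width
#'
#' `level(x) = floor((x - min) / width) + 1`, with the maximum clamped into
#' the top bin so the level range is `1..n_gray_levels`.
#'
#' @param values Numeric vector of in-ROI intensities (non-empty).
#' @param width Positive bin width.
#' @return A list with integer `levels` and `n_gray_levels`.
#' @export
discretize <- function(values, width) {
  if (!length(values)) stop("empty ROI")
  stopifnot(width > 0, all(is.finite(values)))
  lo <- min(values)
  rng <- max(values) - lo
  ngray <- max(ceiling(rng / width - 1e-9), 1L)
  levels <- pmin(floor((values - lo) / width) + 1L, ngray)
  list(levels = as.integer(levels), n_gray_levels = as.integer(ngray))
}

#' First-order intensity features of an ROI
#'
#' The 18 standard first-order descriptors. Entropy and uniformity are
#' computed on the fixed-bin-width discretized histogram; kurtosis is
#' non-excess (a normal distribution scores 3); variance and the higher
#' moments use the population (1/N) convention. For a constant ROI the
#' degenerate-limit conventions skewness = 0 and kurtosis = 3 are used.
#'
#' @param values Numeric vector of in-ROI intensities (non-empty).
#' @param width Discretization bin width for entropy/uniformity.
#' @param voxel_volume_mm3 Voxel volume (mm^3) for TotalEnergy.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(values, width, voxel_volume_mm3 = 125) {
  if (!length(values)) stop("empty ROI")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 3
  disc <- discretize(values, width)
  p <- tabulate(disc$levels, nbins = disc$n_gray_levels) / n
  p <- p[p > 0]
  q <- stats::quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE,
                       type = 7)
  inner <- values[values >= q[1] & values <= q[4]]
  c(Mean = mu,
    Median = stats::median(values),
    Variance = m2,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(values^2),
    TotalEnergy = voxel_volume_mm3 * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    Minimum = min(values),
    Maximum = max(values),
    Range = max(values) - min(values),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    InterquartileRange = q[3] - q[2],
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(values^2)))
}

#' Shape elongation of an ROI
#'
#' Square-root ratio of the second-largest to largest eigenvalue of the
#' covariance of the voxel-centre world coordinates (principal component
#' axis lengths): 1 for an isotropic ROI, toward 0 as it elongates.
#'
#' @param coords_mm Matrix (n x 3) of voxel-centre coordinates in mm.
#' @return Elongation in `[0, 1]`, or `NA` for a degenerate (< 2 distinct
#'   points) ROI.
#' @export
shape_elongation <- function(coords_mm) {
  coords_mm <- as.matrix(coords_mm)
  if (nrow(unique(coords_mm)) < 2) return(NA_real_)
  ev <- sort(eigen(stats::cov(coords_mm), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, 0)
  if (ev[1] <= 0) return(NA_real_)
  sqrt(ev[2] / ev[1])
}

#' Build a gray-level texture matrix
#'
#' Constructs one of the three texture count matrices over a discretized
#' 3-D grid (positive levels inside the mask, 0 outside):
#' * `GLRLM` — maximal runs of equal level along the 13 unique 3-D
#'   directions, aggregated by summing the per-direction matrices;
#' * `GLSZM` — 26-connected zones of equal level, counted by zone size;
#' * `GLDM` — per voxel, the dependence count 1 + (number of 26-neighbours
#'   with the same level).
#'
#' @param levels_grid 3D integer array of gray levels (0 = outside mask).
#' @param kind One of "GLRLM", "GLSZM", "GLDM".
#' @param n_gray_levels Number of gray levels (rows of the matrix).
#' @return An object of class `gray_level_matrix` with fields `kind`,
#'   `matrix`, `n_gray_levels`, `n_voxels` and (GLRLM) `n_directions`.
#' @export
build_gray_level_matrix <- function(levels_grid, kind = c("GLRLM", "GLSZM",
                                                          "GLDM"),
                                    n_gray_levels = max(levels_grid)) {
  kind <- match.arg(kind)
  stopifnot(length(dim(levels_grid)) == 3L)
  lv <- as.integer(levels_grid)
  if (!any(lv > 0)) stop("empty mask")
  dims <- as.integer(dim(levels_grid))
  ng <- as.integer(n_gray_levels)
  m <- switch(kind,
              GLRLM = glrlm_cpp(lv, dims, ng),
              GLSZM = glszm_cpp(lv, dims, ng),
              GLDM = gldm_cpp(lv, dims, ng))
  structure(list(kind = kind, matrix = m, n_gray_levels = ng,
                 n_voxels = sum(lv > 0),
                 n_directions = if (kind == "GLRLM") 13L else NA_integer_),
            class = "gray_level_matrix")
}

#' Scalar texture features of a gray-level matrix
#'
#' Standard scalar summaries per matrix family: 16 for GLRLM, 16 for GLSZM
#' and 14 for GLDM, following the consensus radiomics definitions (run
#' percentage is normalised by voxels x directions under summed direction
#' aggregation).
#'
#' @param glm A [build_gray_level_matrix()] result.
#' @return Named numeric vector of scalar features.
#' @export
texture_features <- function(glm) {
  stopifnot(inherits(glm, "gray_level_matrix"))
  P <- glm$matrix
  if (sum(P) == 0) stop("all-zero matrix")
  i <- row(P)
  j <- col(P)
  Ns <- sum(P)           # runs / zones / voxels
  p <- P / Ns
  pg <- rowSums(P)       # per gray level
  ps <- colSums(P)       # per size index
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  base <- c(
    SE = sum(P / j^2) / Ns,            # short emphasis
    LE = sum(P * j^2) / Ns,            # long/large emphasis
    GLN = sum(pg^2) / Ns,
    GLNN = sum(pg^2) / Ns^2,
    SN = sum(ps^2) / Ns,               # size non-uniformity
    SNN = sum(ps^2) / Ns^2,
    GLV = sum(p * (i - mu_i)^2),
    SV = sum(p * (j - mu_j)^2),
    ENT = ent,
    LGLE = sum(P / i^2) / Ns,
    HGLE = sum(P * i^2) / Ns,
    SLGL = sum(P / (i^2 * j^2)) / Ns,
    SHGL = sum(P * i^2 / j^2) / Ns,
    LLGL = sum(P * j^2 / i^2) / Ns,
    LHGL = sum(P * i^2 * j^2) / Ns)
  if (glm$kind == "GLRLM") {
    stats::setNames(
      c(base[c("SE", "LE", "GLN", "GLNN", "SN", "SNN")],
        Ns / (glm$n_voxels * glm$n_directions),
        base[c("GLV", "SV", "ENT", "LGLE", "HGLE", "SLGL", "SHGL", "LLGL",
               "LHGL")]),
      c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
        "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
        "RunLengthNonUniformityNormalized", "RunPercentage",
        "GrayLevelVariance", "RunVariance", "RunEntropy",
        "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
        "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
        "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
  } else if (glm$kind == "GLSZM") {
    stats::setNames(
      c(base[c("SE", "LE", "GLN", "GLNN", "SN", "SNN")],
        Ns / glm$n_voxels,
        base[c("GLV", "SV", "ENT", "LGLE", "HGLE", "SLGL", "SHGL", "LLGL",
               "LHGL")]),
      c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
        "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
        "SizeZoneNonUniformityNormalized", "ZonePercentage",
        "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
        "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
        "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
        "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
  } else {
    stats::setNames(
      c(base[c("SE", "LE", "GLN", "SN", "SNN", "GLV", "SV", "ENT", "LGLE",
               "HGLE", "SLGL", "SHGL", "LLGL", "LHGL")]),
      c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
        "GrayLevelNonUniformity", "DependenceNonUniformity",
        "DependenceNonUniformityNormalized", "GrayLevelVariance",
        "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
        "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
        "SmallDependenceHighGrayLevelEmphasis",
        "LargeDependenceLowGrayLevelEmphasis",
        "LargeDependenceHighGrayLevelEmphasis"))
  }
}

#' Total metabolic volume
#'
#' Volume (mL) of in-mask voxels with measurable (positive) kPL.
#'
#' @param maps A [parametric_map_set()].
#' @return TMV in mL.
#' @export
total_metabolic_volume <- function(maps) {
  stopifnot(inherits(maps, "parametric_map_set"))
  sum(maps$mask > 0 & maps$kpl > 0) * prod(maps$voxel_mm) / 1000
}

# World coordinates (mm) of in-ROI voxel centres.
roi_coords_mm <- function(roi, affine) {
  idx <- which(roi, arr.ind = TRUE) - 1  # zero-based
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' Extract the full multiparametric feature vector for one patient
#'
#' Merges all lesion labels into one composite ROI (voxels with measurable
#' pyruvate signal), then per source map runs fixed-bin-width
#' discretization, first-order, shape and GLDM/GLRLM/GLSZM texture feature
#' computation, and attaches the total metabolic volume. Feature names
#' follow `<map>_original_<class>_<Feature>` with map prefixes `kPL`,
#' `pyrAUC` and `MT`, plus `TMV`.
#'
#' @param maps A resampled [parametric_map_set()].
#' @param disc A [discretization_config()].
#' @return Named numeric vector of features.
#' @export
extract_patient_features <- function(maps, disc = discretization_config()) {
  stopifnot(inherits(maps, "parametric_map_set"),
            inherits(disc, "discretization_config"))
  roi <- maps$mask > 0 & maps$pyr_auc > 0
  if (!any(roi)) stop("no lesion voxels with measurable signal in mask")
  coords <- roi_coords_mm(roi, maps$affine)
  elong <- shape_elongation(coords)
  vvol <- prod(maps$voxel_mm)
  dims <- dim(maps$kpl)
  out <- numeric(0)
  specs <- list(kPL = list(map = maps$kpl, width = disc$kpl),
                pyrAUC = list(map = maps$pyr_auc, width = disc$pyr_auc),
                MT = list(map = maps$mean_time, width = disc$mean_time))
  for (nm in names(specs)) {
    vals <- specs[[nm]]$map[roi]
    width <- specs[[nm]]$width
    fo <- first_order_features(vals, width, voxel_volume_mm3 = vvol)
    names(fo) <- paste0(nm, "_original_firstorder_", names(fo))
    d <- discretize(vals, width)
    grid <- array(0L, dims)
    grid[roi] <- d$levels
    tex <- numeric(0)
    for (kind in c("GLDM", "GLRLM", "GLSZM")) {
      glm <- build_gray_level_matrix(grid, kind, d$n_gray_levels)
      tf <- texture_features(glm)
      names(tf) <- paste0(nm, "_original_", tolower(kind), "_", names(tf))
      tex <- c(tex, tf)
    }
    sh <- stats::setNames(elong, paste0(nm, "_original_shape_Elongation"))
    out <- c(out, fo, sh, tex)
  }
  c(out, TMV = total_metabolic_volume(maps))
}

#' Extract the cohort feature matrix
#'
#' Runs map computation, resampling and feature extraction for every
#' patient of a synthetic cohort and returns the feature matrix.
#'
#' @param cohort An `hp_cohort` from [generate_cohort()].
#' @param model A [kinetic_model_config()].
#' @param disc A [discretization_config()].
#' @param target_mm Isotropic analysis voxel size (mm).
#' @return A data frame: first column `patient_id`, then one column per
#'   feature; patients whose mask holds no usable voxels are dropped with a
#'   warning.
#' @export
extract_cohort_features <- function(cohort, model = kinetic_model_config(),
                                    disc = discretization_config(),
                                    target_mm = 5) {
  stopifnot(inherits(cohort, "hp_cohort"))
  rows <- list()
  dropped <- character(0)
  for (p in cohort$patients) {
    series <- dynamic_series(p$pyr, p$lac, cohort$acq, p$affine)
    maps <- compute_parametric_maps(series, p$mask, model)
    rmaps <- resample_maps(maps, target_mm)
    fv <- tryCatch(extract_patient_features(rmaps, disc),
                   error = function(e) NULL)
    if (is.null(fv)) dropped <- c(dropped, p$id) else rows[[p$id]] <- fv
  }
  if (length(dropped))
    warning("patients without usable lesion voxels dropped: ",
            paste(dropped, collapse = ", "))
  if (!length(rows)) stop("no patients with usable lesions")
  mat <- do.call(rbind, rows)
  data.frame(patient_id = names(rows), mat, row.names = NULL,
             check.names = FALSE)
}
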