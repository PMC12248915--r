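#' Dynamic series container
#'
#' Pairs the 4D pyruvate and lactate signal arrays with their acquisition
#' settings and a voxel-to-world affine (mm, NIfTI convention: world =
#' affine %*% c(i, j, k, 1) with zero-based voxel indices).
#'
#' @param pyr,lac 4D arrays (x, y, z, frame) with matching dimensions.
#' @param acq An [acquisition_config()]; the frame count must match.
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(pyr, lac, acq, affine) {
  stopifnot(length(dim(pyr)) == 4L, identical(dim(pyr), dim(lac)),
            inherits(acq, "acquisition_config"),
            dim(pyr)[4] == acq$n_frames,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(pyr = pyr, lac = lac, acq = acq, affine = affine),
            class = "dynamic_series")
}

#' Kinetic model settings for the inputless kPL fit
#'
#' @param t1l_seconds Fixed effective lactate T1 (s, default 25; not
#'   fitted).
#' @param kpl_bounds_per_second Fit bounds `c(0, upper)` in 1/s.
#' @param solver_tolerance Convergence tolerance of the optional iterative
#'   minimiser (the default closed-form path is exact).
#' @param noise_floor_factor Multiplier on the robust background noise
#'   estimate below which voxels are zero-filled.
#' @return An object of class `kinetic_model_config`.
#' @export
kinetic_model_config <- function(t1l_seconds = 25,
                                 kpl_bounds_per_second = c(0, 0.2),
                                 solver_tolerance = 1e-10,
                                 noise_floor_factor = 3) {
  stopifnot(t1l_seconds > 0, length(kpl_bounds_per_second) == 2L,
            kpl_bounds_per_second[1] >= 0,
            kpl_bounds_per_second[2] > kpl_bounds_per_second[1],
            solver_tolerance > 0, noise_floor_factor >= 0)
  structure(list(t1l_seconds = t1l_seconds,
                 kpl_bounds_per_second = kpl_bounds_per_second,
                 solver_tolerance = solver_tolerance,
                 noise_floor_factor = noise_floor_factor),
            class = "kinetic_model_config")
}

# Robust background noise scale: MAD of the first pyruvate frame (pre-bolus,
# so it carries noise only) over the whole volume. Centering on the median
# makes the estimate zero for noise-free data.
estimate_noise_floor <- function(series, model) {
  first <- series$pyr[, , , 1, drop = FALSE]
  model$noise_floor_factor * stats::mad(as.numeric(first))
}

#' Fit the inputless two-site exchange model voxelwise
#'
#' Converts signals to magnetizations (divide by `sin(theta)`), seeds the
#' predicted lactate from the first measured lactate frame, and propagates
#' `L[i+1] = L[i] * cos(theta_L) * exp(-TR/T1L) + kpl * TR *
#' (P[i]*cos(theta_P) + P[i+1]) / 2` with the measured pyruvate as the
#' source term. The predicted lactate trajectory is linear in `kpl`, so the
#' bounded least-squares minimiser over `kpl >= 0` is computed in closed
#' form per voxel. Voxels whose pyruvate peak falls below the noise floor,
#' or containing non-finite values, return 0.
#'
#' @param series A [dynamic_series()].
#' @param model A [kinetic_model_config()].
#' @return 3D kPL volume in ks^-1 (1e-3/s), with attribute
#'   `n_nonfinite` counting flagged voxels.
#' @export
fit_kpl_inputless <- function(series, model = kinetic_model_config()) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(model, "kinetic_model_config"))
  acq <- series$acq
  dims <- dim(series$pyr)[1:3]
  n <- acq$n_frames
  nv <- prod(dims)
  Sp <- matrix(series$pyr, nv, n)
  Sl <- matrix(series$lac, nv, n)
  bad <- !is.finite(rowSums(Sp) + rowSums(Sl))
  if (any(bad)) {
    Sp[bad, ] <- 0
    Sl[bad, ] <- 0
  }
  kpl <- fit_kpl_matrix(Sp, Sl, acq, model)
  floor_val <- estimate_noise_floor(series, model)
  peak <- apply(Sp, 1, max)
  kpl[peak <= floor_val | peak <= 0] <- 0
  out <- array(kpl * 1000, dims)  # report in ks^-1
  attr(out, "n_nonfinite") <- sum(bad)
  out
}

# Closed-form per-row bounded least squares for the inputless model.
# Sp, Sl: n_voxel x n_frames signal matrices.
fit_kpl_matrix <- function(Sp, Sl, acq, model) {
  n <- ncol(Sp)
  tr <- acq$tr_seconds
  cp <- cos(acq$flip_pyr_degrees * pi / 180)
  cl <- cos(acq$flip_lac_degrees * pi / 180)
  sp <- sin(acq$flip_pyr_degrees * pi / 180)
  sl <- sin(acq$flip_lac_degrees * pi / 180)
  el <- cl * exp(-tr / model$t1l_seconds)
  P <- Sp / sp      # measured pyruvate magnetization
  Lm <- Sl / sl     # measured lactate magnetization
  nv <- nrow(Sp)
  # predicted lactate magnetization L = a + kpl * b, per voxel
  a <- matrix(0, nv, n)
  b <- matrix(0, nv, n)
  a[, 1] <- Lm[, 1]
  for (i in seq_len(n - 1)) {
    a[, i + 1] <- a[, i] * el
    b[, i + 1] <- b[, i] * el + tr * (P[, i] * cp + P[, i + 1]) / 2
  }
  num <- rowSums(b * (Lm - a))
  den <- rowSums(b * b)
  kpl <- ifelse(den > 0, num / den, 0)
  pmin(pmax(kpl, model$kpl_bounds_per_second[1]),
       model$kpl_bounds_per_second[2])
}

# Iterative bounded 1-D reference minimiser (single voxel); used as an
# internal cross-check of the closed-form path.
fit_kpl_optimize <- function(pyr_signal, lac_signal, acq,
                             model = kinetic_model_config()) {
  obj <- function(k) {
    pred <- predict_lactate(pyr_signal, lac_signal[1], k, acq, model)
    sum((pred - lac_signal)^2)
  }
  stats::optimize(obj, interval = model$kpl_bounds_per_second,
                  tol = model$solver_tolerance)$minimum
}

# Forward-propagated lactate signal given measured pyruvate signal.
predict_lactate <- function(pyr_signal, lac_signal0, kpl, acq, model) {
  n <- length(pyr_signal)
  tr <- acq$tr_seconds
  cp <- cos(acq$flip_pyr_degrees * pi / 180)
  cl <- cos(acq$flip_lac_degrees * pi / 180)
  sp <- sin(acq$flip_pyr_degrees * pi / 180)
  sl <- sin(acq$flip_lac_degrees * pi / 180)
  el <- cl * exp(-tr / model$t1l_seconds)
  P <- pyr_signal / sp
  L <- numeric(n)
  L[1] <- lac_signal0 / sl
  for (i in seq_len(n - 1))
    L[i + 1] <- L[i] * el + kpl * tr * (P[i] * cp + P[i + 1]) / 2
  L * sl
}

#' Pyruvate area under the curve map
#'
#' Per voxel, the plain frame sum of the pyruvate signal (no TR weighting).
#'
#' @param series A [dynamic_series()].
#' @return 3D volume of summed pyruvate signal.
#' @export
compute_pyr_auc <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  rowSums(series$pyr, dims = 3)
}

#' Mean pyruvate time map
#'
#' Center of mass of each voxel's pyruvate signal-time curve:
#' `MT = sum(t_i * S(i)) / sum(S(i))` with `t_i = i * TR`. Voxels whose
#' summed signal does not exceed the noise floor return 0.
#'
#' @param series A [dynamic_series()].
#' @param model A [kinetic_model_config()] (noise floor rule).
#' @return 3D volume of mean pyruvate time (s).
#' @export
compute_mean_time <- function(series, model = kinetic_model_config()) {
  stopifnot(inherits(series, "dynamic_series"))
  acq <- series$acq
  t <- (seq_len(acq$n_frames) - 1) * acq$tr_seconds
  dims <- dim(series$pyr)[1:3]
  Sp <- matrix(series$pyr, prod(dims), acq$n_frames)
  tot <- rowSums(Sp)
  wsum <- as.numeric(Sp %*% t)
  floor_val <- estimate_noise_floor(series, model) * sqrt(acq$n_frames)
  mt <- ifelse(tot > pmax(floor_val, 0), wsum / tot, 0)
  mt <- pmin(pmax(mt, 0), (acq$n_frames - 1) * acq$tr_seconds)
  array(mt, dims)
}

#' Parametric map set
#'
#' Bundles the three co-registered source maps with the lesion label mask.
#'
#' @param kpl_map 3D kPL map (ks^-1, non-negative).
#' @param pyr_auc_map 3D pyruvate AUC map (signal units).
#' @param mean_time_map 3D mean pyruvate time map (s).
#' @param mask 3D integer label mask (0 = background).
#' @param affine 4x4 voxel-to-world transform.
#' @param voxel_mm Voxel dimensions (mm).
#' @return An object of class `parametric_map_set`.
#' @export
parametric_map_set <- function(kpl_map, pyr_auc_map, mean_time_map, mask,
                               affine, voxel_mm) {
  stopifnot(identical(dim(kpl_map), dim(pyr_auc_map)),
            identical(dim(kpl_map), dim(mean_time_map)),
            identical(dim(kpl_map), dim(mask)),
            all(kpl_map >= 0), all(dim(affine) == c(4L, 4L)),
            length(voxel_mm) == 3L, all(voxel_mm > 0))
  structure(list(kpl = kpl_map, pyr_auc = pyr_auc_map,
                 mean_time = mean_time_map,
                 mask = array(as.integer(mask), dim(mask)),
                 affine = affine, voxel_mm = as.numeric(voxel_mm)),
            class = "parametric_map_set")
}

#' Compute the three source parametric maps from a dynamic series
#'
#' @param series A [dynamic_series()].
#' @param mask 3D integer lesion label mask on the native grid.
#' @param model A [kinetic_model_config()].
#' @return A [parametric_map_set()] on the native grid.
#' @export
compute_parametric_maps <- function(series, mask,
                                    model = kinetic_model_config()) {
  kpl <- fit_kpl_inputless(series, model)
  attr(kpl, "n_nonfinite") <- NULL
  parametric_map_set(kpl, compute_pyr_auc(series),
                     compute_mean_time(series, model), mask,
                     series$affine, voxel_size_from_affine(series$affine))
}

voxel_size_from_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Trilinear sampling of 3D array `vol` at continuous zero-based voxel
# coordinates (x, y, z); outside the grid returns `fill`.
trilinear_sample <- function(vol, x, y, z, fill = 0) {
  d <- dim(vol)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  inside <- x >= -0.5 & x <= d[1] - 0.5 & y >= -0.5 & y <= d[2] - 0.5 &
    z >= -0.5 & z <= d[3] - 0.5
  cl <- function(v, dmax) pmin(pmax(v, 0), dmax - 1)
  gat <- function(xi, yi, zi)
    vol[1 + cl(xi, d[1]) + d[1] * (cl(yi, d[2]) + d[2] * cl(zi, d[3]))]
  out <- (1 - fx) * (1 - fy) * (1 - fz) * gat(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * gat(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * gat(x0, y0 + 1, z0) +
    fx * fy * (1 - fz) * gat(x0 + 1, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * gat(x0, y0, z0 + 1) +
    fx * (1 - fy) * fz * gat(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * gat(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * gat(x0 + 1, y0 + 1, z0 + 1)
  out[!inside] <- fill
  out
}

nearest_sample <- function(vol, x, y, z, fill = 0L) {
  d <- dim(vol)
  xi <- round(x); yi <- round(y); zi <- round(z)
  inside <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
  out <- rep(fill, length(x))
  out[inside] <- vol[1 + xi[inside] + d[1] * (yi[inside] + d[2] * zi[inside])]
  out
}

#' Resample a parametric map set to an isotropic analysis grid
#'
#' Intensity maps are resampled with trilinear interpolation and the label
#' mask with nearest-neighbour, onto an axis-aligned isotropic grid (default
#' 5 mm) covering the native field of view.
#'
#' @param maps A [parametric_map_set()] on the native grid.
#' @param target_mm Isotropic target voxel size (mm, default 5).
#' @return A resampled [parametric_map_set()].
#' @export
resample_maps <- function(maps, target_mm = 5) {
  stopifnot(inherits(maps, "parametric_map_set"), target_mm > 0)
  A <- maps$affine
  if (abs(det(A)) < 1e-12) stop("singular affine")
  d <- dim(maps$kpl)
  # bounding box of the native grid (voxel edges) in world space
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5), c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  world <- t(A %*% rbind(t(corners), 1))[, 1:3, drop = FALSE]
  lo <- apply(world, 2, min)
  hi <- apply(world, 2, max)
  nd <- pmax(ceiling((hi - lo) / target_mm), 1)
  Anew <- diag(c(rep(target_mm, 3), 1))
  Anew[1:3, 4] <- lo + target_mm / 2
  g <- expand.grid(i = seq_len(nd[1]) - 1, j = seq_len(nd[2]) - 1,
                   k = seq_len(nd[3]) - 1)
  w <- Anew %*% rbind(g$i, g$j, g$k, 1)
  src <- solve(A, w)          # continuous zero-based source voxel coords
  x <- src[1, ]; y <- src[2, ]; z <- src[3, ]
  resh <- function(v) array(v, nd)
  kpl <- pmax(resh(trilinear_sample(maps$kpl, x, y, z)), 0)
  auc <- resh(trilinear_sample(maps$pyr_auc, x, y, z))
  mt <- resh(trilinear_sample(maps$mean_time, x, y, z))
  msk <- resh(nearest_sample(maps$mask, x, y, z))
  parametric_map_set(kpl, auc, mt, msk, Anew, rep(target_mm, 3))
}

# ---- NIfTI I/O -------------------------------------------------------------

write_volume <- function(arr, affine, path) {
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, affine = unclass(aff)[1:4, 1:4])
}

#' Write a parametric map set as NIfTI volumes
#'
#' @param maps A [parametric_map_set()].
#' @param dir Output directory.
#' @param prefix Filename prefix (e.g. patient id).
#' @return `dir`, invisibly.
#' @export
write_map_set <- function(maps, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("kpl", "pyr_auc", "mean_time", "mask"))
    write_volume(maps[[nm]], maps$affine,
                 file.path(dir, paste0(prefix, "_", nm, ".nii.gz")))
  invisible(dir)
}

#' Read a parametric map set written by [write_map_set()]
#'
#' @param dir Directory holding the NIfTI volumes.
#' @param prefix Filename prefix used when writing.
#' @return A [parametric_map_set()].
#' @export
read_map_set <- function(dir, prefix) {
  vols <- lapply(c("kpl", "pyr_auc", "mean_time", "mask"), function(nm)
    read_volume(file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))))
  aff <- vols[[1]]$affine
  parametric_map_set(vols[[1]]$data, vols[[2]]$data, vols[[3]]$data,
                     round(vols[[4]]$data), aff, voxel_size_from_affine(aff))
}
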