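#' Acquisition settings for a dynamic hyperpolarized 13C series
#'
#' Describes the dynamic [1-13C]pyruvate acquisition: repetition time,
#' number of frames, metabolite-specific excitation flip angles, the native
#' voxel grid, and the magnitude-noise scale.
#'
#' @param tr_seconds Temporal resolution between frames (s).
#' @param n_frames Number of dynamic frames (>= 4).
#' @param flip_pyr_degrees Pyruvate excitation flip angle, in (0, 90].
#' @param flip_lac_degrees Lactate excitation flip angle, in (0, 90].
#' @param voxel_mm Native voxel dimensions (mm), length-3.
#' @param matrix_size Native matrix size (voxels), length-3.
#' @param noise_sigma Additive Gaussian magnitude-noise scale (signal units).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(tr_seconds = 3, n_frames = 20,
                               flip_pyr_degrees = 15, flip_lac_degrees = 30,
                               voxel_mm = c(20, 20, 20),
                               matrix_size = c(16L, 16L, 12L),
                               noise_sigma = 0.006) {
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  if (n_frames < 4) stop("n_frames must be >= 4")
  if (flip_pyr_degrees <= 0 || flip_pyr_degrees > 90)
    stop("flip_pyr_degrees must lie in (0, 90]")
  if (flip_lac_degrees <= 0 || flip_lac_degrees > 90)
    stop("flip_lac_degrees must lie in (0, 90]")
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0),
            length(matrix_size) == 3L, all(matrix_size >= 1),
            noise_sigma >= 0)
  structure(list(tr_seconds = tr_seconds, n_frames = as.integer(n_frames),
                 flip_pyr_degrees = flip_pyr_degrees,
                 flip_lac_degrees = flip_lac_degrees,
                 voxel_mm = as.numeric(voxel_mm),
                 matrix_size = as.integer(matrix_size),
                 noise_sigma = noise_sigma),
            class = "acquisition_config")
}

#' Kinetic parameters of the two-site pyruvate/lactate exchange simulator
#'
#' @param kpl_per_second True pyruvate-to-lactate conversion rate (1/s).
#' @param r1p_per_second Pyruvate longitudinal relaxation rate (1/s).
#' @param r1l_per_second Lactate longitudinal relaxation rate (1/s).
#' @param bolus_amplitude,bolus_alpha,bolus_beta Gamma-variate bolus input
#'   `u(t) = A * t^alpha * exp(-t/beta)` (arbitrary units; alpha unitless;
#'   beta in s).
#' @param bolus_delay Bolus arrival delay (s, >= 0).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(kpl_per_second = 0.017,
                           r1p_per_second = 1 / 25, r1l_per_second = 1 / 25,
                           bolus_amplitude = 0.002, bolus_alpha = 2.5,
                           bolus_beta = 4.5, bolus_delay = 0) {
  if (kpl_per_second < 0 || r1p_per_second < 0 || r1l_per_second < 0)
    stop("rates must be non-negative")
  if (bolus_amplitude <= 0 || bolus_alpha <= 0 || bolus_beta <= 0)
    stop("bolus parameters must be positive")
  stopifnot(bolus_delay >= 0)
  structure(list(kpl_per_second = kpl_per_second,
                 r1p_per_second = r1p_per_second,
                 r1l_per_second = r1l_per_second,
                 bolus_amplitude = bolus_amplitude,
                 bolus_alpha = bolus_alpha, bolus_beta = bolus_beta,
                 bolus_delay = bolus_delay),
            class = "kinetic_params")
}

# Integral of the gamma-variate bolus A*(t-t0)^alpha*exp(-(t-t0)/beta) over
# [t1, t2], via the regularised lower incomplete gamma function.
bolus_integral <- function(t1, t2, amplitude, alpha, beta, delay = 0) {
  s1 <- pmax(t1 - delay, 0)
  s2 <- pmax(t2 - delay, 0)
  amplitude * gamma(alpha + 1) * beta^(alpha + 1) *
    (stats::pgamma(s2, shape = alpha + 1, scale = beta) -
       stats::pgamma(s1, shape = alpha + 1, scale = beta))
}

#' Simulate a dynamic pyruvate/lactate signal pair
#'
#' Propagates the discrete two-site exchange recursion at the frame times
#' `t_i = i * TR`, starting from zero magnetization. Per frame, pyruvate
#' magnetization loses `cos(theta_P)` to excitation and relaxes with rate
#' `r1p` while the integrated bolus feeds in; lactate loses `cos(theta_L)`,
#' relaxes with `r1l`, and gains the trapezoid of the post-excitation
#' pyruvate scaled by `kpl * TR`. Signals are `M * sin(theta)` plus
#' optional additive Gaussian magnitude noise.
#'
#' @param params A [kinetic_params()] object.
#' @param acq An [acquisition_config()] object.
#' @param substeps Integer >= 1. With `substeps = 1` (default) the discrete
#'   frame recursion is used (the exact inverse of [fit_kpl_inputless()]);
#'   larger values integrate the continuous-time exchange ODE on a finer
#'   grid between excitations, to probe discretization bias.
#' @return A list with `time` (s), `pyr` and `lac` signal vectors of length
#'   `acq$n_frames`.
#' @export
simulate_dynamics <- function(params, acq, substeps = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(acq, "acquisition_config"), substeps >= 1)
  sim <- simulate_dynamics_multi(
    kpl = params$kpl_per_second, bolus_scale = 1,
    bolus_delay = params$bolus_delay, params = params, acq = acq,
    substeps = as.integer(substeps))
  noise <- acq$noise_sigma
  pyr <- drop(sim$pyr)
  lac <- drop(sim$lac)
  if (noise > 0) {
    pyr <- pyr + stats::rnorm(length(pyr), sd = noise)
    lac <- lac + stats::rnorm(length(lac), sd = noise)
  }
  list(time = (seq_len(acq$n_frames) - 1) * acq$tr_seconds,
       pyr = as.numeric(pyr), lac = as.numeric(lac))
}

# Vectorised noiseless simulator: kpl, bolus_scale, bolus_delay are
# per-voxel vectors; returns n_voxel x n_frames signal matrices.
simulate_dynamics_multi <- function(kpl, bolus_scale, bolus_delay, params,
                                    acq, substeps = 1L) {
  nv <- length(kpl)
  stopifnot(length(bolus_scale) == nv, length(bolus_delay) == nv,
            all(kpl >= 0))
  n <- acq$n_frames
  tr <- acq$tr_seconds
  cp <- cos(acq$flip_pyr_degrees * pi / 180)
  cl <- cos(acq$flip_lac_degrees * pi / 180)
  sp <- sin(acq$flip_pyr_degrees * pi / 180)
  sl <- sin(acq$flip_lac_degrees * pi / 180)
  P <- matrix(0, nv, n)
  L <- matrix(0, nv, n)
  if (substeps == 1L) {
    ep <- exp(-tr * params$r1p_per_second)
    el <- exp(-tr * params$r1l_per_second)
    for (i in seq_len(n - 1)) {
      t1 <- (i - 1) * tr
      u <- bolus_scale * bolus_integral(t1, t1 + tr, params$bolus_amplitude,
                                        params$bolus_alpha, params$bolus_beta,
                                        delay = bolus_delay)
      P[, i + 1] <- P[, i] * cp * ep + u
      L[, i + 1] <- L[, i] * cl * el + kpl * tr * (P[, i] * cp + P[, i + 1]) / 2
    }
  } else {
    dt <- tr / substeps
    ep <- exp(-dt * params$r1p_per_second)
    el <- exp(-dt * params$r1l_per_second)
    Pc <- rep(0, nv)
    Lc <- rep(0, nv)
    for (i in seq_len(n - 1)) {
      Pc <- Pc * cp  # excitation at frame i - 1
      Lc <- Lc * cl
      for (s in seq_len(substeps)) {
        t1 <- (i - 1) * tr + (s - 1) * dt
        u <- bolus_scale * bolus_integral(t1, t1 + dt, params$bolus_amplitude,
                                          params$bolus_alpha,
                                          params$bolus_beta,
                                          delay = bolus_delay)
        Pn <- Pc * ep + u
        Lc <- Lc * el + kpl * dt * (Pc + Pn) / 2
        Pc <- Pn
      }
      P[, i + 1] <- Pc
      L[, i + 1] <- Lc
    }
  }
  list(pyr = P * sp, lac = L * sl)
}

#' Cohort-level simulation settings
#'
#' Defines the synthetic patient cohort: its size, per-patient lesion count
#' range, the proportional-hazards law that links generator-side (true)
#' imaging features to progression-free and overall survival, and the
#' censoring regime.
#'
#' Recognised names in `hazard_coefficients` are `kpl_median`, `kpl_max`,
#' `kpl_mean`, `tmv`, `psa`, `ldh` and `alp`; each true feature is
#' standardized (z-scored) across the cohort before entering the linear
#' predictor.
#'
#' @param n_patients Number of patients (default 16).
#' @param lesions_per_patient Integer range `c(min, max)`.
#' @param hazard_coefficients Named numeric vector of log-hazard weights.
#' @param baseline_weibull_shape,baseline_weibull_scale Weibull baseline of
#'   the progression process (scale in months).
#' @param os_scale_months Weibull scale of the death process (months).
#' @param censor_rate Probability of independent censoring, in [0, 1).
#' @param followup_months Administrative follow-up horizon (months).
#' @param n_missing_alp Number of patients whose ALP is blanked (to
#'   exercise median imputation downstream).
#' @param seed Integer seed; the same seed yields an identical cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 16, lesions_per_patient = c(1, 4),
                        hazard_coefficients = c(kpl_median = 1.0),
                        baseline_weibull_shape = 1.2,
                        baseline_weibull_scale = 18,
                        os_scale_months = 36,
                        censor_rate = 0.25, followup_months = 36,
                        n_missing_alp = 2, seed = 1L) {
  stopifnot(n_patients >= 1, length(lesions_per_patient) == 2L,
            lesions_per_patient[1] >= 1,
            lesions_per_patient[2] >= lesions_per_patient[1],
            baseline_weibull_shape > 0, baseline_weibull_scale > 0,
            os_scale_months > 0, followup_months > 0, n_missing_alp >= 0)
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must lie in [0, 1)")
  known <- c("kpl_median", "kpl_max", "kpl_mean", "tmv", "psa", "ldh", "alp")
  bad <- setdiff(names(hazard_coefficients), known)
  if (length(hazard_coefficients) && (is.null(names(hazard_coefficients)) ||
                                      length(bad)))
    stop("unknown feature name in hazard_coefficients: ",
         paste(bad, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 hazard_coefficients = hazard_coefficients,
                 baseline_weibull_shape = baseline_weibull_shape,
                 baseline_weibull_scale = baseline_weibull_scale,
                 os_scale_months = os_scale_months,
                 censor_rate = censor_rate,
                 followup_months = followup_months,
                 n_missing_alp = as.integer(n_missing_alp),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Ellipsoid lesion layout for one patient: centers and semi-axes in mm,
# constrained inside the field of view.
sample_lesions <- function(n_lesions, fov_mm) {
  sites <- c("bone", "node", "liver", "soft_tissue", "prostate")
  site_prob <- c(0.72, 0.11, 0.10, 0.02, 0.05)
  lesions <- vector("list", n_lesions)
  for (k in seq_len(n_lesions)) {
    radii <- stats::runif(3, 9, 26)
    center <- stats::runif(3, radii, fov_mm - radii)
    lesions[[k]] <- list(center_mm = center, radii_mm = radii,
                         site_label = sample(sites, 1, prob = site_prob))
  }
  lesions
}

#' Generate a synthetic hyperpolarized 13C MRI cohort
#'
#' Builds, for each patient, a 4D dynamic pyruvate/lactate series over the
#' native grid with ellipsoidal lesions carrying heterogeneous true kPL,
#' perfusion (bolus amplitude) and bolus-arrival values, an integer lesion
#' label mask, and a clinical record. Progression-free and overall survival
#' times are drawn from a Weibull-baseline proportional-hazards law whose
#' linear predictor uses the standardized true feature values named in
#' `spec$hazard_coefficients`; independent uniform censoring is applied at
#' rate `censor_rate` and all follow-up is truncated at `followup_months`.
#'
#' @param spec A [cohort_spec()].
#' @param acq An [acquisition_config()].
#' @param images Synthesize the dynamic image series (default TRUE). With
#'   `FALSE` only masks, generator-side truth features and the clinical
#'   table are produced, which is much faster when only the generative
#'   survival law is being studied.
#' @return A list of class `hp_cohort` with elements `patients` (each with
#'   `id`, `pyr`/`lac` 4D arrays, `mask`, `affine`, `lesions`, `truth`),
#'   `clinical` (data frame with columns patient_id, age, psa, ldh, alp,
#'   pfs_months, pfs_event, os_months, os_event), `truth` (data frame of
#'   generator-side features), `acq` and `spec`.
#' @export
generate_cohort <- function(spec, acq = acquisition_config(),
                            images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(acq, "acquisition_config"))
  set.seed(spec$seed)
  n <- spec$n_patients
  dims <- acq$matrix_size
  fov <- dims * acq$voxel_mm
  affine <- diag(c(acq$voxel_mm, 1))
  affine[1:3, 4] <- acq$voxel_mm / 2  # voxel centres at (i + 0.5) * voxel
  # voxel-centre world coordinates
  cx <- (seq_len(dims[1]) - 0.5) * acq$voxel_mm[1]
  cy <- (seq_len(dims[2]) - 0.5) * acq$voxel_mm[2]
  cz <- (seq_len(dims[3]) - 0.5) * acq$voxel_mm[3]
  base_par <- kinetic_params()

  patients <- vector("list", n)
  truth <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      kpl_median = NA_real_, kpl_max = NA_real_,
                      kpl_mean = NA_real_, tmv = NA_real_)
  for (p in seq_len(n)) {
    n_les <- sample(seq(spec$lesions_per_patient[1],
                        spec$lesions_per_patient[2]), 1)
    lesions <- sample_lesions(n_les, fov)
    base_kpl <- stats::rlnorm(1, meanlog = log(0.015), sdlog = 0.55)
    mask <- array(0L, dims)
    kpl_vox <- numeric(0)
    idx_all <- integer(0)
    scale_all <- numeric(0)
    delay_all <- numeric(0)
    for (k in seq_len(n_les)) {
      les <- lesions[[k]]
      d2 <- outer(outer(((cx - les$center_mm[1]) / les$radii_mm[1])^2,
                        ((cy - les$center_mm[2]) / les$radii_mm[2])^2, "+"),
                  ((cz - les$center_mm[3]) / les$radii_mm[3])^2, "+")
      inside <- which(d2 <= 1)
      if (!length(inside)) {  # degenerate small lesion: keep centre voxel
        ijk <- pmin(pmax(round(les$center_mm / acq$voxel_mm + 0.5), 1), dims)
        inside <- ijk[1] + dims[1] * (ijk[2] - 1) + dims[1] * dims[2] * (ijk[3] - 1)
      }
      lesion_kpl <- base_kpl * stats::rlnorm(1, 0, 0.25)
      vox_kpl <- lesion_kpl * stats::rlnorm(length(inside), 0, 0.15)
      vox_scale <- stats::rlnorm(length(inside), 0, 0.3)
      vox_delay <- stats::runif(1, 0, 4) + stats::runif(length(inside), 0, 1)
      mask[inside] <- k
      idx_all <- c(idx_all, inside)
      kpl_vox <- c(kpl_vox, vox_kpl)
      scale_all <- c(scale_all, vox_scale)
      delay_all <- c(delay_all, vox_delay)
      lesions[[k]]$kpl_per_second <- lesion_kpl
    }
    # later lesions overwrite overlapping voxels in the mask; keep the
    # matching kinetic draw per voxel
    dup <- duplicated(idx_all, fromLast = TRUE)
    idx_use <- idx_all[!dup]
    kpl_use <- kpl_vox[!dup]
    scale_use <- scale_all[!dup]
    delay_use <- delay_all[!dup]

    pyr <- NULL
    lac <- NULL
    if (images) {
      sim <- simulate_dynamics_multi(kpl_use, scale_use, delay_use,
                                     base_par, acq)
      pyr <- array(0, c(dims, acq$n_frames))
      lac <- array(0, c(dims, acq$n_frames))
      nvol <- prod(dims)
      for (f in seq_len(acq$n_frames)) {
        off <- (f - 1) * nvol
        pyr[off + idx_use] <- sim$pyr[, f]
        lac[off + idx_use] <- sim$lac[, f]
      }
      if (acq$noise_sigma > 0) {
        pyr <- pyr + array(stats::rnorm(length(pyr), sd = acq$noise_sigma),
                           dim(pyr))
        lac <- lac + array(stats::rnorm(length(lac), sd = acq$noise_sigma),
                           dim(lac))
      }
    }
    vol_ml <- prod(acq$voxel_mm) / 1000
    truth$kpl_median[p] <- stats::median(kpl_use) * 1000
    truth$kpl_max[p] <- max(kpl_use) * 1000
    truth$kpl_mean[p] <- mean(kpl_use) * 1000
    truth$tmv[p] <- length(idx_use) * vol_ml
    patients[[p]] <- list(id = truth$patient_id[p], pyr = pyr, lac = lac,
                          mask = mask, affine = affine, lesions = lesions)
  }

  clinical <- data.frame(
    patient_id = truth$patient_id,
    age = round(pmin(pmax(stats::rnorm(n, 69, 10), 48), 90)),
    psa = round(stats::rlnorm(n, log(13.9), 1.4), 2),
    ldh = round(stats::rlnorm(n, log(208), 0.30)),
    alp = round(stats::rlnorm(n, log(76), 0.45)))
  truth$psa <- clinical$psa
  truth$ldh <- clinical$ldh
  truth$alp <- clinical$alp

  # proportional-hazards outcome generation on standardized true features
  lp <- rep(0, n)
  for (nm in names(spec$hazard_coefficients)) {
    x <- truth[[nm]]
    s <- stats::sd(x)
    z <- if (is.na(s) || s == 0) rep(0, n) else (x - mean(x)) / s
    lp <- lp + spec$hazard_coefficients[[nm]] * z
  }
  shape <- spec$baseline_weibull_shape
  t_prog <- spec$baseline_weibull_scale *
    (-log(stats::runif(n)) / exp(lp))^(1 / shape)
  t_os <- spec$os_scale_months * (-log(stats::runif(n)) / exp(lp))^(1 / shape)
  t_pfs <- pmin(t_prog, t_os)
  cens <- ifelse(stats::runif(n) < spec$censor_rate,
                 stats::runif(n, 0, spec$followup_months),
                 spec$followup_months)
  clinical$pfs_months <- round(pmin(t_pfs, cens), 3)
  clinical$pfs_event <- as.integer(t_pfs <= cens)
  clinical$os_months <- round(pmin(t_os, cens), 3)
  clinical$os_event <- as.integer(t_os <= cens)
  if (spec$n_missing_alp > 0) {
    blank <- sample(n, min(spec$n_missing_alp, n))
    clinical$alp[blank] <- NA_real_
  }
  structure(list(patients = patients, clinical = clinical, truth = truth,
                 acq = acq, spec = spec),
            class = "hp_cohort")
}

#' @export
print.hp_cohort <- function(x, ...) {
  cat("Synthetic HP 13C cohort:", length(x$patients), "patients,",
      sum(vapply(x$patients, function(p) max(p$mask), 0)), "lesions\n")
  cat("  native grid", paste(x$acq$matrix_size, collapse = "x"),
      "voxels @", paste(x$acq$voxel_mm, collapse = "x"), "mm,",
      x$acq$n_frames, "frames, TR", x$acq$tr_seconds, "s\n")
  cat("  PFS events:", sum(x$clinical$pfs_event),
      " OS events:", sum(x$clinical$os_event), "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes per-patient 4D pyruvate/lactate NIfTI volumes and a 3D integer
#' lesion-label mask, the clinical table as CSV (header: patient_id, age,
#' psa, ldh, alp, pfs_months, pfs_event, os_months, os_event), and a cohort
#' manifest JSON recording the seed and all generator settings.
#'
#' @param cohort An `hp_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    write_volume(p$pyr, p$affine, file.path(dir, paste0(p$id, "_pyr.nii.gz")))
    write_volume(p$lac, p$affine, file.path(dir, paste0(p$id, "_lac.nii.gz")))
    write_volume(p$mask, p$affine, file.path(dir, paste0(p$id, "_mask.nii.gz")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  manifest <- c(list(generator = "hpmfm synthetic cohort"),
                unclass(cohort$spec),
                list(acquisition = unclass(cohort$acq)))
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
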