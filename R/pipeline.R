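# Polynomial rolling hash (mod 2^31 - 1) of a character string; used for
# the manifest config fingerprint so reruns can detect configuration drift
# without extra dependencies. Exact in double arithmetic (< 2^53).
config_fingerprint <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_blocks <- function() {
  list(
    cohort = names(formals(cohort_spec)),
    acquisition = names(formals(acquisition_config)),
    kinetic_model = names(formals(kinetic_model_config)),
    discretization = names(formals(discretization_config)),
    selection = names(formals(selection_config)),
    univariate = c("features", "kpl_median_cutoff"),
    pipeline = c("target_mm", "stages", "seed"))
}

#' Assemble and validate a pipeline configuration
#'
#' A pipeline configuration is a named list of blocks (`cohort`,
#' `acquisition`, `kinetic_model`, `discretization`, `selection`,
#' `univariate`, `pipeline`), each holding only keys understood by the
#' corresponding constructor. Unknown blocks or keys are rejected by name;
#' omitted keys take the constructor defaults. The configuration
#' round-trips losslessly through JSON.
#'
#' @param ... Blocks as named lists (e.g. `cohort = list(n_patients = 8)`).
#' @return A validated configuration (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.null(names(cfg)) && is.list(cfg[[1]]))
    cfg <- cfg[[1]]
  blocks <- config_blocks()
  bad_blocks <- setdiff(names(cfg), names(blocks))
  if (length(bad_blocks))
    stop("unknown config block: ", paste(bad_blocks, collapse = ", "))
  for (bl in names(cfg)) {
    bad <- setdiff(names(cfg[[bl]]), blocks[[bl]])
    if (length(bad))
      stop("unknown config key in '", bl, "': ",
           paste(bad, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with configuration blocks.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

# Instantiate the typed settings objects from a config, applying defaults.
realize_config <- function(cfg) {
  mk <- function(fun, block) do.call(fun, as.list(cfg[[block]]))
  list(cohort = mk(cohort_spec, "cohort"),
       acq = mk(acquisition_config, "acquisition"),
       model = mk(kinetic_model_config, "kinetic_model"),
       disc = mk(discretization_config, "discretization"),
       selection = mk(selection_config, "selection"),
       univariate = cfg$univariate,
       target_mm = if (!is.null(cfg$pipeline$target_mm))
         cfg$pipeline$target_mm else 5)
}

#' Univariate survival report
#'
#' For each chosen feature fits a univariate Cox model per endpoint and
#' tabulates the likelihood-ratio p-values and C-indices; additionally runs
#' the dichotomized Kaplan-Meier analysis of the median-kPL feature at the
#' given cutoff (cohort median when `NULL`).
#'
#' @param feature_matrix Feature data frame (`patient_id` + columns).
#' @param records Clinical data frame (ALP imputed internally).
#' @param features Character vector of feature columns to test; serology
#'   names (PSA/LDH/ALP) map to the clinical columns. Empty vector gives an
#'   empty table.
#' @param kpl_median_cutoff Dichotomization cutoff in ks^-1, or `NULL` for
#'   the cohort median.
#' @return List with `table` (feature, pfs_p, pfs_c, os_p, os_c) and `km`
#'   (a `km_split` for the median-kPL split, when available).
#' @export
univariate_report <- function(feature_matrix, records,
                              features = c("kPL_original_firstorder_Maximum",
                                           "kPL_original_firstorder_Median",
                                           "kPL_original_firstorder_Kurtosis",
                                           "TMV", "PSA", "LDH", "ALP"),
                              kpl_median_cutoff = NULL) {
  records <- impute_alp(records)
  pull <- function(nm) {
    if (nm %in% names(feature_matrix)) return(feature_matrix[[nm]])
    low <- tolower(nm)
    if (low %in% names(records)) return(records[[low]])
    NULL
  }
  rows <- lapply(features, function(nm) {
    x <- pull(nm)
    if (is.null(x) || stats::sd(x) == 0) return(NULL)
    fp <- suppressWarnings(cox_fit(cbind(x = x), records$pfs_months,
                                   records$pfs_event))
    fo <- suppressWarnings(cox_fit(cbind(x = x), records$os_months,
                                   records$os_event))
    data.frame(feature = nm, pfs_p = fp$lrt_p, pfs_c = fp$c_index,
               os_p = fo$lrt_p, os_c = fo$c_index)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(feature = character(0), pfs_p = numeric(0),
                      pfs_c = numeric(0), os_p = numeric(0),
                      os_c = numeric(0))
  km <- NULL
  kmed <- pull("kPL_original_firstorder_Median")
  if (!is.null(kmed)) {
    cut <- if (is.null(kpl_median_cutoff)) stats::median(kmed)
           else kpl_median_cutoff
    km <- km_by_group(kmed, cut, records$pfs_months, records$pfs_event)
  }
  list(table = tab, km = km)
}

km_split_table <- function(split) {
  grab <- function(cv, label) {
    if (is.null(cv)) return(NULL)
    data.frame(group = label, time = cv$times, survival = cv$survival,
               at_risk = cv$at_risk)
  }
  rbind(grab(split$low, "low"), grab(split$high, "high"))
}

read_cohort_tables <- function(dir) {
  utils::read.csv(file.path(dir, "clinical.csv"))
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain simulate -> maps -> features -> survival ->
#' select, writing every artifact under `outdir`: the synthetic cohort
#' (NIfTI volumes, clinical CSV, cohort manifest), resampled parametric
#' maps, the feature matrix CSV, the univariate report and Kaplan-Meier
#' tables, the selection/MPS reports, the correlogram CSV, and a run
#' manifest JSON with the configuration fingerprint and per-stage counts.
#' Any prefix of the chain can be re-run later: disabled early stages are
#' resumed from their cached outputs in `outdir`.
#'
#' @param config A [pipeline_config()] (or plain list accepted by it).
#' @param outdir Output directory.
#' @param stages Stages to execute, a contiguous subset of
#'   `c("simulate", "maps", "features", "survival", "select")`.
#' @param seed Optional integer overriding the cohort seed.
#' @return Invisibly, a list with the in-memory artifacts (`cohort`,
#'   `features`, `univariate`, `mps`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = c("simulate", "maps", "features",
                                    "survival", "select"),
                         seed = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  all_stages <- c("simulate", "maps", "features", "survival", "select")
  stopifnot(all(stages %in% all_stages))
  if (!is.null(seed)) config$cohort$seed <- as.integer(seed)
  rc <- realize_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  cohort <- NULL
  feats <- NULL
  uni <- NULL
  mps <- NULL
  maps_cache <- NULL

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(rc$cohort, rc$acq)
    write_cohort(cohort, file.path(outdir, "cohort"))
    counts$simulate <- list(patients = length(cohort$patients))
  }
  need_cohort <- any(c("maps", "features") %in% stages)
  if (is.null(cohort) && need_cohort) {
    cdir <- file.path(outdir, "cohort")
    if (!file.exists(file.path(cdir, "clinical.csv")))
      stop("missing upstream artifact: ", cdir)
    cohort <- read_cohort(cdir, rc$acq)
  }
  if ("maps" %in% stages) {
    mdir <- file.path(outdir, "maps")
    fit_stats <- list()
    maps_cache <- lapply(cohort$patients, function(p) {
      series <- dynamic_series(p$pyr, p$lac, cohort$acq, p$affine)
      kpl <- fit_kpl_inputless(series, rc$model)
      n_bad <- attr(kpl, "n_nonfinite")
      attr(kpl, "n_nonfinite") <- NULL
      native <- parametric_map_set(kpl, compute_pyr_auc(series),
                                   compute_mean_time(series, rc$model),
                                   p$mask, series$affine,
                                   voxel_size_from_affine(series$affine))
      rmaps <- resample_maps(native, rc$target_mm)
      write_map_set(rmaps, mdir, p$id)
      in_mask <- rmaps$kpl[rmaps$mask > 0]
      fit_stats[[p$id]] <<- list(
        n_nonfinite_voxels = n_bad,
        n_mask_voxels = sum(rmaps$mask > 0),
        kpl_max_ks = if (length(in_mask)) max(in_mask) else 0,
        kpl_median_ks = if (length(in_mask)) stats::median(in_mask) else 0)
      rmaps
    })
    names(maps_cache) <- vapply(cohort$patients, `[[`, "", "id")
    jsonlite::write_json(fit_stats, file.path(mdir, "fit_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    counts$maps <- list(patients = length(maps_cache),
                        voxels = sum(vapply(maps_cache, function(m)
                          sum(m$mask > 0), 0)))
  }
  if ("features" %in% stages) {
    if (is.null(maps_cache)) {
      mdir <- file.path(outdir, "maps")
      ids <- vapply(cohort$patients, `[[`, "", "id")
      if (!file.exists(file.path(mdir, paste0(ids[1], "_kpl.nii.gz"))))
        stop("missing upstream artifact: ", mdir)
      maps_cache <- lapply(ids, function(id) read_map_set(mdir, id))
      names(maps_cache) <- ids
    }
    rows <- lapply(maps_cache, function(m)
      tryCatch(extract_patient_features(m, rc$disc),
               error = function(e) NULL))
    keep <- !vapply(rows, is.null, TRUE)
    if (!any(keep)) stop("no patients with usable lesions")
    if (any(!keep))
      warning("patients without usable lesion voxels dropped: ",
              paste(names(rows)[!keep], collapse = ", "))
    feats <- data.frame(patient_id = names(rows)[keep],
                        do.call(rbind, rows[keep]), row.names = NULL,
                        check.names = FALSE)
    utils::write.csv(feats, file.path(outdir, "features.csv"),
                     row.names = FALSE)
    counts$features <- list(patients = nrow(feats),
                            features = ncol(feats) - 1L)
  }
  need_tables <- any(c("survival", "select") %in% stages)
  records <- NULL
  if (need_tables) {
    if (is.null(feats)) {
      fpath <- file.path(outdir, "features.csv")
      if (!file.exists(fpath)) stop("missing upstream artifact: ", fpath)
      feats <- utils::read.csv(fpath, check.names = FALSE)
    }
    cpath <- file.path(outdir, "cohort", "clinical.csv")
    records <- if (!is.null(cohort)) cohort$clinical
               else utils::read.csv(cpath)
    records <- records[match(feats$patient_id, records$patient_id), ]
  }
  if ("survival" %in% stages) {
    uni <- univariate_report(feats, records,
                             features = if (!is.null(config$univariate$features))
                               config$univariate$features
                             else eval(formals(univariate_report)$features),
                             kpl_median_cutoff =
                               config$univariate$kpl_median_cutoff)
    utils::write.csv(uni$table, file.path(outdir, "univariate.csv"),
                     row.names = FALSE)
    if (!is.null(uni$km))
      utils::write.csv(km_split_table(uni$km),
                       file.path(outdir, "km_kpl_median_pfs.csv"),
                       row.names = FALSE)
    tested <- intersect(uni$table$feature, names(feats))
    if (length(tested))
      utils::write.csv(
        as.data.frame(correlogram(feats[, c("patient_id", tested)],
                                  records)),
        file.path(outdir, "univariate_correlogram.csv"), row.names = TRUE)
    counts$survival <- list(features_tested = nrow(uni$table))
  }
  if ("select" %in% stages) {
    mps <- fit_mps(feats, records, rc$selection)
    utils::write.csv(
      data.frame(feature = names(mps$selection$scores),
                 adjusted_c_index = unname(mps$selection$scores),
                 retained = names(mps$selection$scores) %in%
                   mps$selection$retained, row.names = NULL),
      file.path(outdir, "selection_scores.csv"), row.names = FALSE)
    utils::write.csv(
      as.data.frame(mps$selection$correlation),
      file.path(outdir, "correlogram.csv"), row.names = TRUE)
    jsonlite::write_json(
      list(scores = as.list(mps$selection$scores),
           retained = mps$selection$retained,
           clusters = as.list(mps$selection$clusters),
           representatives = mps$selected_features),
      file.path(outdir, "selection_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(selected_features = mps$selected_features,
           coefficients = as.list(mps$coefficients),
           threshold = mps$threshold,
           pfs = list(lrt_p = mps$pfs_fit$lrt_p,
                      c_index = mps$pfs_fit$c_index),
           os = list(lrt_p = mps$os_lrt_p, c_index = mps$os_c_index),
           loo_normalized_sd = as.list(mps$loo_normalized_sd),
           loo_n_refits = mps$loo_n_refits),
      file.path(outdir, "mps_model.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.csv(km_split_table(mps$km_pfs),
                     file.path(outdir, "km_mps_pfs.csv"), row.names = FALSE)
    utils::write.csv(km_split_table(mps$km_os),
                     file.path(outdir, "km_mps_os.csv"), row.names = FALSE)
    counts$select <- list(candidates = length(mps$selection$scores),
                          retained = length(mps$selection$retained))
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(package = "hpmfm",
                   version = as.character(utils::packageVersion("hpmfm")),
                   config = unclass(config),
                   config_hash = config_fingerprint(as.character(cfg_json)),
                   seed = rc$cohort$seed, stages = stages,
                   counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, features = feats, univariate = uni,
                 mps = mps, manifest = manifest))
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param acq The [acquisition_config()] the cohort was generated with.
#' @return An `hp_cohort` (without generator truth values).
#' @export
read_cohort <- function(dir, acq) {
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"))
  patients <- lapply(clinical$patient_id, function(id) {
    pyr <- read_volume(file.path(dir, paste0(id, "_pyr.nii.gz")))
    lac <- read_volume(file.path(dir, paste0(id, "_lac.nii.gz")))
    mask <- read_volume(file.path(dir, paste0(id, "_mask.nii.gz")))
    list(id = id, pyr = pyr$data, lac = lac$data,
         mask = array(as.integer(round(mask$data)), dim(mask$data)),
         affine = pyr$affine, lesions = NULL)
  })
  structure(list(patients = patients, clinical = clinical, truth = NULL,
                 acq = acq, spec = NULL),
            class = "hp_cohort")
}
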