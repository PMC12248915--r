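#' Metabolic Prognostic Score of a coefficient vector
#'
#' Pure linear score `sum(coefficients * values)` over matching names.
#' Useful for applying an externally reported coefficient vector.
#'
#' @param coefficients Named numeric coefficient vector (log-hazard
#'   weights, including any age term).
#' @param values Named numeric vector or data frame of covariate values.
#' @return The score (numeric; one value per row for a data frame).
#' @export
mps_score <- function(coefficients, values) {
  if (is.data.frame(values) || is.matrix(values)) {
    v <- as.matrix(as.data.frame(values)[, names(coefficients),
                                         drop = FALSE])
    as.numeric(v %*% coefficients)
  } else {
    stopifnot(all(names(coefficients) %in% names(values)))
    sum(coefficients * values[names(coefficients)])
  }
}

# Multivariate Cox fit of representatives + age on the PFS endpoint, with a
# condition-number check and ridge-stabilised fallback for collinearity.
fit_mps_cox <- function(rep_matrix, records) {
  X <- cbind(rep_matrix, Age = records$age)
  sds <- apply(X, 2, stats::sd)
  scaled <- X[, sds > 0, drop = FALSE]
  flagged <- FALSE
  if (ncol(scaled) >= 2) {
    kap <- kappa(stats::cor(scale(scaled)), exact = TRUE)
    if (!is.finite(kap) || kap > 1e8) flagged <- TRUE
  }
  fit <- suppressWarnings(cox_fit(X, records$pfs_months, records$pfs_event))
  if (flagged || fit$diverged) {
    if (flagged)
      warning("collinear representatives; ridge-stabilised refit used")
    df <- data.frame(X, check.names = FALSE)
    df$.time <- records$pfs_months
    df$.event <- records$pfs_event
    vars <- paste0("`", colnames(X), "`", collapse = ", ")
    fml <- stats::as.formula(paste0(
      "survival::Surv(.time, .event) ~ survival::ridge(", vars,
      ", theta = 1, scale = TRUE)"))
    rfit <- suppressWarnings(survival::coxph(fml, data = df,
                                             ties = "breslow"))
    b <- stats::coef(rfit)
    names(b) <- colnames(X)
    b[!is.finite(b)] <- fit$beta[!is.finite(b)]  # fully degenerate columns
    fit$beta <- b
    fit$linear_predictor <- as.numeric(X %*% b)
    fit$ridge <- TRUE
  }
  fit
}

#' Fit the Metabolic Prognostic Score model
#'
#' Runs the full multivariate chain on a cohort feature matrix and clinical
#' records: ALP median imputation, adjusted C-index ranking with top-20%
#' retention, correlation-distance average-linkage clustering cut into
#' `n_clusters` branches, per-cluster representative selection, and a
#' multivariate Cox fit of the representatives plus patient age on the PFS
#' endpoint. The MPS is the resulting pure linear score (lower = more
#' favorable prognosis); the dichotomization threshold is the cohort median
#' MPS. Leave-one-out coefficient stability is assessed by refitting with
#' each patient withheld.
#'
#' @param feature_matrix Data frame from [extract_cohort_features()] (or
#'   compatible): `patient_id` plus feature columns.
#' @param records Clinical data frame aligned row-wise with
#'   `feature_matrix` (columns age, psa, ldh, alp, pfs_months, pfs_event,
#'   os_months, os_event).
#' @param cfg A [selection_config()].
#' @param loo Run the leave-one-out stability analysis (default TRUE).
#' @return An object of class `mps_model`.
#' @export
fit_mps <- function(feature_matrix, records, cfg = selection_config(),
                    loo = TRUE) {
  stopifnot(is.data.frame(records), nrow(feature_matrix) == nrow(records))
  records <- impute_alp(records)
  ranked <- rank_and_retain(feature_matrix, records, cfg)
  sel <- cluster_and_select(ranked$matrix, ranked$scores, cfg)
  rep_matrix <- ranked$matrix[, sel$representatives, drop = FALSE]
  fit <- fit_mps_cox(rep_matrix, records)
  scores <- fit$linear_predictor
  threshold <- stats::median(scores)
  km_pfs <- km_by_group(scores, threshold, records$pfs_months,
                        records$pfs_event)
  km_os <- km_by_group(scores, threshold, records$os_months,
                       records$os_event)
  os_fit <- suppressWarnings(
    cox_fit(cbind(mps = scores), records$os_months, records$os_event))
  loo_res <- if (loo) loo_stability(rep_matrix, records) else NULL
  structure(list(selected_features = sel$representatives,
                 coefficients = fit$beta, threshold = threshold,
                 scores = scores, pfs_fit = fit,
                 os_lrt_p = os_fit$lrt_p, os_c_index = os_fit$c_index,
                 km_pfs = km_pfs, km_os = km_os,
                 loo_normalized_sd = loo_res$normalized_sd,
                 loo_n_refits = loo_res$n_refits,
                 loo_n_failed = loo_res$n_failed,
                 selection = list(scores = ranked$scores,
                                  retained = ranked$retained,
                                  clusters = sel$clusters,
                                  correlation = sel$correlation),
                 records = records, cfg = cfg),
            class = "mps_model")
}

#' Leave-one-out stability of the MPS coefficients
#'
#' Withholds one patient at a time, refits the multivariate Cox model on
#' the remainder, and reports per coefficient the standard deviation across
#' the n refits divided by the absolute full-cohort coefficient. A refit
#' with zero spread reports 0 even when the full coefficient is 0.
#'
#' @param rep_matrix Patients x representatives numeric matrix.
#' @param records Clinical data frame aligned with `rep_matrix`.
#' @return List with `normalized_sd` (named), `coefficient_sd`,
#'   `full_coefficients`, `n_refits`, `n_failed`.
#' @export
loo_stability <- function(rep_matrix, records) {
  n <- nrow(rep_matrix)
  stopifnot(n >= 3, nrow(records) == n)
  full <- suppressWarnings(fit_mps_cox(rep_matrix, records))$beta
  betas <- matrix(NA_real_, n, length(full),
                  dimnames = list(NULL, names(full)))
  failed <- 0L
  for (i in seq_len(n)) {
    b <- tryCatch(
      suppressWarnings(fit_mps_cox(rep_matrix[-i, , drop = FALSE],
                                   records[-i, , drop = FALSE]))$beta,
      error = function(e) NULL)
    if (is.null(b)) failed <- failed + 1L else betas[i, ] <- b
  }
  if (failed == n) stop("every leave-one-out refit failed")
  sds <- apply(betas, 2, stats::sd, na.rm = TRUE)
  nsd <- ifelse(sds == 0, 0, sds / abs(full))
  list(normalized_sd = nsd, coefficient_sd = sds, full_coefficients = full,
       n_refits = n, n_failed = failed)
}

#' @export
coef.mps_model <- function(object, ...) object$coefficients

#' @export
predict.mps_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  nd <- as.data.frame(newdata)
  need <- names(object$coefficients)
  imaging <- setdiff(need, "Age")
  if (!"Age" %in% names(nd) && "age" %in% names(nd)) nd$Age <- nd$age
  missing_cols <- setdiff(c(imaging, "Age"), names(nd))
  if (length(missing_cols))
    stop("newdata lacks columns: ", paste(missing_cols, collapse = ", "))
  mps_score(object$coefficients, nd)
}

#' @export
print.mps_model <- function(x, digits = 4, ...) {
  cat("Metabolic Prognostic Score model (Cox PH, PFS endpoint)\n")
  cat("Selected variables:", paste(x$selected_features, collapse = ", "),
      "\n")
  cat("MPS =", paste(sprintf("%.4g x %s", x$coefficients,
                             names(x$coefficients)), collapse = " + "),
      "\n")
  cat("Dichotomization threshold (cohort median MPS):",
      round(x$threshold, digits), "\n")
  cat(sprintf("PFS: LRT p = %.3g, C-index = %.3f | OS: LRT p = %.3g, C-index = %.3f\n",
              x$pfs_fit$lrt_p, x$pfs_fit$c_index, x$os_lrt_p, x$os_c_index))
  invisible(x)
}

#' @export
summary.mps_model <- function(object, ...) {
  print(object)
  cat("\nDichotomized PFS: ")
  print(object$km_pfs)
  cat("Dichotomized OS: ")
  print(object$km_os)
  if (!is.null(object$loo_normalized_sd)) {
    cat("\nLeave-one-out normalized coefficient SD (",
        object$loo_n_refits, "refits,", object$loo_n_failed, "failed):\n")
    print(round(object$loo_normalized_sd, 3))
  }
  invisible(object)
}
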