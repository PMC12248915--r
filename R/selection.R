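#' Feature-selection settings
#'
#' Controls the concordance-ranked, correlation-clustered selection chain:
#' endpoint weights of the adjusted C-index, the retained fraction, the
#' number of dendrogram branches, and which serology columns join the
#' imaging features.
#'
#' @param w_pfs,w_os Adjusted C-index weights (must sum to 1); the PFS
#'   endpoint is weighted higher to reflect its greater maturity.
#' @param retain_fraction Fraction of features kept after ranking, (0, 1].
#' @param n_clusters Number of clusters cut from the dendrogram.
#' @param serology_features Clinical columns appended to the feature bank.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(w_pfs = 0.8, w_os = 0.2, retain_fraction = 0.20,
                             n_clusters = 4,
                             serology_features = c("psa", "ldh", "alp")) {
  stopifnot(abs(w_pfs + w_os - 1) < 1e-12, retain_fraction > 0,
            retain_fraction <= 1, n_clusters >= 1)
  structure(list(w_pfs = w_pfs, w_os = w_os,
                 retain_fraction = retain_fraction,
                 n_clusters = as.integer(n_clusters),
                 serology_features = serology_features),
            class = "selection_config")
}

# Weighted combination of per-endpoint concordance indices.
combine_c_indices <- function(c_pfs, c_os, cfg = selection_config()) {
  cfg$w_pfs * c_pfs + cfg$w_os * c_os
}

#' Adjusted C-index of a single feature
#'
#' Fits a univariate Cox model per endpoint and returns the weighted sum
#' `w_pfs * C_PFS + w_os * C_OS`, each C being Harrell's C of the fitted
#' linear predictor (self-orienting: the coefficient sign adapts, so the
#' value is >= 0.5 up to sampling noise).
#'
#' @param feature_column Numeric feature values, one per patient.
#' @param records Data frame with `pfs_months`, `pfs_event`, `os_months`,
#'   `os_event`.
#' @param cfg A [selection_config()].
#' @return Adjusted C-index, or `NA` for a degenerate (constant) feature.
#' @export
adjusted_c_index <- function(feature_column, records,
                             cfg = selection_config()) {
  if (stats::sd(feature_column) == 0 || anyNA(feature_column))
    return(NA_real_)
  cp <- suppressWarnings(
    cox_fit(cbind(x = feature_column), records$pfs_months,
            records$pfs_event)$c_index)
  co <- suppressWarnings(
    cox_fit(cbind(x = feature_column), records$os_months,
            records$os_event)$c_index)
  if (is.na(cp) || is.na(co)) return(NA_real_)
  combine_c_indices(cp, co, cfg)
}

#' Rank features by adjusted C-index and retain the top fraction
#'
#' Appends the serology columns to the imaging feature matrix, scores every
#' column by [adjusted_c_index()], and retains the top
#' `ceiling(retain_fraction * n)` by rank with deterministic tie-breaking
#' by feature name. Degenerate (constant) features are excluded before the
#' count is taken.
#'
#' @param feature_matrix Data frame: `patient_id` column plus feature
#'   columns, rows aligned with `records`.
#' @param records Clinical data frame (ALP already imputed).
#' @param cfg A [selection_config()].
#' @return A list with `retained` (ordered names), `scores` (named vector
#'   over all scoreable features) and `matrix` (patients x retained).
#' @export
rank_and_retain <- function(feature_matrix, records,
                            cfg = selection_config()) {
  stopifnot(is.data.frame(feature_matrix),
            nrow(feature_matrix) == nrow(records))
  X <- feature_matrix[, setdiff(names(feature_matrix), "patient_id"),
                      drop = FALSE]
  for (s in cfg$serology_features)
    if (s %in% names(records)) X[[toupper(s)]] <- records[[s]]
  if (ncol(X) < 5) stop("need at least 5 candidate features")
  scores <- vapply(X, adjusted_c_index, numeric(1), records = records,
                   cfg = cfg)
  ok <- !is.na(scores)
  if (!any(ok)) stop("all candidate features degenerate")
  scores <- scores[ok]
  ord <- order(-scores, names(scores))
  n_keep <- ceiling(cfg$retain_fraction * length(scores))
  retained <- names(scores)[ord][seq_len(n_keep)]
  list(retained = retained, scores = scores,
       matrix = as.matrix(X[, retained, drop = FALSE]))
}

#' Cluster retained features and pick one representative per cluster
#'
#' Computes the pairwise distance `1 - |pearson(f, g)|` across patients,
#' builds an average-linkage agglomerative dendrogram, cuts it into
#' `n_clusters` branches, and from each branch returns the member with the
#' highest adjusted C-index (ties broken by name). Also emits the
#' cluster-ordered correlation matrix for correlogram rendering.
#'
#' @param retained_matrix Patients x features numeric matrix.
#' @param scores Named adjusted C-index vector covering the columns.
#' @param cfg A [selection_config()].
#' @return A list with `representatives`, `clusters` (named membership
#'   vector), `correlation` (cluster-ordered matrix) and `dendrogram`
#'   (the hclust object).
#' @export
cluster_and_select <- function(retained_matrix, scores,
                               cfg = selection_config()) {
  m <- as.matrix(retained_matrix)
  if (ncol(m) < cfg$n_clusters)
    stop("fewer retained features than clusters")
  cm <- suppressWarnings(stats::cor(m))
  cm[!is.finite(cm)] <- 0
  d <- stats::as.dist(1 - abs(cm))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = cfg$n_clusters)
  reps <- vapply(seq_len(cfg$n_clusters), function(k) {
    members <- names(cl)[cl == k]
    sc <- scores[members]
    members[order(-sc, members)][1]
  }, character(1))
  ord <- hc$order  # dendrogram order groups clusters contiguously
  list(representatives = sort(reps), clusters = cl,
       correlation = cm[ord, ord], dendrogram = hc)
}

#' Pearson correlogram of features, serology and survival durations
#'
#' Symmetric Pearson correlation table between the given feature columns,
#' the serology markers, and the observed PFS/OS durations (censored
#' durations enter as observed follow-up, a documented approximation).
#'
#' @param feature_matrix Data frame or matrix of feature columns (may
#'   include `patient_id`, which is dropped).
#' @param records Clinical data frame.
#' @param cfg A [selection_config()].
#' @return Symmetric correlation matrix; zero-variance columns yield `NA`
#'   rows/columns.
#' @export
correlogram <- function(feature_matrix, records, cfg = selection_config()) {
  X <- as.data.frame(feature_matrix)
  X$patient_id <- NULL
  for (s in cfg$serology_features)
    if (s %in% names(records) && !toupper(s) %in% names(X))
      X[[toupper(s)]] <- records[[s]]
  X$PFS <- records$pfs_months
  X$OS <- records$os_months
  suppressWarnings(stats::cor(as.matrix(X)))
}
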