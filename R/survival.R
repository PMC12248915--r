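#' Harrell's concordance index
#'
#' Over all usable pairs — a pair is usable iff the smaller observed time
#' is an observed event — counts a pair concordant (weight 1) when the
#' higher risk score belongs to the shorter time, and gives tied risk
#' scores weight 0.5. Pairs with tied times are not usable.
#'
#' @param risk_scores Numeric risk scores (higher = worse expected outcome).
#' @param times Observed times.
#' @param events Event indicators (1 = observed, 0 = censored).
#' @return Concordant fraction in `[0, 1]`, or `NA` when no pair is usable.
#' @export
harrell_c <- function(risk_scores, times, events) {
  n <- length(risk_scores)
  stopifnot(length(times) == n, length(events) == n,
            all(events %in% c(0, 1)))
  earlier <- outer(times, times, "<")
  usable <- earlier & matrix(events == 1, n, n)
  den <- sum(usable)
  if (den == 0) return(NA_real_)
  num <- sum(usable & outer(risk_scores, risk_scores, ">")) +
    0.5 * sum(usable & outer(risk_scores, risk_scores, "=="))
  num / den
}

#' Cox proportional-hazards fit with likelihood-ratio test
#'
#' Maximises the partial likelihood (Breslow tie handling, via
#' [survival::coxph()]) and reports the coefficient vector, the
#' inverse-information covariance, the likelihood-ratio test against the
#' null model, Harrell's C of the fitted linear predictor, and per-covariate
#' hazard ratios with 95% Wald confidence intervals. Monotone-likelihood
#' divergence (perfect separation) is detected, the affected coefficients
#' capped, and the fit flagged.
#'
#' @param covariates Numeric vector, matrix or data frame of covariates
#'   (no missing values).
#' @param times Observed times.
#' @param events Event indicators (1 = observed, 0 = censored).
#' @return An object of class `cox_fit` with elements `beta`, `covariance`,
#'   `lrt_stat`, `lrt_p`, `c_index`, `hazard_ratio_ci`, `linear_predictor`,
#'   `diverged`, `n`, `n_events`.
#' @export
cox_fit <- function(covariates, times, events) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  stopifnot(length(times) == n, length(events) == n, all(times >= 0),
            all(events %in% c(0, 1)))
  if (anyNA(X)) stop("missing covariate values; impute upstream")
  if (sum(events) == 0) stop("no observed events")
  df <- data.frame(X, check.names = FALSE)
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(times, events) ~ ., data = df, ties = "breslow",
    control = survival::coxph.control(eps = 1e-10, iter.max = 100)))
  beta <- stats::coef(fit)
  diverged <- any(!is.finite(beta)) || any(abs(beta) > 15, na.rm = TRUE)
  if (diverged) {
    warning("monotone likelihood suspected; coefficients capped at |15|")
    beta[!is.finite(beta)] <- 0
    beta <- pmin(pmax(beta, -15), 15)
  }
  V <- stats::vcov(fit)
  lrt_stat <- max(2 * (fit$loglik[2] - fit$loglik[1]), 0)
  dfree <- sum(is.finite(stats::coef(fit)))
  lp <- as.numeric(X %*% beta)
  se <- sqrt(pmax(diag(V), 0))
  hr <- data.frame(term = names(beta), hr = exp(beta),
                   lower95 = exp(beta - 1.96 * se),
                   upper95 = exp(beta + 1.96 * se),
                   p_wald = 2 * stats::pnorm(-abs(beta / se)),
                   row.names = NULL)
  structure(list(beta = beta, covariance = V, lrt_stat = lrt_stat,
                 lrt_p = stats::pchisq(lrt_stat, dfree, lower.tail = FALSE),
                 c_index = harrell_c(lp, times, events),
                 hazard_ratio_ci = hr, linear_predictor = lp,
                 diverged = diverged, n = n, n_events = sum(events)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat("Cox proportional-hazards fit (Breslow ties):", x$n, "subjects,",
      x$n_events, "events\n")
  tab <- cbind(beta = x$beta, x$hazard_ratio_ci[, c("hr", "lower95",
                                                    "upper95")])
  print(round(tab, digits))
  cat("LRT p =", format(x$lrt_p, digits = 3),
      "  C-index =", round(x$c_index, 3),
      if (x$diverged) "  [diverged]" else "", "\n")
  invisible(x)
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate of the survival function with the median defined
#' as the smallest time at which the estimate drops to 0.5 or below;
#' a median never reached is reported as `NA` with `median_reached =
#' FALSE` (printed "NR").
#'
#' @param times Observed times.
#' @param events Event indicators (1 = observed, 0 = censored).
#' @return An object of class `km_curve` with `times`, `survival`,
#'   `at_risk`, `n`, `n_events`, `median`, `median_reached`.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)), length(times) >= 1)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- sf$surv
  med_i <- which(s <= 0.5 + 1e-12 & sf$n.event > 0)
  reached <- length(med_i) > 0
  structure(list(times = sf$time, survival = s, at_risk = sf$n.risk,
                 n = length(times), n_events = sum(events),
                 median = if (reached) sf$time[min(med_i)] else NA_real_,
                 median_reached = reached),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", x$n_events, "events; median",
      if (x$median_reached) format(x$median) else "NR", "\n")
  invisible(x)
}

#' Dichotomized Kaplan-Meier analysis
#'
#' Splits subjects at a score threshold (low group: score <= threshold) and
#' returns the per-group product-limit curves and medians, plus the Cox
#' likelihood-ratio p-value and C-index of the binary group indicator.
#'
#' @param scores Numeric risk scores.
#' @param threshold Finite split value.
#' @param times Observed times.
#' @param events Event indicators.
#' @return An object of class `km_split` with `low`, `high` (km_curve or
#'   NULL for an empty group), `medians`, `n`, `lrt_p`, `c_index`,
#'   `hazard_ratio`.
#' @export
km_by_group <- function(scores, threshold, times, events) {
  stopifnot(is.finite(threshold), length(scores) == length(times))
  low <- scores <= threshold
  curves <- list(low = NULL, high = NULL)
  if (any(low)) curves$low <- km_curve(times[low], events[low])
  if (any(!low)) curves$high <- km_curve(times[!low], events[!low])
  med <- function(cv) if (is.null(cv)) NA_real_ else cv$median
  lrt_p <- NA_real_
  cidx <- NA_real_
  hr <- NULL
  if (any(low) && any(!low) && sum(events) > 0) {
    cf <- cox_fit(cbind(high_group = as.numeric(!low)), times, events)
    lrt_p <- cf$lrt_p
    cidx <- harrell_c(as.numeric(!low), times, events)
    hr <- cf$hazard_ratio_ci
  }
  structure(list(low = curves$low, high = curves$high,
                 medians = c(low = med(curves$low), high = med(curves$high)),
                 n = c(low = sum(low), high = sum(!low)),
                 lrt_p = lrt_p, c_index = cidx, hazard_ratio = hr),
            class = "km_split")
}

#' @export
print.km_split <- function(x, ...) {
  fm <- function(cv) if (is.null(cv)) "empty"
    else if (cv$median_reached) format(cv$median) else "NR"
  cat("Dichotomized Kaplan-Meier: median", fm(x$low), "(low, n =",
      x$n["low"], ") vs", fm(x$high), "(high, n =", x$n["high"], ")\n")
  if (is.finite(x$lrt_p))
    cat("LRT p =", format(x$lrt_p, digits = 3), " group C-index =",
        round(x$c_index, 3), "\n")
  invisible(x)
}

#' Median-impute missing alkaline phosphatase values
#'
#' Replaces missing ALP readings by the cohort median of the observed
#' values, mirroring standard serology handling for small cohorts.
#'
#' @param records Data frame with an `alp` column.
#' @return The records with `alp` completed.
#' @export
impute_alp <- function(records) {
  stopifnot(is.data.frame(records), "alp" %in% names(records))
  obs <- records$alp[!is.na(records$alp)]
  if (!length(obs)) stop("all ALP values missing")
  records$alp[is.na(records$alp)] <- stats::median(obs)
  records
}
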