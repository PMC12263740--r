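#' OLS slope with classical standard error
#'
#' Slope of `response` on `predictor` (plus optional covariates), with the
#' textbook homoskedastic standard error. These per-stratum regressions of
#' exposure on instrument and outcome on instrument are the two ingredients
#' of the Wald ratio.
#'
#' @inheritParams ols_residuals
#' @return list with `beta` and `se`.
#' @export
ols_beta <- function(response, predictor, covariates = NULL) {
  n <- length(response)
  stopifnot(length(predictor) == n)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (is.null(covariates)) {
    # closed form for the simple regression: cheaper inside replicate loops
    sxx <- sum((predictor - mean(predictor))^2)
    if (sxx == 0) stop("singular design: predictor is constant",
                       call. = FALSE)
    sxy <- sum((predictor - mean(predictor)) * (response - mean(response)))
    beta <- sxy / sxx
    rss <- sum((response - mean(response) - beta * (predictor - mean(predictor)))^2)
    se <- sqrt(max(rss, 0) / (n - 2L) / sxx)
    return(list(beta = beta, se = se))
  }
  X <- design_matrix(predictor, covariates, n)
  fit <- stats::lm.fit(X, response)
  if (fit$rank < ncol(X)) {
    stop("singular design: predictor collinear with covariates",
         call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - ncol(X))
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  idx <- match("predictor", colnames(X))
  list(beta = unname(fit$coefficients["predictor"]),
       se = sqrt(sigma2 * XtX_inv[idx, idx]))
}

#' Wald ratio estimator
#'
#' The one-sample MR estimate: the instrument-outcome coefficient divided by
#' the instrument-exposure coefficient. The default standard error is the
#' first-order delta approximation `se_gy / |beta_gx|`; `order = 2` adds the
#' term from the uncertainty of the denominator,
#' `sqrt(se_gy^2/beta_gx^2 + beta_gy^2 se_gx^2 / beta_gx^4)`.
#'
#' @param beta_gx,se_gx instrument-exposure coefficient and SE.
#' @param beta_gy,se_gy instrument-outcome coefficient and SE.
#' @param order 1 (default) or 2; delta-method order for the SE.
#' @return list with `wald` and `se_wald`.
#' @export
wald_ratio <- function(beta_gx, se_gx, beta_gy, se_gy, order = 1L) {
  if (beta_gx == 0) {
    stop("undefined Wald ratio: instrument-exposure coefficient is 0",
         call. = FALSE)
  }
  wald <- beta_gy / beta_gx
  se_wald <- if (order >= 2L) {
    sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 * se_gx^2 / beta_gx^4)
  } else {
    se_gy / abs(beta_gx)
  }
  list(wald = wald, se_wald = se_wald)
}

#' Stratum-specific and full-sample Wald estimates
#'
#' For every stratum of the assignment (and for the full sample, reported as
#' stratum 0) runs the within-stratum OLS of exposure on instrument and of
#' outcome on instrument, and combines them with [wald_ratio()]. When
#' covariates are supplied they enter both within-stratum regressions;
#' stratification itself is never covariate-adjusted. Instrument strength is
#' reported as the first-stage F statistic `(beta_gx/se_gx)^2`, and strata
#' with F below `weak_f` are flagged (flagged, not dropped: dropping strata
#' would distort the bias patterns under study).
#'
#' @param cohort an [nlmr_cohort] with columns `g`, `x`, `y`.
#' @param assignment a `stratum_assignment` aligned to the cohort rows.
#' @param covariates optional covariates for the within-stratum regressions
#'   (vector, matrix or data.frame aligned to the cohort).
#' @param se_order delta-method order for the Wald SE (1 or 2).
#' @param weak_f F-statistic threshold for the weak-instrument flag.
#' @param permissive if `TRUE`, a stratum with an exactly-zero
#'   instrument-exposure coefficient yields an `NA` estimate flagged in the
#'   output instead of an error.
#' @return a data.frame with one row per stratum (stratum 0 = full sample)
#'   and columns `stratum, n, beta_gx, se_gx, beta_gy, se_gy, wald, se_wald,
#'   f_stat, weak_flag`.
#' @export
estimate_strata <- function(cohort, assignment, covariates = NULL,
                            se_order = 1L, weak_f = 10, permissive = FALSE) {
  stopifnot(inherits(assignment, "stratum_assignment"),
            length(assignment$stratum) == nrow(cohort))
  cov_mat <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  one <- function(rows, s) {
    if (length(rows) < 3L) {
      stop("stratum ", s, " has fewer than 3 members", call. = FALSE)
    }
    cv <- if (!is.null(cov_mat)) cov_mat[rows, , drop = FALSE] else NULL
    gx <- ols_beta(cohort$x[rows], cohort$g[rows], cv)
    gy <- ols_beta(cohort$y[rows], cohort$g[rows], cv)
    if (gx$beta == 0 && permissive) {
      w <- list(wald = NA_real_, se_wald = NA_real_)
    } else {
      w <- wald_ratio(gx$beta, gx$se, gy$beta, gy$se, order = se_order)
    }
    f <- if (gx$se > 0) (gx$beta / gx$se)^2 else Inf
    data.frame(stratum = s, n = length(rows),
               beta_gx = gx$beta, se_gx = gx$se,
               beta_gy = gy$beta, se_gy = gy$se,
               wald = w$wald, se_wald = w$se_wald,
               f_stat = f, weak_flag = f < weak_f)
  }
  S <- assignment$S
  out <- vector("list", S + 1L)
  out[[1L]] <- one(seq_len(nrow(cohort)), 0L)
  rows_by_stratum <- split(seq_len(nrow(cohort)), assignment$stratum)
  for (s in seq_len(S)) {
    out[[s + 1L]] <- one(rows_by_stratum[[as.character(s)]], s)
  }
  do.call(rbind, out)
}
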