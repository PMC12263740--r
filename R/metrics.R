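#' Cochran's Q heterogeneity statistic across stratum estimates
#'
#' Fixed-effect inverse-variance pooling: weights `w_i = 1/se_i^2`, pooled
#' estimate `sum(w*est)/sum(w)`, `Q = sum(w*(est - pooled)^2)`, compared to
#' a chi-square with `k - 1` degrees of freedom. Under homogeneous stratum
#' effects the p-value is uniform, so the detection rate at `p < 0.05`
#' should sit at the nominal 5%.
#'
#' @param estimates numeric vector of stratum estimates (length >= 2).
#' @param ses positive standard errors, same length.
#' @return list with `Q`, `df`, `p` and the `pooled` estimate.
#' @export
cochran_q <- function(estimates, ses) {
  k <- length(estimates)
  stopifnot(length(ses) == k)
  if (k < 2L) stop("need at least 2 estimates", call. = FALSE)
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop("all standard errors must be finite and > 0", call. = FALSE)
  }
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - pooled)^2)
  df <- k - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       pooled = pooled)
}

#' Stratum-wise and pooled mean squared error across replicates
#'
#' `per_stratum[s]` is the mean over replicates of the squared deviation of
#' the stratum-s estimate from `truth`; `pooled` is the mean over replicates
#' of the within-replicate across-strata mean squared deviation (for a
#' complete matrix this equals the grand mean, and also the mean of
#' `per_stratum`). All study scenarios have `truth = 0`: the exposure never
#' causes the outcome, so squared estimates are squared errors.
#'
#' @param estimates_by_replicate numeric matrix, replicates in rows, strata
#'   in columns.
#' @param truth true stratum-level causal effect (default 0).
#' @param complete_cases drop replicates containing `NA` instead of
#'   erroring.
#' @return list with `per_stratum` (length S) and `pooled`.
#' @export
stratum_mse <- function(estimates_by_replicate, truth = 0,
                        complete_cases = FALSE) {
  m <- as.matrix(estimates_by_replicate)
  if (anyNA(m)) {
    if (!complete_cases) {
      stop("missing estimates; set complete_cases = TRUE to drop those ",
           "replicates", call. = FALSE)
    }
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  if (nrow(m) < 1L) stop("no complete replicates", call. = FALSE)
  sq <- (m - truth)^2
  list(per_stratum = colMeans(sq), pooled = mean(rowMeans(sq)))
}

#' Heterogeneity detection rate across replicates
#'
#' The proportion of replicates whose Cochran's Q p-value falls strictly
#' below `alpha` (nominal evidence of across-strata heterogeneity). 1 means
#' every replicate showed heterogeneity; 0 means none did.
#'
#' @param p_values numeric vector of per-replicate p-values in `[0, 1]`.
#' @param alpha significance threshold (default 0.05).
#' @return proportion in `[0, 1]`.
#' @export
heterogeneity_rate <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  mean(p_values < alpha)
}

#' Confidence-interval coverage of a known truth
#'
#' Fraction of symmetric normal-quantile intervals
#' `estimate +/- z * se` that contain `truth`.
#'
#' @param estimates,ses numeric vectors of equal length; `ses > 0`.
#' @param truth true value.
#' @param level nominal coverage level (default 0.95).
#' @return proportion in `[0, 1]`.
#' @export
coverage <- function(estimates, ses, truth = 0, level = 0.95) {
  stopifnot(length(estimates) == length(ses))
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop("all standard errors must be finite and > 0", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  mean(abs(estimates - truth) <= z * ses)
}
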