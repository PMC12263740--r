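#' Ordinary least-squares residuals of exposure on instrument
#'
#' Fits `response ~ predictor (+ covariates)` by OLS (with intercept) and
#' returns the residual vector together with the slope and intercept. This
#' is the regression underlying the residual stratification method: the
#' exposure is regressed on the genotype and the residuals define the
#' strata.
#'
#' @param response numeric vector.
#' @param predictor numeric vector (non-constant).
#' @param covariates optional numeric vector, matrix or data.frame of extra
#'   regressors.
#' @return list with `residuals`, `slope` (coefficient on `predictor`) and
#'   `intercept`.
#' @export
ols_residuals <- function(response, predictor, covariates = NULL) {
  n <- length(response)
  stopifnot(length(predictor) == n)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  X <- design_matrix(predictor, covariates, n)
  fit <- stats::lm.fit(X, response)
  if (fit$rank < ncol(X)) {
    stop("singular design: predictor (after covariates) is constant or ",
         "collinear", call. = FALSE)
  }
  list(residuals = as.numeric(fit$residuals),
       slope = unname(fit$coefficients["predictor"]),
       intercept = unname(fit$coefficients["(Intercept)"]))
}

design_matrix <- function(predictor, covariates, n) {
  if (is.null(covariates)) {
    cbind("(Intercept)" = rep(1, n), predictor = predictor)
  } else {
    Z <- as.matrix(covariates)
    stopifnot(nrow(Z) == n)
    if (is.null(colnames(Z))) {
      colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    }
    cbind("(Intercept)" = rep(1, n), predictor = predictor, Z)
  }
}

new_assignment <- function(stratum, method, S, pre_stratum = NULL) {
  structure(list(stratum = as.integer(stratum), method = method,
                 S = as.integer(S), pre_stratum = pre_stratum),
            class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat(sprintf("<stratum_assignment> method = %s, S = %d, n = %d\n",
              x$method, x$S, length(x$stratum)))
  print(table(stratum = x$stratum))
  invisible(x)
}

#' Residual-method stratification
#'
#' Regresses the exposure on the instrument, sorts individuals by the
#' residual and cuts them into `S` equal-count strata (sizes differ by at
#' most one); stratum 1 holds the lowest residuals. Valid for stratified MR
#' only under the constant-genetic-effect assumption. Ties in the residual
#' are broken by a deterministic id-keyed pseudo-random key (see Details of
#' [stratify_doubly_ranked()]).
#'
#' @param cohort an [nlmr_cohort] (needs columns `g`, `x`, `id`).
#' @param S number of strata (>= 2).
#' @param covariates optional covariates to residualize on jointly with `g`.
#' @param tie_seed seed for the tie-break key.
#' @return a `stratum_assignment` aligned to the cohort rows.
#' @export
stratify_residual <- function(cohort, S, covariates = NULL,
                              tie_seed = 20260920L) {
  n <- nrow(cohort)
  check_strata_args(n, S)
  res <- ols_residuals(cohort$x, cohort$g, covariates)$residuals
  # residuals indistinguishable from 0 at machine precision (exact fits)
  # collapse to an exact tie so the tie rule, not QR round-off, decides
  scale <- max(stats::sd(cohort$x), .Machine$double.eps)
  res[abs(res) < 1e-10 * scale] <- 0
  key <- tie_keys(cohort$id, tie_seed)
  rnk <- rank_with_key(res, key)
  new_assignment(position_stratum(rnk, n, S), "residual", S)
}

#' Doubly-ranked stratification
#'
#' Individuals are first ranked by the instrument `g` and cut into
#' consecutive pre-strata of size `S` (the number of strata); within each
#' pre-stratum individuals are then ranked by the exposure, and the member
#' with the j-th lowest exposure is placed in stratum j. Stratum 1 thus
#' collects the lowest-exposure member of every pre-stratum, and each
#' stratum spans the full range of the instrument. When `S` does not divide
#' `n`, the final pre-stratum holds `m < S` members and its j-th-lowest
#' member is placed in stratum `ceiling(j*S/m)`, which preserves
#' monotonicity of stratum in exposure rank.
#'
#' Valid for stratified MR under the rank-preserving assumption (an
#' individual's exposure rank would be unchanged at any counterfactual level
#' of the instrument), which is weaker than the constant-genetic-effect
#' assumption of the residual method.
#'
#' All ranks break ties with a deterministic pseudo-random key drawn per
#' `id` from `tie_seed`, so the assignment is reproducible and equivariant
#' under permutation of the input rows.
#'
#' @inheritParams stratify_residual
#' @return a `stratum_assignment` with `pre_stratum` filled in.
#' @export
stratify_doubly_ranked <- function(cohort, S, tie_seed = 20260920L) {
  n <- nrow(cohort)
  check_strata_args(n, S)
  key <- tie_keys(cohort$id, tie_seed)
  g_rank <- rank_with_key(cohort$g, key)
  pre <- as.integer(ceiling(g_rank / S))
  # within-pre-stratum exposure rank
  ord <- order(pre, cohort$x, key)
  j <- integer(n)
  j[ord] <- stats::ave(rep(1L, n), pre[ord], FUN = seq_along)
  m <- tabulate(pre)[pre] # size of each row's pre-stratum
  stratum <- as.integer(ceiling(j * S / m))
  new_assignment(stratum, "doubly_ranked", S, pre_stratum = pre)
}

check_strata_args <- function(n, S) {
  if (S < 2L) stop("'S' must be >= 2", call. = FALSE)
  if (n < 2L * S) stop("need n >= 2*S individuals for ", S, " strata",
                       call. = FALSE)
  invisible(TRUE)
}

#' Write a stratum assignment as tab-separated text
#'
#' @param assignment a `stratum_assignment`.
#' @param cohort the cohort it is aligned to (for ids).
#' @param path file path.
#' @export
write_assignment <- function(assignment, cohort, path) {
  df <- data.frame(id = cohort$id, method = assignment$method,
                   pre_stratum = assignment$pre_stratum %||% NA_integer_,
                   stratum = assignment$stratum)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
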