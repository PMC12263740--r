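#' Run one simulation scenario across replicates and methods
#'
#' The central Monte Carlo driver. For each replicate a fresh cohort is
#' generated from the scenario configuration under its own child seed, the
#' cohort is stratified by each requested method, Wald estimates are formed
#' for every stratum and for the full sample, and Cochran's Q is computed
#' across the stratum estimates. Results are aggregated into per-method
#' summaries: stratum-wise mean estimates with Monte Carlo standard errors,
#' stratum-wise and pooled mean squared error (against the true effect of
#' 0), the heterogeneity detection rate, and confidence-interval coverage.
#'
#' Covariate adjustment (the adjustment experiment) enters the
#' within-stratum regressions only; stratification is always unadjusted.
#' `adjust = "u"` adjusts on the true confounder; `adjust = "u_error"`
#' adjusts on an error-prone measurement of it with Pearson correlation
#' `u_error_r` (incomplete adjustment).
#'
#' @param config a [scenario_config()].
#' @param methods any of `"residual"`, `"doubly_ranked"`.
#' @param adjust `"none"`, `"u"` or `"u_error"`.
#' @param u_error_r correlation of the error-prone confounder with `u`.
#' @param se_order delta-method order for Wald SEs.
#' @return object of class `scenario_result`: list with `config`,
#'   `estimates` (long data.frame: method, replicate, stratum, estimates),
#'   `q` (per-replicate Cochran's Q), and `summaries` (per-method list; see
#'   [scenario_summary()]).
#' @examples
#' cfg <- scenario_config(n = 2000, seed = 1, n_replicates = 5,
#'                        b_ux = 0.3, b_uy = 0.3)
#' res <- run_scenario(cfg)
#' scenario_summary(res, "doubly_ranked")$per_stratum_mean
#' @export
run_scenario <- function(config, methods = c("residual", "doubly_ranked"),
                         adjust = c("none", "u", "u_error"),
                         u_error_r = 0.8, se_order = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  adjust <- match.arg(adjust)
  methods <- match.arg(methods, c("residual", "doubly_ranked"),
                       several.ok = TRUE)
  R <- config$n_replicates
  seeds <- child_seeds(config$seed, 2L * R) # second half: auxiliary draws
  est_rows <- list()
  q_rows <- list()
  failed <- 0L
  for (r in seq_len(R)) {
    rep_out <- tryCatch(
      run_one_replicate(config, methods, adjust, u_error_r, se_order,
                        cohort_seed = seeds[r], aux_seed = seeds[R + r],
                        replicate = r),
      error = function(e) {
        message("replicate ", r, " (seed ", seeds[r], ") failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(rep_out)) {
      failed <- failed + 1L
      next
    }
    est_rows[[r]] <- rep_out$estimates
    q_rows[[r]] <- rep_out$q
  }
  if (failed > 0.05 * R) {
    stop("more than 5% of replicates failed (", failed, " of ", R, ")",
         call. = FALSE)
  }
  estimates <- do.call(rbind, est_rows)
  q <- do.call(rbind, q_rows)
  summaries <- lapply(stats::setNames(methods, methods), function(m) {
    summarize_method(estimates[estimates$method == m, ],
                     q[q$method == m, ], config)
  })
  structure(list(config = config, methods = methods, adjust = adjust,
                 estimates = estimates, q = q, summaries = summaries,
                 n_failed = failed),
            class = "scenario_result")
}

run_one_replicate <- function(config, methods, adjust, u_error_r, se_order,
                              cohort_seed, aux_seed, replicate) {
  cohort <- generate_cohort(config, seed = cohort_seed)
  covariates <- switch(adjust,
    none = NULL,
    u = cohort$u,
    u_error = generate_error_prone_confounder(cohort$u, u_error_r,
                                              seed = aux_seed))
  est_list <- list()
  q_list <- list()
  for (m in methods) {
    asg <- if (m == "residual") {
      stratify_residual(cohort, config$n_strata)
    } else {
      stratify_doubly_ranked(cohort, config$n_strata)
    }
    est <- estimate_strata(cohort, asg, covariates = covariates,
                           se_order = se_order)
    est$method <- m
    est$replicate <- replicate
    strata <- est[est$stratum > 0L, ]
    qq <- cochran_q(strata$wald, strata$se_wald)
    est_list[[m]] <- est
    q_list[[m]] <- data.frame(method = m, replicate = replicate,
                              Q = qq$Q, df = qq$df, p = qq$p)
  }
  list(estimates = do.call(rbind, est_list), q = do.call(rbind, q_list))
}

summarize_method <- function(est, q, config) {
  S <- config$n_strata
  strata <- est[est$stratum > 0L, ]
  reps <- sort(unique(strata$replicate))
  wald_mat <- matrix(NA_real_, length(reps), S)
  for (i in seq_along(reps)) {
    rows <- strata[strata$replicate == reps[i], ]
    wald_mat[i, rows$stratum] <- rows$wald
  }
  mse <- stratum_mse(wald_mat, truth = 0, complete_cases = TRUE)
  per_mean <- colMeans(wald_mat)
  per_mc_se <- apply(wald_mat, 2L, stats::sd) / sqrt(nrow(wald_mat))
  cov_by_stratum <- vapply(seq_len(S), function(s) {
    rows <- strata[strata$stratum == s, ]
    coverage(rows$wald, rows$se_wald, truth = 0)
  }, numeric(1))
  full <- est[est$stratum == 0L, ]
  list(method = est$method[1L],
       n_replicates = length(reps),
       per_stratum_mean = per_mean,
       per_stratum_mc_se = per_mc_se,
       per_stratum_mse = mse$per_stratum,
       pooled_mse = mse$pooled,
       het_rate = heterogeneity_rate(q$p),
       coverage = cov_by_stratum,
       full_sample = list(mean = mean(full$wald),
                          mc_se = stats::sd(full$wald) / sqrt(nrow(full)),
                          coverage = coverage(full$wald, full$se_wald,
                                              truth = 0)),
       config_echo = unclass(config))
}

#' Extract one method's summary from a scenario result
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @param method `"residual"` or `"doubly_ranked"`.
#' @return the per-method summary list (stratum means, Monte Carlo SEs,
#'   MSEs, pooled MSE, heterogeneity rate, coverage, full-sample summary).
#' @export
scenario_summary <- function(result, method) {
  stopifnot(inherits(result, "scenario_result"))
  s <- result$summaries[[method]]
  if (is.null(s)) stop("no summary for method '", method, "'", call. = FALSE)
  s
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  print(x$config)
  for (m in x$methods) {
    s <- x$summaries[[m]]
    cat(sprintf("  %s: pooled MSE %.4g, heterogeneity rate %.2f\n",
                m, s$pooled_mse, s$het_rate))
    cat("    stratum means:",
        paste(sprintf("%.3f", s$per_stratum_mean), collapse = " "), "\n")
  }
  invisible(x)
}

#' Write scenario results to disk (JSON summary + TSV estimates)
#'
#' The JSON file embeds the full configuration (including the base seed)
#' and package version, so a run can be reproduced bit-exactly from the
#' file alone; the TSV holds the per-replicate stratum estimates in long
#' format.
#'
#' @param result a `scenario_result`.
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @export
write_scenario_result <- function(result, json_path = NULL,
                                  tsv_path = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  if (!is.null(json_path)) {
    payload <- list(
      package_version = as.character(utils::packageVersion("nlmrbias")),
      config = unclass(result$config),
      adjust = result$adjust,
      summaries = result$summaries)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(result$estimates, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}

#' Run a grid of scenarios over swept configuration fields
#'
#' Takes a base configuration and a named list of values to sweep (e.g.
#' `list(b_gux = c(-0.1, -0.02, 0, 0.02, 0.1))`), runs every combination in
#' the Cartesian product with an independent child seed per scenario, and
#' returns the scenario results plus a long summary table.
#'
#' @param base a [scenario_config()].
#' @param sweep named list; names must be `scenario_config` fields.
#' @param methods,adjust,u_error_r,se_order passed to [run_scenario()].
#' @return object of class `grid_result`: list with `scenarios` (data.frame
#'   of swept values), `results` (list of `scenario_result`), and `table`
#'   (long data.frame: scenario, method, stratum, mean, mc_se, mse,
#'   coverage, pooled_mse, het_rate).
#' @export
run_grid <- function(base, sweep,
                     methods = c("residual", "doubly_ranked"),
                     adjust = "none", u_error_r = 0.8, se_order = 1L) {
  stopifnot(inherits(base, "scenario_config"), is.list(sweep),
            length(sweep) >= 1L)
  bad <- setdiff(names(sweep), names(unclass(base)))
  if (length(bad)) {
    stop("swept fields not in scenario_config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE)
  message("running ", nrow(grid), " scenario(s): ",
          paste(names(sweep), collapse = " x "))
  seeds <- child_seeds(base$seed, nrow(grid))
  results <- vector("list", nrow(grid))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cfg_fields <- unclass(base)
    for (f in names(sweep)) cfg_fields[[f]] <- grid[i, f]
    cfg_fields$seed <- seeds[i]
    cfg <- do.call(scenario_config, cfg_fields)
    res <- tryCatch(
      run_scenario(cfg, methods = methods, adjust = adjust,
                   u_error_r = u_error_r, se_order = se_order),
      error = function(e) {
        message("scenario ", i, " failed: ", conditionMessage(e))
        NULL
      })
    results[[i]] <- res
    if (is.null(res)) next
    for (m in methods) {
      s <- res$summaries[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = i, grid[i, , drop = FALSE], method = m,
        stratum = seq_along(s$per_stratum_mean),
        mean = s$per_stratum_mean, mc_se = s$per_stratum_mc_se,
        mse = s$per_stratum_mse, coverage = s$coverage,
        pooled_mse = s$pooled_mse, het_rate = s$het_rate,
        row.names = NULL)
    }
  }
  structure(list(scenarios = grid, results = results,
                 table = do.call(rbind, rows)),
            class = "grid_result")
}
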