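#' Configuration for the semi-empirical falsification test
#'
#' Defaults match the study design for the falsification analysis:
#' simulated confounding with `b_ux = -1`, `b_uy = 1`, 100 replicates, 10
#' strata, and the exposure scaled to mean 0 / SD 1 before the confounder
#' is added.
#'
#' @param b_ux effect of the simulated confounder on the simulated
#'   exposure.
#' @param b_uy effect of the simulated confounder on the simulated outcome.
#' @param n_replicates Monte Carlo replicates.
#' @param S number of strata.
#' @param scale_exposure standardize the measured exposure first?
#' @param seed base integer seed.
#' @param verdict_se_mult flag bias when any stratum's absolute mean
#'   estimate exceeds this many Monte Carlo SEs.
#' @param verdict_het_bound flag bias when the heterogeneity detection rate
#'   exceeds this bound.
#' @param se_order delta-method order for Wald SEs.
#' @return a `semi_empirical_config` list.
#' @export
semi_empirical_config <- function(b_ux = -1, b_uy = 1, n_replicates = 100L,
                                  S = 10L, scale_exposure = TRUE, seed = 1L,
                                  verdict_se_mult = 3,
                                  verdict_het_bound = 0.5, se_order = 1L) {
  stopifnot(n_replicates >= 1L, S >= 2L, verdict_se_mult > 0,
            verdict_het_bound > 0)
  structure(list(b_ux = b_ux, b_uy = b_uy,
                 n_replicates = as.integer(n_replicates), S = as.integer(S),
                 scale_exposure = isTRUE(scale_exposure),
                 seed = as.integer(seed),
                 verdict_se_mult = verdict_se_mult,
                 verdict_het_bound = verdict_het_bound,
                 se_order = as.integer(se_order)),
            class = "semi_empirical_config")
}

#' Graft simulated confounding onto a measured exposure
#'
#' Builds the confounded simulated exposure and simulated outcome
#' \deqn{x_s = exposure + b_{ux} u, \qquad y_s = b_{uy} u + e_y,}
#' with `u` and `e_y` drawn Normal(2, 1) and the measured exposure
#' standardized first when `scale_exposure` is set. The simulated outcome
#' depends only on `(u, e_y)`, both independent of any instrument, so the
#' instrument remains a valid IV for the simulated pair by construction and
#' the true causal effect is exactly 0 for everyone: any stratum-level bias
#' exposes a failure of the stratification method's own assumption.
#'
#' @param exposure numeric vector (the measured exposure).
#' @param config a [semi_empirical_config()].
#' @param seed seed for this draw (defaults to `config$seed`).
#' @return list with `x_s`, `y_s`, and `u` (returned for oracle checks).
#' @export
confound_exposure_outcome <- function(exposure, config = semi_empirical_config(),
                                      seed = config$seed) {
  stopifnot(all(is.finite(exposure)))
  n <- length(exposure)
  if (n < 2L * config$S) stop("need n >= 2*S observations", call. = FALSE)
  # a constant exposure carries no scale to standardize; leave it be
  if (config$scale_exposure && stats::sd(exposure) > 0) {
    exposure <- standardize(exposure)
  }
  set.seed(as.integer(seed))
  u <- stats::rnorm(n, 2, 1)
  e_y <- stats::rnorm(n, 2, 1)
  list(x_s = exposure + config$b_ux * u,
       y_s = config$b_uy * u + e_y,
       u = u)
}

#' Falsification test for stratified MR on a measured exposure / score pair
#'
#' The recommended pre-flight check before a stratified (non-linear) MR
#' analysis: take the measured exposure and its polygenic score, replace
#' the outcome with a purely simulated one that the exposure cannot cause
#' (see [confound_exposure_outcome()]), run both stratification methods,
#' and look for non-null stratum estimates. Because the core IV assumptions
#' hold by construction and the true effect is 0, systematic stratum-level
#' deviations from 0 can only come from violations of the
#' constant-genetic-effect assumption (residual method) or the
#' rank-preserving assumption (doubly-ranked method) — for example through
#' heterogeneous genetic effects on the real exposure.
#'
#' The verdict flags "bias suspected" for a method when any stratum's
#' absolute mean estimate exceeds `verdict_se_mult` Monte Carlo SEs, or the
#' heterogeneity detection rate exceeds `verdict_het_bound`.
#'
#' @param data data.frame with columns `id`, `prs` (instrument /
#'   polygenic score) and `exposure`; missing values are rejected with row
#'   numbers.
#' @param config a [semi_empirical_config()].
#' @param methods stratification methods to run.
#' @return object of class `falsification_report`: per-method summaries
#'   (as in [scenario_summary()]), per-replicate estimates, full-sample
#'   coverage of 0, the first-stage F statistic, and per-method
#'   `bias_suspected` flags.
#' @export
falsification_test <- function(data, config = semi_empirical_config(),
                               methods = c("residual", "doubly_ranked")) {
  need <- c("id", "prs", "exposure")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("input table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!stats::complete.cases(data[, need]))
  if (length(bad)) {
    stop("missing values in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  methods <- match.arg(methods, c("residual", "doubly_ranked"),
                       several.ok = TRUE)
  exposure <- if (config$scale_exposure) standardize(data$exposure) else
    data$exposure
  first_stage <- ols_beta(exposure, data$prs)
  f_full <- (first_stage$beta / first_stage$se)^2
  if (f_full < 10) {
    warning("full-sample instrument F = ", round(f_full, 2),
            " < 10: the falsification test is uninformative with a weak ",
            "instrument", call. = FALSE)
  }
  R <- config$n_replicates
  seeds <- child_seeds(config$seed, R)
  est_rows <- list()
  q_rows <- list()
  for (r in seq_len(R)) {
    sim <- confound_exposure_outcome(data$exposure, config, seed = seeds[r])
    cohort <- new_cohort(data.frame(id = data$id, g = data$prs,
                                    x = sim$x_s, y = sim$y_s))
    for (m in methods) {
      asg <- if (m == "residual") {
        stratify_residual(cohort, config$S)
      } else {
        stratify_doubly_ranked(cohort, config$S)
      }
      est <- estimate_strata(cohort, asg, se_order = config$se_order)
      est$method <- m
      est$replicate <- r
      strata <- est[est$stratum > 0L, ]
      qq <- cochran_q(strata$wald, strata$se_wald)
      est_rows[[length(est_rows) + 1L]] <- est
      q_rows[[length(q_rows) + 1L]] <- data.frame(method = m, replicate = r,
                                                  Q = qq$Q, p = qq$p)
    }
  }
  estimates <- do.call(rbind, est_rows)
  q <- do.call(rbind, q_rows)
  summaries <- lapply(stats::setNames(methods, methods), function(m) {
    s <- summarize_method(estimates[estimates$method == m, ],
                          q[q$method == m, ],
                          list(n_strata = config$S))
    s$bias_suspected <-
      any(abs(s$per_stratum_mean) >
            config$verdict_se_mult * s$per_stratum_mc_se) ||
      s$het_rate > config$verdict_het_bound
    s
  })
  structure(list(config = config, methods = methods,
                 estimates = estimates, q = q, summaries = summaries,
                 first_stage_f = f_full,
                 bias_suspected = vapply(summaries, `[[`, logical(1),
                                         "bias_suspected")),
            class = "falsification_report")
}

#' @export
print.falsification_report <- function(x, ...) {
  cat("<falsification_report>",
      sprintf("(replicates = %d, strata = %d, b_ux = %g, b_uy = %g)\n",
              x$config$n_replicates, x$config$S, x$config$b_ux,
              x$config$b_uy))
  cat(sprintf("  first-stage F: %.1f\n", x$first_stage_f))
  for (m in x$methods) {
    s <- x$summaries[[m]]
    cat(sprintf("  %s: het rate %.2f, bias suspected: %s\n", m, s$het_rate,
                if (s$bias_suspected) "YES" else "no"))
    cat("    stratum means:",
        paste(sprintf("%.3f", s$per_stratum_mean), collapse = " "), "\n")
  }
  cat(sprintf("  full-sample coverage of 0: %.2f (%s)\n",
              x$summaries[[1L]]$full_sample$coverage, x$methods[1L]))
  invisible(x)
}

#' Boxplots of per-replicate stratum estimates from a falsification test
#'
#' @param x a `falsification_report`.
#' @param method which method to plot.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.falsification_report <- function(x, method = x$methods[1L], ...) {
  est <- x$estimates
  est <- est[est$method == method & est$stratum > 0L, ]
  graphics::boxplot(wald ~ stratum, data = est,
                    xlab = "stratum", ylab = "MR estimate",
                    main = paste("falsification test,", method), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Write a falsification report (JSON verdict + TSV estimates)
#'
#' @param report a `falsification_report`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @export
write_falsification_report <- function(report, json_path = NULL,
                                       tsv_path = NULL) {
  stopifnot(inherits(report, "falsification_report"))
  if (!is.null(json_path)) {
    payload <- list(
      package_version = as.character(utils::packageVersion("nlmrbias")),
      config = unclass(report$config),
      first_stage_f = report$first_stage_f,
      bias_suspected = as.list(report$bias_suspected),
      summaries = report$summaries)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(report$estimates, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Instrument-by-modifier interaction test on the exposure
#'
#' Tests whether the instrument-exposure association differs across levels
#' of a candidate effect modifier (e.g. an illness score): OLS of the
#' exposure on the standardized instrument, the standardized modifier, and
#' their product. A non-zero product coefficient is direct evidence of
#' genetic effect heterogeneity — the condition under which stratified MR
#' estimates become vulnerable to bias.
#'
#' @param exposure,prs,modifier aligned numeric vectors; `prs` and
#'   `modifier` are standardized internally.
#' @return list with `beta`, `se` and two-sided `p` for the product term.
#' @export
interaction_test <- function(exposure, prs, modifier) {
  n <- length(exposure)
  stopifnot(length(prs) == n, length(modifier) == n)
  d <- data.frame(exposure = exposure, prs = standardize(prs),
                  modifier = standardize(modifier))
  fit <- stats::lm(exposure ~ prs * modifier, data = d)
  if (anyNA(stats::coef(fit))) {
    stop("singular design: modifier collinear with the instrument",
         call. = FALSE)
  }
  cf <- summary(fit)$coefficients["prs:modifier", ]
  list(beta = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
       p = unname(cf["Pr(>|t|)"]))
}

#' Illness summary score and median-rank illness score
#'
#' Two generic constructions of an "ill-health" proxy from continuous
#' health markers and diagnosis flags:
#'
#' * **Summary score** — one point per marker in `high_bad` whose value lies
#'   strictly above its 80th percentile, one point per marker in `low_bad`
#'   strictly below its 20th percentile, and one point per `TRUE` condition
#'   flag.
#' * **Median-rank score** — each marker is ranked in its "illness
#'   direction" (`high_bad` ascending, so the highest value has the highest
#'   rank; `low_bad` descending, so the lowest value has the highest rank);
#'   each participant's score is the median of their marker ranks,
#'   standardized to mean 0 / SD 1.
#'
#' @param table data.frame with an `id` column, numeric marker columns and
#'   logical condition columns.
#' @param high_bad,low_bad names of marker columns where high (resp. low)
#'   values indicate illness.
#' @param conditions names of logical condition columns; defaults to every
#'   logical column of `table`.
#' @param probs the two quantile thresholds (low, high).
#' @return list with integer `summary_score` and numeric
#'   `median_rank_score`, both aligned to the rows of `table`.
#' @export
illness_scores <- function(table, high_bad = character(),
                           low_bad = character(), conditions = NULL,
                           probs = c(0.2, 0.8)) {
  markers <- c(high_bad, low_bad)
  if (length(markers) == 0L) stop("no marker columns named", call. = FALSE)
  missing_cols <- setdiff(markers, names(table))
  if (length(missing_cols)) {
    stop("marker columns absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- names(table)[vapply(table, is.logical, logical(1))]
  }
  n <- nrow(table)
  score <- integer(n)
  for (mk in high_bad) {
    thr <- stats::quantile(table[[mk]], probs[2L], na.rm = TRUE, names = FALSE)
    score <- score + as.integer(table[[mk]] > thr)
  }
  for (mk in low_bad) {
    thr <- stats::quantile(table[[mk]], probs[1L], na.rm = TRUE, names = FALSE)
    score <- score + as.integer(table[[mk]] < thr)
  }
  for (cn in conditions) {
    score <- score + as.integer(isTRUE_vec(table[[cn]]))
  }
  rank_mat <- vapply(markers, function(mk) {
    v <- table[[mk]]
    if (mk %in% low_bad) v <- -v
    rank(v, ties.method = "average")
  }, numeric(n))
  med <- apply(rank_mat, 1L, stats::median)
  # degenerate all-tied markers leave no ranking information: score is 0
  mrs <- if (stats::sd(med) > 0) standardize(med) else med - mean(med)
  list(summary_score = score, median_rank_score = mrs)
}

isTRUE_vec <- function(v) !is.na(v) & as.logical(v)
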