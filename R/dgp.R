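#' Generate a simulation cohort (models A and B)
#'
#' Draws `g`, `u`, `v`, `e_x`, `e_y` mutually independent Normal(`mu`,
#' `sigma`) (`g` with SD `sigma_g`) and builds the exposure and outcome from
#' the scenario's structural equations:
#' \deqn{x = \beta_g g + b_{ux} u + b_{gux} g u + b_{vx} v + e_x}
#' \deqn{y = b_{uy} u + b_{vy} v + e_y}
#' The exposure has no causal effect on the outcome anywhere in this design:
#' any exposure-outcome association flows through `u` and `v` alone, so the
#' true stratum-specific causal effect is 0 throughout.
#'
#' The column `v` is only materialised when the model uses it
#' (`b_vx != 0` or `b_vy != 0`).
#'
#' @param config a [scenario_config()].
#' @param seed seed for this cohort; defaults to `config$seed`. Replicate
#'   loops pass child seeds (see [child_seeds()]).
#' @return an [nlmr_cohort].
#' @examples
#' cfg <- scenario_config(n = 500, seed = 7, b_ux = 0.3, b_gux = -0.1,
#'                        b_uy = 0.3)
#' co <- generate_cohort(cfg)
#' head(co)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  n <- config$n
  set.seed(as.integer(seed))
  g <- stats::rnorm(n, config$mu, config$sigma_g)
  u <- stats::rnorm(n, config$mu, config$sigma)
  use_v <- config$b_vx != 0 || config$b_vy != 0
  v <- if (use_v) stats::rnorm(n, config$mu, config$sigma) else NULL
  e_x <- stats::rnorm(n, config$mu, config$sigma)
  e_y <- stats::rnorm(n, config$mu, config$sigma)
  v0 <- if (use_v) v else 0
  x <- config$beta_g * g + config$b_ux * u + config$b_gux * g * u +
    config$b_vx * v0 + e_x
  y <- config$b_uy * u + config$b_vy * v0 + e_y
  df <- data.frame(id = seq_len(n), g = g, u = u)
  if (use_v) df$v <- v
  df$e_x <- e_x
  df$e_y <- e_y
  df$x <- x
  df$y <- y
  new_cohort(df, config = c(unclass(config), list(cohort_seed = seed)))
}

#' Table of genotype-exposure models M1-M13
#'
#' The catalogue of exposure-generating models used by the rank-preservation
#' diagnostics. All use `g`, `u` and the error term drawn Normal(0, 1)
#' except M10, where `g` has SD 0.25. M11-M13 draw a per-individual genetic
#' effect `alpha` conditional on the error term and/or `u`.
#'
#' @format A data.frame with columns `model_id` and `description`.
#' @export
model_catalogue <- function() {
  data.frame(
    model_id = paste0("M", 1:13),
    description = c(
      "x = 0.3 g + u + e (linear)",
      "x = 0.3 g + 0.1 u + e (reduced u effect)",
      "x = 0.3 g + u + 0.1 g u + e (small GxU)",
      "x = 0.3 g + u + 0.2 g u + e (large GxU)",
      "x = 0.3 g + 0.1 g u + e (GxU without u main effect)",
      "x = 0.3 g + u - 0.2 g u + e (negative GxU)",
      "x = 0.3 g + 0.1 u + 0.5 g u + e (large GxU, small u)",
      "x = 0.3 g + u + 0.05 g u + e (very small GxU)",
      "x = 0.3 g + 0.1 g^2 + u + e (quadratic g)",
      "x = -10 + (1.5 + 0.4 u)(g + 5) + u + e (sd(g) = 0.25)",
      "x = alpha g + u + e, alpha ~ N(0.3 + 0.1 e, 0.1^2)",
      "x = alpha g + u + e, alpha ~ N(0.3 + 0.1/sqrt(2) (e + u), 0.1^2)",
      "x = alpha g + u + e, alpha ~ N(0.3 + 0.1 u, 0.1^2)"
    ),
    stringsAsFactors = FALSE
  )
}

model_ids <- function() paste0("M", 1:13)

#' Evaluate a catalogue model's exposure formula on stored components
#'
#' Pure formula evaluation: given the individual components (`g`, `u`, error
#' `eps`, and `alpha` for M11-M13), returns the exposure. Used both by
#' [generate_model_cohort()] and by [counterfactual_exposures()], which
#' re-evaluates the formula with `g` replaced by fixed counterfactual levels
#' while every other component is held at its stored value.
#'
#' @param model_id one of `"M1"`..`"M13"`.
#' @param g,u,eps numeric vectors of equal length.
#' @param alpha per-individual genetic effect; required for M11-M13.
#' @return numeric vector of exposures.
#' @export
model_exposure <- function(model_id, g, u, eps, alpha = NULL) {
  if (!model_id %in% model_ids()) {
    stop("unknown model_id '", model_id, "'; valid ids: ",
         paste(model_ids(), collapse = ", "), call. = FALSE)
  }
  switch(model_id,
    M1 = 0.3 * g + u + eps,
    M2 = 0.3 * g + 0.1 * u + eps,
    M3 = 0.3 * g + u + 0.1 * g * u + eps,
    M4 = 0.3 * g + u + 0.2 * g * u + eps,
    M5 = 0.3 * g + 0.1 * g * u + eps,
    M6 = 0.3 * g + u - 0.2 * g * u + eps,
    M7 = 0.3 * g + 0.1 * u + 0.5 * g * u + eps,
    M8 = 0.3 * g + u + 0.05 * g * u + eps,
    M9 = 0.3 * g + 0.1 * g^2 + u + eps,
    M10 = -10 + (1.5 + 0.4 * u) * (g + 5) + u + eps,
    M11 = ,
    M12 = ,
    M13 = {
      if (is.null(alpha)) {
        stop("model ", model_id, " requires the stored per-individual ",
             "genetic effect 'alpha'", call. = FALSE)
      }
      alpha * g + u + eps
    }
  )
}

# SD of g under each catalogue model (0.25 for M10, 1 otherwise).
model_sigma_g <- function(model_id) if (model_id == "M10") 0.25 else 1

#' Generate a cohort under one of the catalogue models M1-M13
#'
#' `g`, `u` and the error term are drawn Normal(0, 1), except that `g` has
#' SD 0.25 under M10. For M11-M13 the error (and `u`) are drawn first, then
#' the per-individual genetic effect `alpha` from its conditional normal,
#' then `x = alpha*g + u + eps`; `alpha` is stored on the cohort as a fixed
#' individual attribute. No outcome is generated (`y` is not part of the
#' catalogue models).
#'
#' @param model_id one of `"M1"`..`"M13"`.
#' @param n cohort size (>= 2).
#' @param seed integer seed.
#' @param components optional list with entries `g`, `u`, `eps` (and `alpha`
#'   for M11-M13) to inject fixed component values instead of drawing them;
#'   intended for formula-level checks.
#' @return an [nlmr_cohort] with columns `id, g, u, e_x, x` (plus `alpha`).
#' @examples
#' co <- generate_model_cohort("M4", n = 1000, seed = 1)
#' head(co)
#' @export
generate_model_cohort <- function(model_id, n, seed = 1L, components = NULL) {
  if (!model_id %in% model_ids()) {
    stop("unknown model_id '", model_id, "'; valid ids: ",
         paste(model_ids(), collapse = ", "), call. = FALSE)
  }
  stopifnot(n >= 2L)
  sigma_g <- model_sigma_g(model_id)
  if (is.null(components)) {
    set.seed(as.integer(seed))
    g <- stats::rnorm(n, 0, sigma_g)
    u <- stats::rnorm(n, 0, 1)
    eps <- stats::rnorm(n, 0, 1)
    alpha <- switch(model_id,
      M11 = stats::rnorm(n, 0.3 + 0.1 * eps, 0.1),
      M12 = stats::rnorm(n, 0.3 + 0.1 / sqrt(2) * (eps + u), 0.1),
      M13 = stats::rnorm(n, 0.3 + 0.1 * u, 0.1),
      NULL)
  } else {
    g <- components$g
    u <- components$u
    eps <- components$eps
    alpha <- components$alpha
    n <- length(g)
    stopifnot(length(u) == n, length(eps) == n)
  }
  x <- model_exposure(model_id, g, u, eps, alpha)
  df <- data.frame(id = seq_len(n), g = g, u = u, e_x = eps, x = x)
  if (!is.null(alpha)) df$alpha <- alpha
  new_cohort(df, config = list(model_id = model_id, n = n, seed = seed,
                               mu = 0, sigma = 1, sigma_g = sigma_g))
}

#' Error-prone measurement of a confounder
#'
#' Builds `u_error = a*u + b*z` with `z` independent standard normal, with
#' `a`, `b` chosen so that the population correlation with `u` equals
#' `target_correlation` and `Var(u_error) = Var(u)`: `a = r * sd(u) / sd(u)`
#' reduces to `a = r`, `b = sd(u) * sqrt(1 - r^2)`. Used for the
#' incomplete-adjustment experiment, where stratum regressions adjust for a
#' mismeasured confounder instead of the true one.
#'
#' @param u numeric confounder vector (non-constant).
#' @param target_correlation desired Pearson correlation in (0, 1].
#' @param seed integer seed for the independent noise.
#' @return numeric vector, same length as `u`.
#' @export
generate_error_prone_confounder <- function(u, target_correlation, seed = 1L) {
  if (stats::sd(u) == 0 || !is.finite(stats::sd(u))) {
    stop("'u' is constant: correlation with a measurement of it is undefined",
         call. = FALSE)
  }
  r <- target_correlation
  if (!(r > 0 && r <= 1)) {
    stop("'target_correlation' must lie in (0, 1]", call. = FALSE)
  }
  if (r == 1) return(u)
  set.seed(as.integer(seed))
  z <- stats::rnorm(length(u))
  r * u + stats::sd(u) * sqrt(1 - r^2) * z
}

#' Stand-in empirical cohort for the falsification test
#'
#' Emulates the shape of a biobank-style (polygenic score, exposure) pair so
#' the falsification test can be exercised without individual-level human
#' data: `n_variants` biallelic dosages (each Binomial(2, f), allele
#' frequency f drawn uniformly in `freq_range`) are combined with weights
#' drawn once per call into a weighted score `g`; a latent illness-like
#' modifier `m ~ Normal(0, 1)` scales the genetic effect, giving the raw
#' exposure
#' \deqn{x_{raw} = (\beta_g + h \, m)\, g_{std} + m + e_x,}
#' where `h` is the `heterogeneity` argument and `g_std` the standardized
#' score. With `skew = TRUE` the raw exposure is exponentiated (a crude
#' right-skew mechanism) before the final scaling. Both `g` and `x` are
#' returned scaled to mean 0 / SD 1, matching how exposures are prepared for
#' the falsification analysis; the pre-scaling SD of the exposure is stored
#' as attribute `"x_scale"` (coefficients on the analysis scale are the raw
#' coefficients divided by it).
#'
#' This generator is study plumbing, not an empirical claim: allele
#' frequencies, weights and the skew mechanism are conventional choices.
#'
#' @param n cohort size.
#' @param n_variants number of biallelic variants in the score (>= 1).
#' @param heterogeneity modifier-by-score interaction strength `h` (0 =
#'   homogeneous genetic effect).
#' @param skew exponentiate the exposure before scaling?
#' @param seed integer seed.
#' @param beta_g genetic main effect on the raw exposure scale.
#' @param freq_range allele-frequency range for the variants.
#' @return an [nlmr_cohort] with columns `id, g, x` and modifier column `m`.
#' @export
generate_empirical_standin <- function(n, n_variants = 50L,
                                       heterogeneity = 0, skew = FALSE,
                                       seed = 1L, beta_g = 0.3,
                                       freq_range = c(0.05, 0.95)) {
  stopifnot(n >= 2L, n_variants >= 1L)
  set.seed(as.integer(seed))
  freqs <- stats::runif(n_variants, freq_range[1], freq_range[2])
  weights <- stats::runif(n_variants)
  dosages <- vapply(freqs, function(f) stats::rbinom(n, 2L, f),
                    numeric(n))
  g <- as.numeric(dosages %*% weights)
  g_std <- standardize(g)
  m <- stats::rnorm(n)
  e_x <- stats::rnorm(n)
  x_raw <- (beta_g + heterogeneity * m) * g_std + m + e_x
  if (isTRUE(skew)) x_raw <- exp(standardize(x_raw))
  x_scale <- stats::sd(x_raw)
  df <- data.frame(id = seq_len(n), g = standardize(g),
                   x = standardize(x_raw), m = m)
  co <- new_cohort(df,
                   config = list(model_id = "empirical_standin", n = n,
                                 n_variants = n_variants,
                                 heterogeneity = heterogeneity,
                                 skew = isTRUE(skew), seed = seed,
                                 beta_g = beta_g),
                   modifiers = "m")
  attr(co, "x_scale") <- x_scale
  co
}
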