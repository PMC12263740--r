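#' Scenario configuration for the Monte Carlo simulations
#'
#' Bundles every parameter of one simulation scenario: cohort size, replicate
#' count, strata count, the structural coefficients of the exposure and
#' outcome models, the distributional settings of the latent variables, and
#' the base random seed. Two scenario families are supported:
#'
#' * `model_id = "A"`: a single modifier/confounder `u`, with
#'   `x = beta_g*g + b_ux*u + b_gux*g*u + e_x` and `y = b_uy*u + e_y`.
#'   Genetic effect heterogeneity is present whenever `b_gux != 0`.
#' * `model_id = "B"`: adds a second latent variable `v` that confounds the
#'   exposure-outcome relationship but does not modify the genetic effect:
#'   `x = beta_g*g + b_ux*u + b_gux*g*u + b_vx*v + e_x` and
#'   `y = b_uy*u + b_vy*v + e_y`.
#'
#' All latent variables (`g`, `u`, `v`, `e_x`, `e_y`) are drawn mutually
#' independent Normal with mean `mu` and SD `sigma` (`g` with `sigma_g`).
#' The main simulations use `mu = 2`; rank-preservation work uses `mu = 0`.
#'
#' @param n cohort size (must allow at least 2 members per stratum).
#' @param seed base integer seed for the scenario; replicate r uses the r-th
#'   child seed from [child_seeds()].
#' @param n_replicates number of Monte Carlo replicates.
#' @param n_strata number of strata for the stratified estimators.
#' @param beta_g fixed genotype-exposure effect (0.3 in all study scenarios).
#' @param b_ux,b_gux,b_uy coefficients of `u` on `x`, of the `g*u` interaction
#'   on `x`, and of `u` on `y`.
#' @param b_vx,b_vy coefficients of `v` on `x` and `y` (model B only).
#' @param b_v convenience shorthand: sets `b_vx = b_vy = b_v`.
#' @param mu common mean of `g`, `u`, `v` and the error terms.
#' @param sigma common SD of `u`, `v` and the error terms (> 0).
#' @param sigma_g SD of `g`; defaults to `sigma`.
#' @param model_id `"A"` or `"B"`.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @seealso [generate_cohort()], [run_scenario()]
#' @examples
#' cfg <- scenario_config(n = 1000, seed = 1, b_ux = 0.3, b_gux = -0.1,
#'                        b_uy = 0.3)
#' cfg
#' @export
scenario_config <- function(n,
                            seed,
                            n_replicates = 100L,
                            n_strata = 10L,
                            beta_g = 0.3,
                            b_ux = 0,
                            b_gux = 0,
                            b_uy = 0,
                            b_vx = 0,
                            b_vy = 0,
                            b_v = NULL,
                            mu = 2,
                            sigma = 1,
                            sigma_g = sigma,
                            model_id = c("A", "B")) {
  model_id <- match.arg(model_id)
  if (!is.null(b_v)) {
    b_vx <- b_v
    b_vy <- b_v
  }
  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed),
         n_replicates = as.integer(n_replicates),
         n_strata = as.integer(n_strata),
         beta_g = beta_g, b_ux = b_ux, b_gux = b_gux, b_uy = b_uy,
         b_vx = b_vx, b_vy = b_vy,
         mu = mu, sigma = sigma, sigma_g = sigma_g,
         model_id = model_id),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("scenario_config: field '", field,
           "' must be a single finite number", call. = FALSE)
    }
  }
  for (f in c("n", "seed", "n_replicates", "n_strata", "beta_g", "b_ux",
              "b_gux", "b_uy", "b_vx", "b_vy", "mu", "sigma", "sigma_g")) {
    num1(f)
  }
  if (cfg$n < 2L) stop("scenario_config: field 'n' must be >= 2", call. = FALSE)
  if (cfg$n_replicates < 1L) {
    stop("scenario_config: field 'n_replicates' must be >= 1", call. = FALSE)
  }
  if (cfg$n_strata < 1L) {
    stop("scenario_config: field 'n_strata' must be >= 1", call. = FALSE)
  }
  if (cfg$n < 2L * cfg$n_strata) {
    stop("scenario_config: field 'n' must be >= 2 * n_strata (n = ", cfg$n,
         ", n_strata = ", cfg$n_strata, ")", call. = FALSE)
  }
  if (cfg$sigma <= 0) {
    stop("scenario_config: field 'sigma' must be > 0", call. = FALSE)
  }
  if (cfg$sigma_g <= 0) {
    stop("scenario_config: field 'sigma_g' must be > 0", call. = FALSE)
  }
  # model A has no v pathway: non-zero v coefficients would silently change
  # the generating model, so reject them at construction
  if (cfg$model_id == "A" && (cfg$b_vx != 0 || cfg$b_vy != 0)) {
    stop("scenario_config: fields 'b_vx'/'b_vy' must be 0 under model_id ",
         "\"A\" (use model_id = \"B\" for the two-confounder design)",
         call. = FALSE)
  }
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> model", x$model_id,
      sprintf("(n = %d, replicates = %d, strata = %d, seed = %d)\n",
              x$n, x$n_replicates, x$n_strata, x$seed))
  cat(sprintf("  x = %.3g g %+.3g u %+.3g g*u %+.3g v + e_x\n",
              x$beta_g, x$b_ux, x$b_gux, x$b_vx))
  cat(sprintf("  y = %+.3g u %+.3g v + e_y\n", x$b_uy, x$b_vy))
  cat(sprintf("  g, u, v, e ~ Normal(mu = %.3g, sd = %.3g); sd(g) = %.3g\n",
              x$mu, x$sigma, x$sigma_g))
  invisible(x)
}

#' Deterministic child seeds for replicate streams
#'
#' One base seed per scenario; replicate r uses the r-th entry of the child
#' seed vector, drawn without replacement from the 31-bit integer range under
#' `set.seed(seed)`. Replicates are therefore mutually independent streams
#' and any single replicate can be reconstructed from `(seed, r)` alone.
#'
#' @param seed base integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1L)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' Write / read a scenario configuration as YAML
#'
#' @param cfg a `scenario_config`.
#' @param path file path.
#' @return `config_to_yaml` returns `path` invisibly; `config_from_yaml`
#'   returns a validated `scenario_config`.
#' @export
config_to_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(scenario_config, x)
}
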