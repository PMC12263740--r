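test_that("with all coefficients zero the exposure is genotype plus noise", {
  cfg <- scenario_config(n = 2000, seed = 11, n_strata = 2, mu = 0)
  co <- generate_cohort(cfg)
  expect_equal(co$x, 0.3 * co$g + co$e_x)
  expect_equal(co$y, co$e_y)
  expect_false("v" %in% names(co))
  # u enters nowhere: sample correlation is pure noise
  expect_lt(abs(cor(co$x, co$u)), 4 / sqrt(nrow(co)))
})

test_that("sample mean of x matches the analytic expectation", {
  # E[x] = 0.3*2 + 0.3*2 - 0.1*E[g*u] + 2 with E[g*u] = 4 by independence
  cfg <- scenario_config(n = 200000, seed = 12, b_ux = 0.3, b_gux = -0.1,
                         b_uy = 0.3, mu = 2)
  co <- generate_cohort(cfg)
  se <- sd(co$x) / sqrt(nrow(co))
  expect_lt(abs(mean(co$x) - 2.8), 4 * se)
})

test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- scenario_config(n = 1000, seed = 13, b_ux = 0.3, b_gux = -0.1,
                         b_uy = 0.3, b_v = 1, model_id = "B")
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("x and y are recomputable exactly from stored components", {
  cfg <- scenario_config(n = 5000, seed = 14, b_ux = -0.3, b_gux = -0.1,
                         b_uy = 0, b_v = 1, model_id = "B")
  co <- generate_cohort(cfg)
  c2 <- attr(co, "config")
  expect_identical(co$x, c2$beta_g * co$g + c2$b_ux * co$u +
                     c2$b_gux * co$g * co$u + c2$b_vx * co$v + co$e_x)
  expect_identical(co$y, c2$b_uy * co$u + c2$b_vy * co$v + co$e_y)
  # model A (no v): same property
  cfgA <- scenario_config(n = 1000, seed = 14, b_ux = 0.3, b_gux = -0.1,
                          b_uy = 0.3)
  coA <- generate_cohort(cfgA)
  expect_identical(coA$x, 0.3 * coA$g + 0.3 * coA$u -
                     0.1 * coA$g * coA$u + 0 * 0 + coA$e_x)
})

test_that("latent variables are calibrated to their configured moments", {
  cfg <- scenario_config(n = 100000, seed = 15, b_ux = 0.3, b_uy = 0.3,
                         mu = 2, sigma = 1)
  co <- generate_cohort(cfg)
  se_mean <- 1 / sqrt(nrow(co))
  for (v in c("g", "u", "e_x", "e_y")) {
    expect_lt(abs(mean(co[[v]]) - 2), 5 * se_mean)
    expect_lt(abs(sd(co[[v]]) - 1), 5 * se_mean)
  }
})

test_that("catalogue formulas evaluate exactly on injected components", {
  comp <- list(g = c(1, 0, -1), u = c(0, 0, 0), eps = c(0, 0, 0))
  co <- generate_model_cohort("M1", n = 3, components = comp)
  expect_equal(co$x, c(0.3, 0, -0.3))
  co4 <- generate_model_cohort("M4", n = 3,
                               components = modifyList(comp,
                                                       list(u = c(1, 1, 1))))
  expect_equal(co4$x, 0.3 * comp$g + 1 + 0.2 * comp$g)
  co10 <- generate_model_cohort("M10", n = 3, components = comp)
  expect_equal(co10$x, -10 + 1.5 * (comp$g + 5))
  expect_error(generate_model_cohort("M99", n = 10), "M1")
})

test_that("M10 draws the instrument with SD 0.25", {
  co <- generate_model_cohort("M10", n = 50000, seed = 16)
  expect_lt(abs(sd(co$g) - 0.25), 5 * 0.25 / sqrt(2 * nrow(co)))
})

test_that("per-individual effects in M11-M13 have the stated structure", {
  # alpha = 0.3 + 0.1*target + N(0, 0.1): cor with target = 0.1/sqrt(0.02)
  target_cor <- 0.1 / sqrt(0.1^2 + 0.1^2)
  n <- 50000
  tol <- 5 / sqrt(n)
  co11 <- generate_model_cohort("M11", n = n, seed = 17)
  expect_lt(abs(cor(co11$alpha, co11$e_x) - target_cor), tol)
  co12 <- generate_model_cohort("M12", n = n, seed = 18)
  expect_lt(abs(cor(co12$alpha, (co12$e_x + co12$u) / sqrt(2)) - target_cor),
            tol)
  co13 <- generate_model_cohort("M13", n = n, seed = 19)
  expect_lt(abs(cor(co13$alpha, co13$u) - target_cor), tol)
  for (co in list(co11, co12, co13)) {
    expect_lt(abs(mean(co$alpha) - 0.3), 5 * sd(co$alpha) / sqrt(n))
    expect_identical(co$x, co$alpha * co$g + co$u + co$e_x)
  }
})

test_that("error-prone confounder hits the target correlation and variance", {
  set.seed(20)
  u <- rnorm(100000, 2, 1)
  expect_identical(generate_error_prone_confounder(u, 1), u)
  ue <- generate_error_prone_confounder(u, 0.8, seed = 21)
  expect_lt(abs(cor(u, ue) - 0.8), 5 / sqrt(length(u)))
  expect_lt(abs(var(ue) - var(u)), 5 * var(u) * sqrt(2 / length(u)))
  expect_error(generate_error_prone_confounder(rep(1, 10), 0.8), "constant")
  expect_error(generate_error_prone_confounder(u, 0), "target_correlation")
})

test_that("stand-in empirical cohort is scaled and recovers its own truth", {
  st <- generate_empirical_standin(50000, n_variants = 30,
                                   heterogeneity = 0.2, seed = 22)
  expect_equal(mean(st$x), 0, tolerance = 1e-10)
  expect_equal(sd(st$x), 1, tolerance = 1e-10)
  expect_equal(mean(st$g), 0, tolerance = 1e-10)
  expect_equal(sd(st$g), 1, tolerance = 1e-10)
  # coefficients live on the scaled-exposure scale: raw truth / sd(x_raw)
  scale <- attr(st, "x_scale")
  fit <- ols_beta(st$x, st$g)
  expect_lt(abs(fit$beta - 0.3 / scale), 4 * fit$se)
  it <- interaction_test(st$x, st$g, st$m)
  expect_lt(abs(it$beta - 0.2 / scale), 4 * it$se)
  # homogeneous case: no interaction
  st0 <- generate_empirical_standin(50000, heterogeneity = 0, seed = 23)
  it0 <- interaction_test(st0$x, st0$g, st0$m)
  expect_lt(abs(it0$beta), 4 * it0$se)
  # determinism
  expect_identical(st$x, generate_empirical_standin(50000, n_variants = 30,
                                                    heterogeneity = 0.2,
                                                    seed = 22)$x)
  # skewed variant remains scaled
  sk <- generate_empirical_standin(10000, skew = TRUE, seed = 24)
  expect_equal(sd(sk$x), 1, tolerance = 1e-10)
  expect_gt(moments_skew(sk$x), 0.5)
})

test_that("cohorts round-trip through TSV", {
  cfg <- scenario_config(n = 100, seed = 25, n_strata = 2, b_ux = 0.3,
                         b_uy = 0.3)
  co <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(names(back), names(co))
  for (col in names(co)) {
    expect_equal(back[[col]], co[[col]], tolerance = 1e-12)
  }
})
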