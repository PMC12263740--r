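test_that("confounded exposure/outcome have the analytic structure", {
  cfg <- semi_empirical_config(seed = 81)
  # degenerate zero exposure: x_s = -u, y_s = u + e_y, cor = -1/sqrt(2)
  sim <- confound_exposure_outcome(rep(0, 50000), cfg)
  expect_equal(sim$x_s, -sim$u)
  expect_lt(abs(cor(sim$x_s, sim$y_s) + 1 / sqrt(2)), 5 / sqrt(50000))
  # no confounding: x_s is the standardized exposure, y_s pure noise
  set.seed(82)
  expo <- rnorm(5000, 10, 3)
  cfg0 <- semi_empirical_config(b_ux = 0, b_uy = 0, seed = 83)
  sim0 <- confound_exposure_outcome(expo, cfg0)
  expect_equal(sim0$x_s, as.numeric(scale(expo)))
  expect_lt(abs(cor(sim0$x_s, sim0$y_s)), 5 / sqrt(5000))
  # u and e_y are Normal(2, 1)
  expect_lt(abs(mean(sim$u) - 2), 5 / sqrt(50000))
  expect_lt(abs(sd(sim$u) - 1), 5 / sqrt(50000))
})

test_that("the simulated outcome is independent of the instrument", {
  st <- generate_empirical_standin(5000, heterogeneity = 0.2, seed = 84)
  cfg <- semi_empirical_config(n_replicates = 10, seed = 85)
  seeds <- child_seeds(cfg$seed, 10)
  for (s in seeds) {
    sim <- confound_exposure_outcome(st$x, cfg, seed = s)
    expect_lt(abs(cor(st$g, sim$y_s)), 5 / sqrt(5000))
  }
})

test_that("interaction test recovers nulls, truths and rejects collinearity", {
  set.seed(86)
  n <- 20000
  prs <- rnorm(n)
  mod <- rnorm(n)
  x_null <- 0.3 * prs + 0.5 * mod + rnorm(n)
  it0 <- interaction_test(x_null, prs, mod)
  expect_lt(abs(it0$beta), 4 * it0$se)
  expect_gt(it0$p, 0.001)
  x_int <- 0.3 * prs + 0.5 * mod + 0.2 * prs * mod + rnorm(n)
  it <- interaction_test(x_int, prs, mod)
  expect_lt(abs(it$beta - 0.2), 4 * it$se)
  expect_lt(it$p, 1e-10)
  expect_error(interaction_test(x_int, prs, prs), "singular|collinear")
})

test_that("illness scores follow the quantile and rank rules", {
  tab <- data.frame(id = 1:5,
                    crp = c(1, 2, 3, 4, 5),
                    albumin = c(5, 4, 3, 2, 1),
                    dementia = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # crp 80th pct = 4.2 (only 5 exceeds); condition adds a point for id 3
  got <- illness_scores(tab, high_bad = "crp")
  expect_equal(got$summary_score, c(0L, 0L, 1L, 0L, 1L))
  # albumin low_bad: 20th pct = 1.8, only value 1 (id 5) is below
  got2 <- illness_scores(tab, high_bad = "crp", low_bad = "albumin")
  expect_equal(got2$summary_score, c(0L, 0L, 1L, 0L, 2L))
  # constant markers never exceed their quantiles: conditions only
  tabc <- data.frame(id = 1:4, crp = rep(1, 4),
                     cancer = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(illness_scores(tabc, high_bad = "crp")$summary_score,
               c(1L, 0L, 0L, 1L))
  # median-rank score: both markers rank id5 most ill; standardized output
  mr <- got2$median_rank_score
  expect_equal(mean(mr), 0, tolerance = 1e-12)
  expect_equal(sd(mr), 1, tolerance = 1e-12)
  expect_equal(which.max(mr), 5L)
  expect_error(illness_scores(tab), "marker")
})

test_that("falsification test validates input and stays calibrated", {
  st <- generate_empirical_standin(4000, heterogeneity = 0, seed = 87)
  d <- data.frame(id = st$id, prs = st$g, exposure = st$x)
  bad <- d
  bad$exposure[c(5, 9)] <- NA
  expect_error(falsification_test(bad), "rows: 5, 9")
  expect_error(falsification_test(d[, 1:2]), "exposure")
  cfg <- semi_empirical_config(n_replicates = 8, seed = 88)
  rep0 <- falsification_test(d, cfg)
  expect_s3_class(rep0, "falsification_report")
  expect_gt(rep0$first_stage_f, 10)
  # homogeneous genetic effect: full-sample estimates cover 0
  expect_gte(rep0$summaries$doubly_ranked$full_sample$coverage, 0.5)
  # determinism
  rep1 <- falsification_test(d, cfg)
  expect_identical(rep0$estimates, rep1$estimates)
  # weak instrument warning
  dweak <- d
  set.seed(89)
  dweak$prs <- rnorm(nrow(d))
  expect_warning(falsification_test(dweak,
                                    semi_empirical_config(n_replicates = 2,
                                                          seed = 90)),
                 "weak")
})
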