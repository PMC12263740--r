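test_that("exposure-on-genotype residuals match the hand fit", {
  # g=[0,0,1,1], x=[0,2,1,3]: slope 1, intercept 1, residuals [-1,1,-1,1]
  fit <- ols_residuals(c(0, 2, 1, 3), c(0, 0, 1, 1))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$residuals, c(-1, 1, -1, 1))
  # exact linear relationship leaves zero residuals
  g <- 1:10
  expect_equal(ols_residuals(2 + 3 * g, g)$residuals, rep(0, 10),
               tolerance = 1e-12)
  expect_error(ols_residuals(1:5, rep(2, 5)), "singular")
})

test_that("residuals agree with a normal-equations solver", {
  set.seed(31)
  for (i in 1:5) {
    g <- rnorm(50)
    z <- rnorm(50)
    x <- 0.5 * g + 0.2 * z + rnorm(50)
    ours <- ols_residuals(x, g, covariates = z)
    ref <- brute_ols(x, cbind(1, g, z))
    expect_equal(ours$residuals, ref$residuals, tolerance = 1e-10)
    expect_equal(ours$slope, ref$beta[2], tolerance = 1e-10)
  }
})

test_that("residual stratification continues the hand example", {
  co <- new_cohort_for_test(g = c(0, 0, 1, 1), x = c(0, 2, 1, 3))
  asg <- stratify_residual(co, S = 2)
  expect_identical(asg$stratum, c(1L, 2L, 1L, 2L))
  expect_identical(asg$method, "residual")
})

test_that("residual strata are equal-count and tie-stable", {
  set.seed(32)
  co <- new_cohort_for_test(g = rnorm(1000), x = rnorm(1000))
  asg <- stratify_residual(co, S = 10)
  expect_equal(as.integer(table(asg$stratum)), rep(100L, 10))
  # all-ties degenerate case: x = g exactly, so all residuals are 0;
  # the id-keyed tie rule still yields an equal split, invariant to order
  co2 <- new_cohort_for_test(g = 1:10, x = 1:10)
  asg2 <- stratify_residual(co2, S = 2)
  expect_equal(as.integer(table(asg2$stratum)), c(5L, 5L))
  perm <- sample(10)
  co2p <- new_cohort_for_test(g = co2$g[perm], x = co2$x[perm],
                              id = co2$id[perm])
  expect_identical(stratify_residual(co2p, S = 2)$stratum,
                   asg2$stratum[perm])
})

test_that("doubly-ranked stratification reproduces the hand trace", {
  co <- new_cohort_for_test(g = 1:6, x = c(10, 5, 7, 3, 8, 1))
  asg <- stratify_doubly_ranked(co, S = 2)
  expect_identical(asg$pre_stratum, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(sort(co$id[asg$stratum == 1L]), c(2L, 4L, 6L))
  expect_identical(sort(co$id[asg$stratum == 2L]), c(1L, 3L, 5L))
})

test_that("comonotone exposure gives stratum = within-pre-stratum g order", {
  g <- sort(rnorm(40))
  co <- new_cohort_for_test(g = g, x = g)
  asg <- stratify_doubly_ranked(co, S = 4)
  # each pre-stratum contributes its members in g-order
  for (p in unique(asg$pre_stratum)) {
    rows <- which(asg$pre_stratum == p)
    expect_identical(asg$stratum[rows][order(co$g[rows])], 1:4)
  }
})

test_that("both stratifiers match brute-force references on random instances", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(20:500, 1)
    S <- sample(2:min(10, n %/% 2), 1)
    co <- new_cohort_for_test(g = rnorm(n), x = rnorm(n))
    key <- oracle_keys(co$id)
    dr <- stratify_doubly_ranked(co, S)
    ref <- brute_doubly_ranked(co$g, co$x, S, key)
    expect_identical(dr$pre_stratum, as.integer(ref$pre))
    expect_identical(dr$stratum, as.integer(ref$stratum))
    rs <- stratify_residual(co, S)
    expect_identical(rs$stratum, as.integer(
      brute_residual_strata(co$g, co$x, S, key)))
  }
})

test_that("within every pre-stratum exposure increases with stratum label", {
  set.seed(34)
  co <- new_cohort_for_test(g = rnorm(10000), x = rnorm(10000))
  asg <- stratify_doubly_ranked(co, S = 10)
  ord <- order(asg$pre_stratum, asg$stratum)
  by_pre <- split(co$x[ord], asg$pre_stratum[ord])
  expect_true(all(vapply(by_pre, function(v) !is.unsorted(v), logical(1))))
})

test_that("doubly-ranked strata span the cohort's instrument range", {
  # every stratum holds one member of each complete pre-stratum, so on the
  # rank scale each stratum reaches both instrument extremes
  set.seed(35)
  co <- new_cohort_for_test(g = rnorm(10000), x = rnorm(10000))
  asg <- stratify_doubly_ranked(co, S = 10)
  g_rank <- rank(co$g) / nrow(co)
  rank_spans <- vapply(split(g_rank, asg$stratum),
                       function(v) diff(range(v)), numeric(1))
  expect_true(all(rank_spans >= 0.99))
  # with a bounded instrument the raw-range version holds too (a normal
  # instrument's extreme order statistics are too spread out for it)
  cou <- new_cohort_for_test(g = runif(10000), x = rnorm(10000))
  asgu <- stratify_doubly_ranked(cou, S = 10)
  gr <- diff(range(cou$g))
  spans <- vapply(split(cou$g, asgu$stratum),
                  function(v) diff(range(v)) / gr, numeric(1))
  expect_true(all(spans >= 0.9))
})

test_that("remainder pre-strata keep sizes within the documented bound", {
  co <- new_cohort_for_test(g = rnorm(47), x = rnorm(47))
  asg <- stratify_doubly_ranked(co, S = 5) # last pre-stratum has 2 members
  sizes <- tabulate(asg$stratum, 5)
  expect_equal(sum(sizes), 47L)
  expect_lte(diff(range(sizes)), ceiling(5 / 2))
  # monotone remainder mapping: j-th lowest of m maps to ceiling(j*S/m)
  last <- which(asg$pre_stratum == max(asg$pre_stratum))
  expect_identical(sort(asg$stratum[last]),
                   as.integer(ceiling(seq_along(last) * 5 / length(last))))
})

test_that("permuting cohort rows permutes assignments identically", {
  set.seed(36)
  n <- 500
  co <- new_cohort_for_test(g = rnorm(n), x = rnorm(n))
  perm <- sample(n)
  cop <- new_cohort_for_test(g = co$g[perm], x = co$x[perm],
                             id = co$id[perm])
  for (f in list(stratify_residual, stratify_doubly_ranked)) {
    expect_identical(f(cop, 10)$stratum, f(co, 10)$stratum[perm])
  }
})
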