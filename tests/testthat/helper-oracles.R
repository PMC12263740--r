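# Brute-force reference implementations, kept deliberately independent of
# the package internals: normal-equations OLS, a chunk-and-sort doubly-ranked
# stratifier, and a literal fixed-effect meta-analysis Q.

brute_ols <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = as.numeric(beta), se = as.numeric(se),
       residuals = as.numeric(resid))
}

# sort by g (ties by key), chunk into pre-strata of size S, sort each chunk
# by x (ties by key), hand out stratum labels by within-chunk position
brute_doubly_ranked <- function(g, x, S, key) {
  n <- length(g)
  ord_g <- order(g, key)
  pre <- integer(n)
  pre[ord_g] <- ceiling(seq_len(n) / S)
  stratum <- integer(n)
  for (p in unique(pre)) {
    rows <- which(pre == p)
    m <- length(rows)
    rows_sorted <- rows[order(x[rows], key[rows])]
    stratum[rows_sorted] <- ceiling(seq_len(m) * S / m)
  }
  list(pre = pre, stratum = stratum)
}

brute_residual_strata <- function(g, x, S, key) {
  fit <- brute_ols(x, cbind(1, g))
  r <- fit$residuals
  ord <- order(r, key)
  stratum <- integer(length(g))
  stratum[ord] <- floor((seq_along(g) - 1) * S / length(g)) + 1
  stratum
}

brute_q <- function(est, se) {
  w <- 1 / se^2
  pooled <- sum(w * est) / sum(w)
  Q <- sum(w * (est - pooled)^2)
  list(Q = Q, p = pchisq(Q, length(est) - 1, lower.tail = FALSE))
}

# the package's id-keyed tie-break, reproduced here so brute-force
# stratifiers rank in the same order
oracle_keys <- function(id, tie_seed = 20260920L) {
  set.seed(tie_seed)
  runif(max(id))[id]
}

# 99% two-sided binomial acceptance band for an observed proportion
binomial_band <- function(p, n, conf = 0.99) {
  a <- (1 - conf) / 2
  qbinom(c(a, 1 - a), n, p) / n
}

moments_skew <- function(v) mean(((v - mean(v)) / sd(v))^3)

new_cohort_for_test <- function(g, x, y = NULL, id = seq_along(g)) {
  df <- data.frame(id = as.integer(id), g = g, x = x)
  if (!is.null(y)) df$y <- y
  structure(df, class = c("nlmr_cohort", "data.frame"))
}

# convenience: simulation-A style config used across tests
test_config <- function(n = 2000, seed = 1, R = 5, ...) {
  scenario_config(n = n, seed = seed, n_replicates = R, ...)
}
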