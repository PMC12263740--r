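# Internal numeric helpers shared across modules.

# Deterministic pseudo-random tie-break keys, indexed by id rather than by
# row position so that permuting the input rows permutes the keys (and hence
# all rank-based assignments) identically.
tie_keys <- function(id, tie_seed) {
  stopifnot(all(id >= 1L))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(tie_seed))
  stats::runif(max(id))[id]
}

# Rank with ties broken by a shared key vector; returns integer ranks 1..n.
rank_with_key <- function(v, key) {
  o <- order(v, key)
  r <- integer(length(v))
  r[o] <- seq_along(v)
  r
}

# Equal-count stratum label for sorted position i of n into S groups;
# sizes differ by at most 1.
position_stratum <- function(i, n, S) {
  as.integer(floor((i - 1) * S / n) + 1L)
}

standardize <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector",
                                    call. = FALSE)
  (v - mean(v)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
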