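# Internal numeric helpers.

# log(exp(a) + exp(b)) without overflow; handles -Inf arguments.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  lo <- pmin(a, b)
  out <- m + log1p(exp(lo - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code does not perturb user streams.
# seed = NULL runs in the ambient RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a master seed and a stream counter, kept inside
# the 32-bit signed integer range.
derive_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 48271 + counter * 16807) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name,
                  format(lower)))
  }
  invisible(x)
}
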