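# Shared fixtures and independent oracles for the test suite.

# the mixture shape used throughout: bimodal log-scale expression
atlas_mixture <- function() mixture_params(0.4, 3.5, 1.2, 7.5, 1.8)

# random model parameters for property tests
random_f <- function() {
  mixture_params(runif(1), rnorm(1, 0, 3), runif(1, 0.2, 2),
                 rnorm(1, 3, 3), runif(1, 0.2, 2))
}

# Brute-force minimum-BIC segmentation by enumerating all 2^(G-1)
# segmentations of a small arm; independent of the DP (uses the R closed
# form per segment, not the C++ search).
brute_force_optimum <- function(mat, f, g, n_free = 1) {
  G <- nrow(mat)
  n_data <- G * ncol(mat)
  # memoise every contiguous interval's log likelihood (R closed form only)
  llmat <- matrix(NA_real_, G, G)
  for (a in 1:G) for (b in a:G) {
    llmat[a, b] <- sum(vapply(seq_len(ncol(mat)), function(t) {
      segment_log_marginal(mat[a:b, t], f, g)
    }, numeric(1)))
  }
  best <- Inf
  best_lengths <- NULL
  for (mask in 0:(2^(G - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(G - 1) - 1)) > 0)
    ends <- c(cuts, G)
    starts <- c(1, head(ends, -1) + 1)
    ll <- sum(llmat[cbind(starts, ends)])
    K <- length(ends) + n_free
    score <- -2 * ll + K * log(n_data)
    if (score < best) {
      best <- score
      best_lengths <- ends - c(0, head(ends, -1))
    }
  }
  list(score = best, lengths = as.integer(best_lengths))
}

# Two-sample KS statistic by direct ECDF gap scan.
ks_stat_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(grid, function(v) mean(b <= v), numeric(1))
  max(abs(Fa - Fb))
}

# Pearson chi-squared by the textbook formula sum (O - E)^2 / E.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of probabilities of all tables (with the same margins) no more
# probable than the observed one.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Hypergeometric upper-tail p (>= k successes) by direct summation.
hyper_tail_oracle <- function(k, K, N, n) {
  sum(dhyper(k:min(K, n), K, N - K, n))
}

# All permutations of a vector (with duplicates), as a list.
combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# A small deterministic expression fixture with replicate columns.
replicate_fixture <- function() {
  set.seed(42)
  base <- matrix(rnorm(40, 5, 2), nrow = 20)
  tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    brain.1 = base[, 1], brain.2 = base[, 1] + rnorm(20, 0, 0.05),
    gut.1 = base[, 2], gut.2 = base[, 2] + rnorm(20, 0, 3)
  )
}
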