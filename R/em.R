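#' Fit the segment-effect mixture by EM
#'
#' Fits a two-component (by default) univariate normal mixture to the pooled
#' expression values over all genes and tissues. The fitted mixture is the
#' distribution `f` of segment effects and is held fixed during all
#' subsequent segmentation; only the deviation sd is trained later.
#'
#' Components are initialised at the 25th/75th percentiles of the data with
#' the pooled variance; `n_restarts` jittered restarts are run and the fit
#' with the best log likelihood is kept. Components in the returned
#' parameters are ordered by increasing mean.
#'
#' @param values Numeric vector of expression values (pooled over tissues).
#' @param n_components Number of mixture components (default 2).
#' @param tol Convergence tolerance on the relative change in log likelihood.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of jittered restarts.
#' @param seed Optional seed for the restart jitter (restores the caller's
#'   RNG state afterwards).
#' @param var_floor Lower bound on component variances; hitting it on
#'   degenerate data (for example all values equal) raises an error.
#'
#' @return An object of class `mixture_em_fit` with elements `params` (a
#'   [mixture_params()] when `n_components == 2`), `weights`, `means`, `sds`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 3, 1), rnorm(500, 8, 1.5))
#' fit <- fit_mixture_em(x, seed = 1)
#' glance(fit)
#' @export
fit_mixture_em <- function(values, n_components = 2L, tol = 1e-8,
                           max_iter = 500L, n_restarts = 5L, seed = NULL,
                           var_floor = 1e-8) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) abort("`values` must be finite.")
  n <- length(values)
  if (n < 10L * n_components) {
    abort(sprintf("need at least %d values to fit %d components.",
                  10L * n_components, n_components))
  }
  if (var(values) < var_floor) {
    abort("degenerate data: pooled variance below the variance floor.")
  }

  base_means <- quantile(values, probs = seq(1, 2 * n_components - 1, by = 2) /
                           (2 * n_components), names = FALSE)
  base_sd <- sd(values)

  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      mu <- if (r == 1L) base_means else base_means + rnorm(n_components, 0, base_sd / 4)
      em_run(values, mu0 = mu, sd0 = rep(base_sd, n_components),
             w0 = rep(1 / n_components, n_components),
             tol = tol, max_iter = max_iter, var_floor = var_floor)
    })
  })
  best <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]

  ord <- order(best$means)
  w <- best$weights[ord]; mu <- best$means[ord]; s <- best$sds[ord]
  params <- if (n_components == 2L) mixture_params(w[1], mu[1], s[1], mu[2], s[2]) else NULL
  if (!best$converged) {
    warn(sprintf("EM did not reach tol within %d iterations; returning best fit so far.",
                 max_iter))
  }
  structure(
    list(params = params, weights = w, means = mu, sds = s,
         loglik = best$loglik, loglik_trace = best$trace,
         n_iter = best$n_iter, converged = best$converged, n = n,
         values = values),
    class = "mixture_em_fit"
  )
}

# One EM run from a given starting point.
em_run <- function(x, mu0, sd0, w0, tol, max_iter, var_floor) {
  K <- length(mu0)
  n <- length(x)
  mu <- mu0; s <- pmax(sd0, sqrt(var_floor)); w <- w0
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lp <- vapply(seq_len(K), function(k) log(w[k]) + dnorm(x, mu[k], s[k], log = TRUE),
                 numeric(n))
    m <- lp[, 1L]
    for (k in seq_len(K)[-1L]) m <- pmax(m, lp[, k])
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    resp <- exp(lp - lse)                       # n x K responsibilities
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- vapply(seq_len(K), function(k) sum(resp[, k] * (x - mu[k])^2) / nk[k],
                numeric(1))
    if (any(v < var_floor)) {
      abort("EM variance floor violated: a component collapsed onto few points.")
    }
    s <- sqrt(v)
  }
  list(weights = w, means = mu, sds = s, loglik = ll, trace = trace,
       n_iter = iter, converged = converged)
}

#' @export
print.mixture_em_fit <- function(x, ...) {
  cat(sprintf("Normal mixture EM fit (%d components, n = %d)\n",
              length(x$means), x$n))
  cat(sprintf("  loglik = %.4f after %d iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  for (k in seq_along(x$means)) {
    cat(sprintf("  component %d: weight %.4f, mean %.4f, sd %.4f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  }
  invisible(x)
}

#' Mixture density of a fitted or specified mixture
#'
#' @param x Points at which to evaluate the density.
#' @param f A [mixture_params()] object.
#' @return Density values.
#' @export
mixture_density <- function(x, f) {
  f <- as_mixture_params(f)
  f$phi * dnorm(x, f$mu1, f$sigma1) + (1 - f$phi) * dnorm(x, f$mu2, f$sigma2)
}
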