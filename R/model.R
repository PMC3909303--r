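#' Segment-effect mixture distribution
#'
#' The distribution `f` of latent segment effects: a two-component normal
#' mixture with mixing weight `phi` on the first component. A single `f` is
#' shared by all tissues and is held fixed while segmentations are searched.
#'
#' @param phi Mixing weight of the first component, in `[0, 1]`.
#' @param mu1,mu2 Component means, in expression units (log scale for
#'   typical microarray/RNA-seq input).
#' @param sigma1,sigma2 Component standard deviations, strictly positive.
#'
#' @return An object of class `mixture_params`.
#' @seealso [deviation_params()], [fit_mixture_em()]
#' @examples
#' f <- mixture_params(0.4, 3.5, 1.2, 7.5, 1.8)
#' tidy(f)
#' @export
mixture_params <- function(phi, mu1, sigma1, mu2, sigma2) {
  stopifnot_scalar_number(phi, "phi", 0)
  if (phi > 1) abort("`phi` must lie in [0, 1].")
  stopifnot_scalar_number(mu1, "mu1")
  stopifnot_scalar_number(mu2, "mu2")
  stopifnot_scalar_number(sigma1, "sigma1")
  stopifnot_scalar_number(sigma2, "sigma2")
  if (sigma1 <= 0 || sigma2 <= 0) abort("component sds must be > 0.")
  structure(
    list(phi = phi, mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2),
    class = "mixture_params"
  )
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("Segment-effect mixture f(s):\n")
  cat(sprintf("  %.4f * N(%.4f, %.4f^2) + %.4f * N(%.4f, %.4f^2)\n",
              x$phi, x$mu1, x$sigma1, 1 - x$phi, x$mu2, x$sigma2))
  invisible(x)
}

#' Mean and variance of the segment-effect mixture
#' @param f A [mixture_params()] object.
#' @return Named list with `mean` and `var`.
#' @export
mixture_moments <- function(f) {
  m <- f$phi * f$mu1 + (1 - f$phi) * f$mu2
  v <- f$phi * (f$sigma1^2 + f$mu1^2) + (1 - f$phi) * (f$sigma2^2 + f$mu2^2) - m^2
  list(mean = m, var = v)
}

#' Gene-specific deviation distribution
#'
#' The distribution `g` of per-gene, per-tissue deviations from the segment
#' effect: a zero-mean normal with standard deviation `sigma`. This is the
#' only distribution parameter trained during segmentation (see
#' [train_sigma()]).
#'
#' @param sigma Standard deviation, `>= 0`. Simulation accepts `sigma = 0`
#'   (the zero-noise limit); likelihood evaluation enforces a floor of
#'   `1e-4`, below which the marginal likelihood diverges.
#' @return An object of class `deviation_params`.
#' @export
deviation_params <- function(sigma) {
  stopifnot_scalar_number(sigma, "sigma", 0)
  structure(list(sigma = sigma), class = "deviation_params")
}

# scoring-side floor: the likelihood diverges as sigma -> 0
check_scoring_sigma <- function(g) {
  if (g$sigma < 1e-4) {
    abort("likelihood evaluation needs `sigma` >= 1e-4.")
  }
  g
}

#' @export
print.deviation_params <- function(x, ...) {
  cat(sprintf("Gene-deviation distribution g: N(0, %.4f^2)\n", x$sigma))
  invisible(x)
}

as_mixture_params <- function(f) {
  if (inherits(f, "mixture_params")) return(f)
  abort("`f` must be a `mixture_params` object (see `mixture_params()`).")
}

as_deviation_params <- function(g) {
  if (inherits(g, "deviation_params")) return(g)
  if (is.numeric(g) && length(g) == 1L) return(deviation_params(g))
  abort("`g` must be a `deviation_params` object or a single sd.")
}

# Closed-form log marginal of n iid N(s, sigma^2) values with s ~ N(mu, tau^2):
# -(n/2) log 2*pi - (n-1) log sigma - 0.5 log(sigma^2 + n tau^2)
#   - S/(2 sigma^2) - n (xbar - mu)^2 / (2 (sigma^2 + n tau^2))
# where S is the within-segment sum of squares. Vectorised over (n, xbar, S).
normal_normal_lmarg <- function(n, xbar, S, mu, tau, sigma) {
  d <- sigma^2 + n * tau^2
  -0.5 * n * log(2 * pi) - (n - 1) * log(sigma) - 0.5 * log(d) -
    S / (2 * sigma^2) - n * (xbar - mu)^2 / (2 * d)
}

#' Segment log marginal likelihood in one tissue
#'
#' Log probability of the expression values of one segment's genes in a
#' single tissue, with the shared segment effect integrated out. The effect
#' is drawn from the mixture `f`, each gene deviates from it by an
#' independent `N(0, g$sigma^2)` draw, and the integral over the effect has
#' a closed form per mixture component (a normal-normal conjugate marginal);
#' the two components are combined on the log scale.
#'
#' @param x Numeric vector: the segment's values in one tissue (length `n >= 1`).
#' @param f A [mixture_params()] object.
#' @param g A [deviation_params()] object (or a single sd).
#' @return A single log probability.
#' @seealso [segment_log_marginal_quadrature()] for the same quantity by
#'   numerical integration.
#' @examples
#' f <- mixture_params(1, 0, 1, 0, 1)
#' segment_log_marginal(0, f, deviation_params(1))  # log N(0; 0, 2)
#' @export
segment_log_marginal <- function(x, f, g) {
  f <- as_mixture_params(f)
  g <- check_scoring_sigma(as_deviation_params(g))
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    abort("`x` must be a non-empty finite numeric vector.")
  }
  n <- length(x)
  xbar <- mean(x)
  S <- sum((x - xbar)^2)
  lp1 <- if (f$phi > 0) {
    log(f$phi) + normal_normal_lmarg(n, xbar, S, f$mu1, f$sigma1, g$sigma)
  } else -Inf
  lp2 <- if (f$phi < 1) {
    log1p(-f$phi) + normal_normal_lmarg(n, xbar, S, f$mu2, f$sigma2, g$sigma)
  } else -Inf
  logsumexp2(lp1, lp2)
}

#' Segment log marginal by adaptive quadrature
#'
#' Evaluates the defining integral over the segment effect numerically,
#' component by component, with the integrand rescaled by its value at the
#' conjugate posterior mode for stability. Intended as an independent check
#' of [segment_log_marginal()]; the closed form is what the search uses.
#'
#' @inheritParams segment_log_marginal
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return A single log probability.
#' @export
segment_log_marginal_quadrature <- function(x, f, g, rel_tol = 1e-10) {
  f <- as_mixture_params(f)
  g <- check_scoring_sigma(as_deviation_params(g))
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    abort("`x` must be a non-empty finite numeric vector.")
  }
  n <- length(x)
  sigma <- g$sigma
  comp <- function(mu, tau) {
    # the integrand is a product of Gaussians in s, concentrated around the
    # conjugate posterior mode; integrate a generous multiple of the
    # posterior sd around it so narrow spikes are never missed
    prec <- n / sigma^2 + 1 / tau^2
    m <- (sum(x) / sigma^2 + mu / tau^2) / prec
    half <- 30 / sqrt(prec)
    lo <- m - half
    hi <- m + half
    logh <- function(s) {
      vapply(s, function(si) {
        sum(dnorm(x, si, sigma, log = TRUE)) + dnorm(si, mu, tau, log = TRUE)
      }, numeric(1))
    }
    shift <- logh(m)
    val <- integrate(function(s) exp(logh(s) - shift), lo, hi,
                     rel.tol = rel_tol, subdivisions = 500L)
    if (val$message != "OK") abort(paste("quadrature failed:", val$message))
    shift + log(val$value)
  }
  lp1 <- if (f$phi > 0) log(f$phi) + comp(f$mu1, f$sigma1) else -Inf
  lp2 <- if (f$phi < 1) log1p(-f$phi) + comp(f$mu2, f$sigma2) else -Inf
  logsumexp2(lp1, lp2)
}

# Coerce expression input (tibble with gene_id + tissue columns, or a plain
# numeric matrix) to a genes x tissues numeric matrix.
expr_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    meta <- intersect(c("gene_id", "arm", "start", "end", "strand"), names(x))
    vals <- x[setdiff(names(x), meta)]
    if (!all(vapply(vals, is.numeric, logical(1)))) {
      abort("non-numeric tissue columns in expression data.")
    }
    m <- as.matrix(vals)
    if ("gene_id" %in% names(x)) rownames(m) <- x$gene_id
    return(m)
  }
  abort("expression data must be a data frame or numeric matrix.")
}

check_lengths <- function(lengths, n_genes) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 1L || any(lengths < 1L)) {
    abort("segment lengths must all be >= 1.")
  }
  if (sum(lengths) != n_genes) {
    abort(sprintf("segment lengths sum to %d but the arm has %d genes.",
                  sum(lengths), n_genes))
  }
  lengths
}

#' Log likelihood of a segmentation
#'
#' Sums [segment_log_marginal()] over all segments and tissues; segments and
#' tissues are modelled as independent.
#'
#' @param expr Expression data for one arm: a tibble with a `gene_id` column
#'   and one numeric column per tissue (rows ordered by transcription start),
#'   or a genes-by-tissues numeric matrix.
#' @param lengths Integer vector of segment lengths (genes per segment),
#'   summing to the number of genes.
#' @inheritParams segment_log_marginal
#' @return Total log likelihood (a single number).
#' @export
segmentation_loglik <- function(expr, lengths, f, g) {
  f <- as_mixture_params(f)
  g <- check_scoring_sigma(as_deviation_params(g))
  m <- expr_matrix(expr)
  lengths <- check_lengths(lengths, nrow(m))
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  sum(seg_ll_batch_cpp(m, starts, ends, f$phi, f$mu1, f$sigma1,
                       f$mu2, f$sigma2, g$sigma))
}

#' BIC score of a segmentation
#'
#' `score = -2 loglik + K log(n_data)` where `K` counts one parameter per
#' segment plus `n_free_dist_params` free distribution parameters (1 by
#' default: only the deviation sd is trained; the mixture `f` is fixed).
#' `n_data` is genes times tissues for the arm. Lower scores are better.
#'
#' @param loglik Total log likelihood of the segmentation.
#' @param lengths Integer vector of segment lengths.
#' @param n_data Number of data points on the arm (genes x tissues).
#' @param n_free_dist_params Free distribution parameters counted in `K`.
#' @param arm_id Optional arm identifier carried on the result.
#' @return A `scored_segmentation` object; see [tidy.scored_segmentation()].
#' @examples
#' bic_score(-10, c(2, 5, 3), n_data = 100)
#' @export
bic_score <- function(loglik, lengths, n_data, n_free_dist_params = 1,
                      arm_id = NULL) {
  stopifnot_scalar_number(loglik, "loglik")
  if (!is.numeric(n_data) || n_data < 2) abort("`n_data` must be >= 2.")
  lengths <- check_lengths(lengths, sum(as.integer(lengths)))
  K <- length(lengths) + n_free_dist_params
  new_scored_segmentation(
    lengths = lengths, loglik = loglik, K = K, n_data = n_data,
    score = -2 * loglik + K * log(n_data), arm_id = arm_id
  )
}

new_scored_segmentation <- function(lengths, loglik, K, n_data, score,
                                    arm_id = NULL, sigma = NULL,
                                    n_iterations = NULL, trace = NULL) {
  expect <- -2 * loglik + K * log(n_data)
  if (is.finite(score) && abs(score - expect) > 1e-6 * max(1, abs(expect))) {
    abort("inconsistent scored segmentation: score != -2*loglik + K*log(n).")
  }
  structure(
    list(lengths = as.integer(lengths), loglik = loglik, K = K,
         n_data = n_data, score = score, arm_id = arm_id, sigma = sigma,
         n_iterations = n_iterations, trace = trace),
    class = "scored_segmentation"
  )
}

#' @export
print.scored_segmentation <- function(x, ...) {
  cat(sprintf(
    "Scored segmentation%s: %d segments over %d genes\n",
    if (is.null(x$arm_id)) "" else paste0(" [", x$arm_id, "]"),
    length(x$lengths), sum(x$lengths)))
  cat(sprintf("  loglik = %.4f, K = %d, n = %d, BIC score = %.4f\n",
              x$loglik, x$K, x$n_data, x$score))
  if (!is.null(x$sigma)) cat(sprintf("  sigma = %.6f\n", x$sigma))
  invisible(x)
}

#' Internal segment boundaries of a segmentation
#'
#' Boundary `b` means "between gene `b` and gene `b + 1`" (cumulative gene
#' counts, excluding the arm end).
#'
#' @param lengths Integer vector of segment lengths.
#' @return Integer vector of internal boundaries (possibly empty).
#' @export
segment_boundaries <- function(lengths) {
  ends <- cumsum(as.integer(lengths))
  head(ends, -1L)
}

#' Write or read fitted model parameters
#'
#' Serializes the fixed mixture `f` and the deviation sd as a flat key-value
#' text file so a fitted `f` can be frozen once and reused across runs.
#'
#' @param f A [mixture_params()] object.
#' @param g A [deviation_params()] object, or `NULL` to omit.
#' @param path File path.
#' @return `write_model_params()` returns `path` invisibly;
#'   `read_model_params()` returns `list(f = , g = )` (with `g = NULL` if no
#'   deviation sd was stored).
#' @export
write_model_params <- function(f, g = NULL, path) {
  f <- as_mixture_params(f)
  lines <- c(
    sprintf("phi = %.17g", f$phi),
    sprintf("mu1 = %.17g", f$mu1),
    sprintf("sigma1 = %.17g", f$sigma1),
    sprintf("mu2 = %.17g", f$mu2),
    sprintf("sigma2 = %.17g", f$sigma2)
  )
  if (!is.null(g)) {
    g <- check_scoring_sigma(as_deviation_params(g))
    lines <- c(lines, sprintf("sigma = %.17g", g$sigma))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) {
    abort(sprintf("malformed parameter line %d: %s", bad[1], lines[bad[1]]))
  }
  vals <- setNames(
    vapply(kv, function(p) as.numeric(trimws(p[2])), numeric(1)),
    vapply(kv, function(p) trimws(p[1]), character(1))
  )
  need <- c("phi", "mu1", "sigma1", "mu2", "sigma2")
  if (!all(need %in% names(vals))) {
    abort(paste("missing parameter keys:",
                paste(setdiff(need, names(vals)), collapse = ", ")))
  }
  list(
    f = mixture_params(vals[["phi"]], vals[["mu1"]], vals[["sigma1"]],
                       vals[["mu2"]], vals[["sigma2"]]),
    g = if ("sigma" %in% names(vals)) deviation_params(vals[["sigma"]]) else NULL
  )
}
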