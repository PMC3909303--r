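#' Train the deviation sd by simplex search over replicate scores
#'
#' The only distribution parameter estimated during segmentation is the sd
#' of the gene-specific deviation `g`; the mixture `f` stays fixed at its
#' EM fit. For a candidate sd the objective is the aggregated (by default
#' median) final BIC score of `n_replicates` greedy descents from random
#' starts; the sd is optimised by a one-dimensional Nelder-Mead simplex on
#' `log(sigma)`, which keeps the sd positive. Every objective evaluation
#' reuses the same `master_seed`, so all candidate sds are scored against
#' identical sets of starting segmentations and the objective is a
#' deterministic function of sigma.
#'
#' @inheritParams run_replicates
#' @param sigma_init Starting value for the deviation sd.
#' @param tol Relative simplex width (on `log(sigma)`) at convergence.
#' @param step Initial simplex step on `log(sigma)`.
#' @param max_eval Cap on objective evaluations.
#' @return A `sigma_training` object: list with `sigma` (trained sd),
#'   `objective` (aggregated score at `sigma`), `best` (best-scoring single
#'   segmentation found at the trained sd, a `scored_segmentation`),
#'   `evaluations` (tibble of all `(sigma, score)` pairs in evaluation
#'   order), `n_eval`, and `converged`.
#' @seealso [run_replicates()], [dp_optimal_segmentation()]
#' @export
train_sigma <- function(expr, f, sigma_init = 1, n_replicates = 64L,
                        master_seed = 1L, tol = 1e-3, step = 0.5,
                        max_eval = 100L,
                        aggregator = c("median", "best", "mean"),
                        mean_len = 2, n_free_dist_params = 1,
                        arm_id = NULL) {
  aggregator <- arg_match(aggregator)
  f <- as_mixture_params(f)
  stopifnot_scalar_number(sigma_init, "sigma_init")
  if (sigma_init <= 0) abort("`sigma_init` must be > 0.")
  m <- expr_matrix(expr)

  evals <- list()
  cache <- new.env(parent = emptyenv())
  objective <- function(logsig) {
    key <- sprintf("%.15g", logsig)
    if (!is.null(cache[[key]])) return(cache[[key]])
    sigma <- max(exp(logsig), 1e-4)
    rs <- run_replicates(m, f, deviation_params(sigma),
                         n_replicates = n_replicates,
                         master_seed = master_seed, aggregator = aggregator,
                         mean_len = mean_len,
                         n_free_dist_params = n_free_dist_params,
                         arm_id = arm_id, keep_results = FALSE)
    evals[[length(evals) + 1L]] <<- list(sigma = sigma, score = rs$score,
                                         best_score = min(rs$scores))
    val <- list(score = rs$score, sigma = sigma)
    cache[[key]] <- val
    val
  }

  # 1-D Nelder-Mead on log(sigma): reflection, expansion, contraction.
  x1 <- log(sigma_init)
  x2 <- x1 + step
  f1 <- objective(x1)$score
  f2 <- objective(x2)$score
  if (!is.finite(f1) && !is.finite(f2)) {
    abort("objective non-finite at both initial simplex points.")
  }
  n_eval <- 2L
  converged <- FALSE
  while (n_eval < max_eval) {
    if (f2 < f1) { tmp <- x1; x1 <- x2; x2 <- tmp; tmp <- f1; f1 <- f2; f2 <- tmp }
    if (abs(x1 - x2) < tol) { converged <- TRUE; break }
    xr <- x1 + (x1 - x2)                 # reflect worst through best
    fr <- objective(xr)$score; n_eval <- n_eval + 1L
    if (fr < f1) {
      xe <- x1 + 2 * (x1 - x2)           # expand
      fe <- objective(xe)$score; n_eval <- n_eval + 1L
      if (fe < fr) { x2 <- xe; f2 <- fe } else { x2 <- xr; f2 <- fr }
    } else {
      xc <- (x1 + x2) / 2                # contract (= shrink in 1-D)
      fc <- objective(xc)$score; n_eval <- n_eval + 1L
      if (fc < f2) { x2 <- xc; f2 <- fc } else {
        # no progress in either direction: halve towards the best point
        x2 <- (x1 + x2) / 2
        f2 <- objective(x2)$score; n_eval <- n_eval + 1L
      }
    }
  }
  if (f2 < f1) { tmp <- x1; x1 <- x2; x2 <- tmp; tmp <- f1; f1 <- f2; f2 <- tmp }

  sigma_hat <- max(exp(x1), 1e-4)
  # best single segmentation at the trained parameter value
  final_rs <- run_replicates(m, f, deviation_params(sigma_hat),
                             n_replicates = n_replicates,
                             master_seed = master_seed,
                             aggregator = aggregator, mean_len = mean_len,
                             n_free_dist_params = n_free_dist_params,
                             arm_id = arm_id, keep_results = TRUE)
  structure(
    list(sigma = sigma_hat, objective = f1, best = final_rs$best,
         replicates = final_rs,
         evaluations = bind_rows(lapply(evals, as_tibble)),
         n_eval = length(evals), converged = converged,
         aggregator = aggregator, master_seed = master_seed),
    class = "sigma_training"
  )
}

#' @export
print.sigma_training <- function(x, ...) {
  cat(sprintf(
    "Deviation-sd training: sigma = %.6f (%s replicate score %.4f, %d objective evaluations%s)\n",
    x$sigma, x$aggregator, x$objective, x$n_eval,
    if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  best segmentation: %d segments, score %.4f\n",
              length(x$best$lengths), x$best$score))
  invisible(x)
}
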