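# broom-style tidiers for the package's fitted objects.

#' Tidy a fitted segment-effect mixture
#'
#' @param x A `mixture_em_fit` from [fit_mixture_em()], or a
#'   [mixture_params()] object.
#' @param ... Unused.
#' @return One row per mixture component: `component`, `weight`, `mean`, `sd`.
#' @export
tidy.mixture_em_fit <- function(x, ...) {
  tibble(component = seq_along(x$means), weight = x$weights,
         mean = x$means, sd = x$sds)
}

#' @rdname tidy.mixture_em_fit
#' @export
tidy.mixture_params <- function(x, ...) {
  tibble(component = 1:2, weight = c(x$phi, 1 - x$phi),
         mean = c(x$mu1, x$mu2), sd = c(x$sigma1, x$sigma2))
}

#' @rdname tidy.mixture_em_fit
#' @export
glance.mixture_em_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n = x$n, n_components = length(x$means))
}

#' Tidy a scored segmentation
#'
#' @param x A `scored_segmentation` (from [bic_score()],
#'   [greedy_descent()], [dp_optimal_segmentation()] or [train_sigma()]).
#' @param ... Unused.
#' @return One row per segment: `segment`, `first_gene`, `last_gene`,
#'   `n_genes` (gene positions are 1-based indices in arm order).
#' @export
tidy.scored_segmentation <- function(x, ...) {
  ends <- cumsum(x$lengths)
  tibble(segment = seq_along(x$lengths),
         first_gene = c(1L, head(ends, -1L) + 1L),
         last_gene = ends, n_genes = x$lengths)
}

#' @rdname tidy.scored_segmentation
#' @export
glance.scored_segmentation <- function(x, ...) {
  tibble(score = x$score, loglik = x$loglik, K = x$K, n_data = x$n_data,
         n_segments = length(x$lengths),
         sigma = x$sigma %||% NA_real_,
         mean_segment_len = mean(x$lengths),
         fraction_multigenic_genes = sum(x$lengths[x$lengths > 1]) / sum(x$lengths))
}

#' Tidy a replicate set
#'
#' @param x A `replicate_set` from [run_replicates()].
#' @param ... Unused.
#' @return One row per replicate: `replicate`, `score`, `loglik`,
#'   `n_segments`, `n_iterations`.
#' @export
tidy.replicate_set <- function(x, ...) {
  if (is.null(x$results)) {
    return(tibble(replicate = seq_along(x$scores), score = x$scores))
  }
  purrr::map_dfr(seq_along(x$results), function(i) {
    r <- x$results[[i]]
    tibble(replicate = i, score = r$score, loglik = r$loglik,
           n_segments = length(r$lengths),
           n_iterations = r$n_iterations %||% NA_integer_)
  })
}

#' @rdname tidy.replicate_set
#' @export
glance.replicate_set <- function(x, ...) {
  tibble(score = x$score, aggregator = x$aggregator,
         best_score = min(x$scores), worst_score = max(x$scores),
         n_replicates = x$n_replicates, master_seed = x$master_seed)
}

#' Tidy a deviation-sd training run
#'
#' @param x A `sigma_training` from [train_sigma()].
#' @param ... Unused.
#' @return The objective evaluations in order: `sigma`, `score`,
#'   `best_score`.
#' @export
tidy.sigma_training <- function(x, ...) {
  x$evaluations
}

#' @rdname tidy.sigma_training
#' @export
glance.sigma_training <- function(x, ...) {
  tibble(sigma = x$sigma, objective = x$objective,
         best_score = x$best$score, n_segments = length(x$best$lengths),
         n_eval = x$n_eval, converged = x$converged,
         aggregator = x$aggregator)
}

#' Augment expression data with segment assignments
#'
#' @param x A `scored_segmentation`.
#' @param data Expression tibble for the same arm (rows in arm order).
#' @param ... Unused.
#' @return `data` with a `segment` column.
#' @export
augment.scored_segmentation <- function(x, data, ...) {
  if (nrow(data) != sum(x$lengths)) {
    abort("`data` has a different number of genes than the segmentation.")
  }
  data$segment <- rep.int(seq_along(x$lengths), x$lengths)
  data
}
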