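# ggplot2 diagnostics for the package's result types.

#' Plot a fitted segment-effect mixture over the data
#'
#' Histogram of the pooled expression values with the fitted mixture
#' density and its two components overlaid.
#'
#' @param object A `mixture_em_fit` from [fit_mixture_em()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_em_fit <- function(object, bins = 80, ...) {
  df <- tibble(value = object$values)
  grid <- seq(min(df$value), max(df$value), length.out = 512)
  dens <- purrr::map_dfr(seq_along(object$means), function(k) {
    tibble(value = grid,
           density = object$weights[k] * dnorm(grid, object$means[k],
                                               object$sds[k]),
           component = paste("component", k))
  })
  total <- tibble(value = grid,
                  density = rowSums(vapply(seq_along(object$means), function(k) {
                    object$weights[k] * dnorm(grid, object$means[k], object$sds[k])
                  }, numeric(length(grid)))),
                  component = "mixture")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = bind_rows(dens, total),
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component,
                                    linetype = .data$component)) +
    ggplot2::labs(x = "expression value", y = "density",
                  title = "Segment-effect mixture fit") +
    ggplot2::theme_minimal()
}

#' Plot segment expression profiles (mean vs. SD)
#'
#' Scatter of across-tissue mean against across-tissue standard deviation
#' of the per-segment expression values, the classic view separating
#' housekeeping-like segments (low SD) from tissue-restricted ones (top
#' quartile of SD). Classified profiles (from [classify_segments()]) are
#' coloured by class, with the quartile cutoff drawn.
#'
#' @param object A `segment_profiles` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segment_profiles <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$across_tissue_mean,
                                    y = .data$across_tissue_sd))
  if ("class" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class,
                                              size = .data$n_genes),
                                 alpha = 0.7)
    cutoff <- attr(object, "sd_cutoff")
    if (!is.null(cutoff)) {
      p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                                   colour = "grey40")
    }
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$n_genes),
                                 alpha = 0.7, colour = "steelblue")
  }
  p +
    ggplot2::labs(x = "across-tissue mean of segment values",
                  y = "across-tissue SD of segment values",
                  title = "Segment expression profiles") +
    ggplot2::theme_minimal()
}

#' Plot the objective surface of a deviation-sd training run
#'
#' Aggregated replicate score at every evaluated sd, with the trained value
#' marked.
#'
#' @param object A `sigma_training` from [train_sigma()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigma_training <- function(object, ...) {
  ggplot2::ggplot(object$evaluations,
                  ggplot2::aes(x = .data$sigma, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$sigma, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "deviation sd (log scale)",
                  y = paste(object$aggregator, "replicate score"),
                  title = "Simplex training of the deviation sd") +
    ggplot2::theme_minimal()
}

#' Plot segment structure along the arm
#'
#' Gene positions (arm order) coloured by segment, one panel per tissue for
#' up to `max_tissues` tissues, with segment boundaries drawn.
#'
#' @param object A `scored_segmentation`.
#' @param expr Optional expression tibble/matrix for the same arm; when
#'   given, per-gene expression is drawn instead of segment indices.
#' @param max_tissues Maximum number of tissues to facet.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scored_segmentation <- function(object, expr = NULL,
                                         max_tissues = 4L, ...) {
  bounds <- segment_boundaries(object$lengths) + 0.5
  if (is.null(expr)) {
    df <- tibble(gene = seq_len(sum(object$lengths)),
                 segment = rep.int(seq_along(object$lengths), object$lengths))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = 1,
                                       fill = factor(.data$segment %% 2))) +
        ggplot2::geom_tile(height = 1, show.legend = FALSE) +
        ggplot2::geom_vline(xintercept = bounds, linewidth = 0.2,
                            colour = "white") +
        ggplot2::scale_fill_manual(values = c("grey35", "grey65")) +
        ggplot2::labs(x = "gene (arm order)", y = NULL,
                      title = sprintf("%d segments, BIC score %.1f",
                                      length(object$lengths), object$score)) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.y = ggplot2::element_blank())
    )
  }
  m <- expr_matrix(expr)
  keep <- seq_len(min(ncol(m), max_tissues))
  df <- tibble(
    gene = rep(seq_len(nrow(m)), length(keep)),
    tissue = rep(colnames(m)[keep] %||% paste0("tissue", keep),
                 each = nrow(m)),
    value = as.vector(m[, keep]),
    segment = rep(rep.int(seq_along(object$lengths), object$lengths),
                  length(keep))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$segment %% 2)),
                        size = 0.6, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = bounds, linewidth = 0.2,
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c("grey20", "steelblue")) +
    ggplot2::facet_wrap(~tissue, ncol = 1) +
    ggplot2::labs(x = "gene (arm order)", y = "expression",
                  title = sprintf("%d segments, BIC score %.1f",
                                  length(object$lengths), object$score)) +
    ggplot2::theme_minimal()
}
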