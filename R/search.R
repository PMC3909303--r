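#' Random initial segmentation
#'
#' Draws segment lengths iid from a geometric distribution on `{1, 2, ...}`
#' with mean `mean_len` (success probability `1/mean_len`) until the arm is
#' covered; the final segment is truncated to fit exactly. Uses the current
#' R RNG stream.
#'
#' @param n_genes Number of genes on the arm.
#' @param mean_len Mean segment length of the geometric draw (default 2).
#' @return Integer vector of segment lengths summing to `n_genes`.
#' @export
random_segmentation <- function(n_genes, mean_len = 2) {
  stopifnot_scalar_number(n_genes, "n_genes", 1)
  stopifnot_scalar_number(mean_len, "mean_len", 1)
  n_genes <- as.integer(n_genes)
  lengths <- integer(0)
  total <- 0L
  while (total < n_genes) {
    # draw in batches; rgeom counts failures, so + 1 gives support {1, 2, ...}
    k <- max(16L, ceiling((n_genes - total) / mean_len))
    draw <- rgeom(k, prob = 1 / mean_len) + 1L
    lengths <- c(lengths, draw)
    total <- total + sum(draw)
  }
  ends <- cumsum(lengths)
  keep <- which(ends >= n_genes)[1]
  lengths <- lengths[seq_len(keep)]
  lengths[keep] <- lengths[keep] - (sum(lengths) - n_genes)
  if (lengths[keep] == 0L) lengths <- lengths[-keep]
  as.integer(lengths)
}

#' Enumerate candidate moves of a segmentation
#'
#' Lists every split (each internal position of each multigenic segment),
#' every merge of adjacent segments, and every shift of an existing boundary
#' to an alternative position within its two flanking segments (at least one
#' gene must remain on each side). Shifts that reproduce the current
#' boundary are excluded. The row order is the deterministic tie-break
#' order of the greedy search: splits by segment then position, merges by
#' boundary, shifts by boundary then position.
#'
#' @param lengths Integer vector of segment lengths.
#' @return A tibble with columns `kind` (`"split"`, `"merge"`, `"shift"`),
#'   `index` (segment index for splits, boundary index otherwise) and `pos`
#'   (absolute gene index of the new cut; `NA` for merges).
#' @export
enumerate_moves <- function(lengths) {
  lengths <- check_lengths(lengths, sum(as.integer(lengths)))
  nseg <- length(lengths)
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1L) + 1L)

  splits <- purrr::map_dfr(seq_len(nseg), function(j) {
    if (lengths[j] < 2L) return(tibble())
    tibble(kind = "split", index = j, pos = seq(starts[j], ends[j] - 1L))
  })
  merges <- if (nseg > 1L) {
    tibble(kind = "merge", index = seq_len(nseg - 1L), pos = NA_integer_)
  } else tibble()
  shifts <- purrr::map_dfr(seq_len(max(nseg - 1L, 0L)), function(b) {
    cand <- setdiff(seq(starts[b], ends[b + 1L] - 1L), ends[b])
    if (!length(cand)) return(tibble())
    tibble(kind = "shift", index = b, pos = cand)
  })
  out <- bind_rows(splits, merges, shifts)
  if (nrow(out) == 0L) {
    out <- tibble(kind = character(), index = integer(), pos = integer())
  }
  out
}

#' Apply or invert a move
#'
#' @param lengths Integer vector of segment lengths.
#' @param move One-row data frame (or list) with `kind`, `index`, `pos` as
#'   produced by [enumerate_moves()].
#' @return The new lengths vector. `invert_move()` returns the move that
#'   undoes `move` when applied to the *result* of `apply_move()`.
#' @export
apply_move <- function(lengths, move) {
  lengths <- as.integer(lengths)
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  kind <- as.character(move$kind)
  i <- as.integer(move$index)
  if (kind == "split") {
    pos <- as.integer(move$pos)
    if (pos < starts[i] || pos >= ends[i]) abort("split position outside segment.")
    new_ends <- sort(c(ends, pos))
  } else if (kind == "merge") {
    if (i < 1L || i >= length(lengths)) abort("merge boundary out of range.")
    new_ends <- ends[-i]
  } else if (kind == "shift") {
    pos <- as.integer(move$pos)
    if (i < 1L || i >= length(lengths)) abort("shift boundary out of range.")
    if (pos < starts[i] || pos >= ends[i + 1L] || pos == ends[i]) {
      abort("shift position invalid.")
    }
    new_ends <- ends
    new_ends[i] <- pos
  } else {
    abort("unknown move kind.")
  }
  as.integer(diff(c(0L, new_ends)))
}

#' @rdname apply_move
#' @export
invert_move <- function(lengths, move) {
  lengths <- as.integer(lengths)
  ends <- cumsum(lengths)
  kind <- as.character(move$kind)
  i <- as.integer(move$index)
  if (kind == "split") {
    list(kind = "merge", index = i, pos = NA_integer_)
  } else if (kind == "merge") {
    list(kind = "split", index = i, pos = ends[i])
  } else if (kind == "shift") {
    list(kind = "shift", index = i, pos = ends[i])
  } else {
    abort("unknown move kind.")
  }
}

#' Incremental score change of a move
#'
#' Score difference `score(after) - score(before)` computed from the
#' segments the move touches only; segments elsewhere on the arm cancel.
#'
#' @inheritParams segmentation_loglik
#' @inheritParams apply_move
#' @param n_data Data points on the arm (genes x tissues); defaults to the
#'   dimensions of `expr`.
#' @return A single number (negative = improvement).
#' @export
move_delta_score <- function(expr, lengths, move, f, g, n_data = NULL) {
  f <- as_mixture_params(f)
  g <- check_scoring_sigma(as_deviation_params(g))
  m <- expr_matrix(expr)
  lengths <- check_lengths(lengths, nrow(m))
  if (is.null(n_data)) n_data <- nrow(m) * ncol(m)
  ln_n <- log(n_data)
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ll <- function(a, b) {
    sum(seg_ll_batch_cpp(m, a, b, f$phi, f$mu1, f$sigma1, f$mu2, f$sigma2,
                         g$sigma))
  }
  kind <- as.character(move$kind)
  i <- as.integer(move$index)
  if (kind == "split") {
    p <- as.integer(move$pos)
    dll <- ll(starts[i], p) + ll(p + 1L, ends[i]) - ll(starts[i], ends[i])
    -2 * dll + ln_n
  } else if (kind == "merge") {
    dll <- ll(starts[i], ends[i + 1L]) -
      ll(starts[i], ends[i]) - ll(starts[i + 1L], ends[i + 1L])
    -2 * dll - ln_n
  } else if (kind == "shift") {
    p <- as.integer(move$pos)
    dll <- ll(starts[i], p) + ll(p + 1L, ends[i + 1L]) -
      ll(starts[i], ends[i]) - ll(starts[i + 1L], ends[i + 1L])
    -2 * dll
  } else {
    abort("unknown move kind.")
  }
}

#' Greedy descent to a locally optimal segmentation
#'
#' From an initial segmentation, repeatedly evaluates the score change of
#' every candidate move (incrementally: only segments touched by a move are
#' re-scored) and applies the single best strictly improving move, until no
#' move improves the BIC score by more than `eps`. Ties are broken by a
#' fixed enumeration order (see [enumerate_moves()]).
#'
#' @inheritParams segmentation_loglik
#' @param init Initial segment lengths (for example from
#'   [random_segmentation()]).
#' @param n_free_dist_params Free distribution parameters counted in `K`.
#' @param eps Minimum score improvement for a move to be applied.
#' @param max_iter Hard cap on the number of applied moves.
#' @param arm_id Optional arm identifier carried on the result.
#' @return A `replicate_result`: list with `final` (a `scored_segmentation`),
#'   `n_iterations`, `trace` (score after each move, starting at the initial
#'   score) and `moves` (the applied moves).
#' @export
greedy_descent <- function(expr, init, f, g, n_free_dist_params = 1,
                           eps = 1e-9, max_iter = 100000L, arm_id = NULL) {
  f <- as_mixture_params(f)
  g <- check_scoring_sigma(as_deviation_params(g))
  m <- expr_matrix(expr)
  init <- check_lengths(init, nrow(m))
  n_data <- nrow(m) * ncol(m)
  res <- greedy_descent_cpp(m, init, f$phi, f$mu1, f$sigma1, f$mu2, f$sigma2,
                            g$sigma, log(n_data), eps, max_iter,
                            n_free_dist_params)
  final <- new_scored_segmentation(
    lengths = res$lengths, loglik = res$loglik,
    K = length(res$lengths) + n_free_dist_params, n_data = n_data,
    score = res$score, arm_id = arm_id, sigma = g$sigma,
    n_iterations = res$n_iterations, trace = res$trace
  )
  moves <- as_tibble(res$moves)
  moves$kind <- c("split", "merge", "shift")[moves$kind]
  moves$pos[moves$kind == "merge"] <- NA_integer_
  structure(
    list(final = final, n_iterations = res$n_iterations, trace = res$trace,
         moves = moves),
    class = "replicate_result"
  )
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("Greedy descent: %d moves, final score %.4f (%d segments)\n",
              x$n_iterations, x$final$score, length(x$final$lengths)))
  invisible(x)
}

#' Replicated greedy descents from random starts
#'
#' Runs `n_replicates` greedy descents, each from a fresh random
#' segmentation (geometric lengths, mean `mean_len`). All replicate initial
#' segmentations are generated from one stream seeded by `master_seed`, so
#' the whole set is reproducible from that one seed. The replicate scores
#' are aggregated by their median by default (even counts: mean of the two
#' central values); `"best"` (minimum) and `"mean"` are also available.
#'
#' @inheritParams greedy_descent
#' @param n_replicates Number of random starting segmentations.
#' @param master_seed Integer seed controlling all replicate starts.
#' @param aggregator How to turn replicate scores into one objective value.
#' @param mean_len Mean of the geometric initial segment lengths.
#' @param keep_results Keep the full per-replicate results (set `FALSE` to
#'   save memory in long training loops).
#' @return A `replicate_set`: list with `score` (aggregated), `aggregator`,
#'   `scores` (per replicate), `best` (best-scoring replicate's
#'   `scored_segmentation`), and `results` (list of `scored_segmentation`s,
#'   if kept).
#' @export
run_replicates <- function(expr, f, g, n_replicates = 1024L, master_seed = 1L,
                           aggregator = c("median", "best", "mean"),
                           mean_len = 2, n_free_dist_params = 1, eps = 1e-9,
                           max_iter = 100000L, arm_id = NULL,
                           keep_results = TRUE) {
  aggregator <- arg_match(aggregator)
  f <- as_mixture_params(f)
  g <- check_scoring_sigma(as_deviation_params(g))
  m <- expr_matrix(expr)
  if (n_replicates < 1L) abort("`n_replicates` must be >= 1.")
  n_data <- nrow(m) * ncol(m)

  inits <- with_seed(master_seed, {
    lapply(seq_len(n_replicates), function(i) random_segmentation(nrow(m), mean_len))
  })
  res <- run_replicates_cpp(m, inits, f$phi, f$mu1, f$sigma1, f$mu2, f$sigma2,
                            g$sigma, log(n_data), eps, max_iter,
                            n_free_dist_params)
  scores <- res$score
  agg <- switch(aggregator,
                median = median(scores),
                best = min(scores),
                mean = mean(scores))
  make_scored <- function(i) {
    new_scored_segmentation(
      lengths = res$lengths[[i]], loglik = res$loglik[i],
      K = length(res$lengths[[i]]) + n_free_dist_params, n_data = n_data,
      score = scores[i], arm_id = arm_id, sigma = g$sigma,
      n_iterations = res$n_iterations[i]
    )
  }
  best_i <- which.min(scores)
  structure(
    list(score = agg, aggregator = aggregator, scores = scores,
         best = make_scored(best_i),
         results = if (keep_results) lapply(seq_len(n_replicates), make_scored),
         n_replicates = n_replicates, master_seed = master_seed),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("%d greedy replicates: %s score %.4f (best %.4f, worst %.4f)\n",
              x$n_replicates, x$aggregator, x$score, min(x$scores),
              max(x$scores)))
  invisible(x)
}

#' Exact optimal segmentation by dynamic programming
#'
#' Finds the global minimum-BIC segmentation of an arm. The per-segment
#' score contribution (`-2` times the segment log marginal plus one `log(n)`
#' penalty) is additive over segments, so an `O(G^2)`-evaluation partition
#' dynamic program is exact. Practical for arms up to a few hundred genes;
#' used as the gold standard against which the greedy search is checked.
#'
#' @inheritParams greedy_descent
#' @return A `scored_segmentation`.
#' @export
dp_optimal_segmentation <- function(expr, f, g, n_free_dist_params = 1,
                                    arm_id = NULL) {
  f <- as_mixture_params(f)
  g <- check_scoring_sigma(as_deviation_params(g))
  m <- expr_matrix(expr)
  n_data <- nrow(m) * ncol(m)
  res <- dp_optimal_cpp(m, f$phi, f$mu1, f$sigma1, f$mu2, f$sigma2, g$sigma,
                        log(n_data), n_free_dist_params)
  new_scored_segmentation(
    lengths = res$lengths, loglik = res$loglik,
    K = length(res$lengths) + n_free_dist_params, n_data = n_data,
    score = res$score, arm_id = arm_id, sigma = g$sigma
  )
}

#' Agreement between replicate segmentations
#'
#' Measures how consistently independent greedy replicates land on the same
#' segmentation: the fraction of the best-scoring replicate's internal
#' boundaries (intersegment regions) shared with the second-best and with
#' the worst replicate, and the fraction of distinct segments (identified by
#' their gene spans) seen in any replicate that occur in more than half of
#' the replicates.
#'
#' @param results A `replicate_set` from [run_replicates()] (with results
#'   kept), or a list of `scored_segmentation` objects.
#' @return A one-row tibble with `shared_best_second`, `shared_best_worst`,
#'   `segments_majority_fraction`, `n_replicates`.
#' @export
replicate_agreement <- function(results) {
  if (inherits(results, "replicate_set")) {
    if (is.null(results$results)) {
      abort("replicate results were not kept; rerun with `keep_results = TRUE`.")
    }
    results <- results$results
  }
  if (length(results) < 2L) abort("need at least 2 replicates.")
  scores <- vapply(results, function(r) r$score, numeric(1))
  ord <- order(scores)
  bounds <- lapply(results, function(r) segment_boundaries(r$lengths))
  shared <- function(a, b) {
    if (!length(a)) return(NA_real_)
    length(intersect(a, b)) / length(a)
  }
  segs <- lapply(results, function(r) {
    ends <- cumsum(r$lengths)
    paste(c(1L, head(ends, -1L) + 1L), ends, sep = "-")
  })
  all_segs <- unique(unlist(segs))
  counts <- vapply(all_segs, function(sg) {
    sum(vapply(segs, function(s) sg %in% s, logical(1)))
  }, numeric(1))
  tibble(
    shared_best_second = shared(bounds[[ord[1]]], bounds[[ord[2]]]),
    shared_best_worst = shared(bounds[[ord[1]]], bounds[[ord[length(ord)]]]),
    segments_majority_fraction = mean(counts > length(results) / 2),
    n_replicates = length(results)
  )
}
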