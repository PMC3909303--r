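#' Simulate a segmented expression dataset
#'
#' Generates one synthetic chromosome arm under the generative model the
#' segmentation method assumes. Segment lengths are drawn from a geometric
#' distribution with mean `mean_len` until all genes are assigned (the last
#' segment is truncated); for each segment and tissue a segment effect is
#' drawn from the mixture `f`; and each gene adds an independent
#' `N(0, g$sigma^2)` deviation to its segment's effect. In heteroscedastic
#' mode an independent deviation sd accompanies every effect draw, sampled
#' from a log-normal with median `g$sigma` and geometric sd `sigma_spread`.
#'
#' The default `f` (`phi = 0.4`, components `N(3.5, 1.2^2)` and
#' `N(7.5, 1.8^2)`) and `g` (`sigma = 0.6`) give a bimodal log-scale
#' expression distribution of the kind seen in multi-tissue microarray
#' atlases.
#'
#' @param n_genes,n_tissues Dimensions of the simulated arm.
#' @param mean_len Mean of the geometric segment-length distribution.
#' @param f Segment-effect distribution ([mixture_params()]).
#' @param g Gene-deviation distribution ([deviation_params()]).
#' @param heteroscedastic Draw an independent deviation sd per
#'   (segment, tissue)?
#' @param sigma_spread Geometric sd of the per-draw deviation sd in
#'   heteroscedastic mode.
#' @param seed Optional seed (caller's RNG state is restored).
#' @param arm_id Arm identifier for the generated matrix.
#'
#' @return A `simulated_dataset`: list with `truth` (segment lengths),
#'   `effects` (segments x tissues matrix of effect draws), `sigma_truth`
#'   (the generating sd, or a segments x tissues matrix in heteroscedastic
#'   mode), `expr` (tibble: `gene_id` plus one column per tissue), `matrix`
#'   (the same values as a matrix), and the generating parameters.
#' @examples
#' sim <- simulate_dataset(60, 4, seed = 1)
#' sim$truth
#' @export
simulate_dataset <- function(n_genes, n_tissues, mean_len = 2,
                             f = mixture_params(0.4, 3.5, 1.2, 7.5, 1.8),
                             g = deviation_params(0.6),
                             heteroscedastic = FALSE, sigma_spread = 1.5,
                             seed = NULL, arm_id = "sim") {
  stopifnot_scalar_number(n_genes, "n_genes", 1)
  stopifnot_scalar_number(n_tissues, "n_tissues", 1)
  f <- as_mixture_params(f)
  g <- as_deviation_params(g)
  n_genes <- as.integer(n_genes)
  n_tissues <- as.integer(n_tissues)

  with_seed(seed, {
    truth <- random_segmentation(n_genes, mean_len)
    nseg <- length(truth)
    comp <- matrix(runif(nseg * n_tissues) >= f$phi, nseg, n_tissues)
    effects <- matrix(rnorm(nseg * n_tissues,
                            mean = ifelse(comp, f$mu2, f$mu1),
                            sd = ifelse(comp, f$sigma2, f$sigma1)),
                      nseg, n_tissues)
    sig <- if (heteroscedastic) {
      matrix(rlnorm(nseg * n_tissues, meanlog = log(g$sigma),
                    sdlog = log(sigma_spread)), nseg, n_tissues)
    } else {
      g$sigma
    }
    seg_of_gene <- rep.int(seq_len(nseg), truth)
    dev_sd <- if (heteroscedastic) sig[seg_of_gene, , drop = FALSE]
              else matrix(g$sigma, n_genes, n_tissues)
    deviations <- matrix(rnorm(n_genes * n_tissues, 0, dev_sd),
                         n_genes, n_tissues)
    values <- effects[seg_of_gene, , drop = FALSE] + deviations

    gene_ids <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
    tissue_ids <- sprintf("tissue%02d", seq_len(n_tissues))
    dimnames(values) <- list(gene_ids, tissue_ids)
    expr <- bind_cols(tibble(gene_id = gene_ids), as_tibble(values))

    structure(
      list(truth = truth, effects = effects, sigma_truth = sig,
           expr = expr, matrix = values, f = f, g = g,
           heteroscedastic = heteroscedastic, mean_len = mean_len,
           arm_id = arm_id, seed = seed),
      class = "simulated_dataset"
    )
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated arm '%s': %d genes x %d tissues in %d segments%s\n",
    x$arm_id, nrow(x$matrix), ncol(x$matrix), length(x$truth),
    if (x$heteroscedastic) " (heteroscedastic deviations)" else ""))
  invisible(x)
}

#' Compare an inferred segmentation with the generating truth
#'
#' Boundary-level precision, recall and F1 over internal segment boundaries,
#' an exact-match flag, and a Rand index over the induced gene partitions
#' (the probability that a random gene pair is classified consistently —
#' same segment in both or different segments in both).
#'
#' Edge convention: an empty boundary set makes its ratio vacuously 1
#' (no internal truth boundaries: recall 1; no inferred boundaries:
#' precision 1), so two boundary-free segmentations score 1 throughout.
#'
#' @param inferred,truth Integer vectors of segment lengths over the same
#'   genes (a `scored_segmentation` is also accepted for `inferred`).
#' @return A one-row tibble: `precision`, `recall`, `f1`, `exact`,
#'   `rand_index`, `n_inferred`, `n_truth`.
#' @export
score_against_truth <- function(inferred, truth) {
  if (inherits(inferred, "scored_segmentation")) inferred <- inferred$lengths
  if (inherits(truth, "simulated_dataset")) truth <- truth$truth
  inferred <- as.integer(inferred)
  truth <- as.integer(truth)
  if (sum(inferred) != sum(truth)) {
    abort("segmentations cover different numbers of genes.")
  }
  bi <- segment_boundaries(inferred)
  bt <- segment_boundaries(truth)
  tp <- length(intersect(bi, bt))
  precision <- if (length(bi)) tp / length(bi) else 1
  recall <- if (length(bt)) tp / length(bt) else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0

  # Rand index from per-cluster pair counts
  n <- sum(truth)
  pairs <- function(k) k * (k - 1) / 2
  a_i <- rep.int(seq_along(inferred), inferred)
  b_i <- rep.int(seq_along(truth), truth)
  tab <- table(a_i, b_i)
  together_both <- sum(pairs(tab))
  together_a <- sum(pairs(inferred))
  together_b <- sum(pairs(truth))
  total <- pairs(n)
  rand <- if (total > 0) {
    (total + 2 * together_both - together_a - together_b) / total
  } else 1

  tibble(
    precision = precision, recall = recall, f1 = f1,
    exact = identical(bi, bt), rand_index = rand,
    n_inferred = length(inferred), n_truth = length(truth)
  )
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix as TSV, the truth segmentation as a BED file
#' over gene indices (0-based half-open), and a parameter manifest.
#'
#' @param sim A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  if (!inherits(sim, "simulated_dataset")) abort("`sim` must be a simulated_dataset.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(sim$expr, file.path(dir, "matrix.tsv"))
  ends <- cumsum(sim$truth)
  starts <- c(0L, head(ends, -1L))
  readr::write_tsv(
    tibble(chrom = sim$arm_id, start = starts, end = ends,
           name = sprintf("segment_%03d", seq_along(ends))),
    file.path(dir, "truth_segments.bed"), col_names = FALSE)
  manifest <- list(
    arm_id = sim$arm_id, n_genes = nrow(sim$matrix),
    n_tissues = ncol(sim$matrix), mean_len = sim$mean_len,
    heteroscedastic = sim$heteroscedastic, seed = sim$seed,
    f = unclass(sim$f),
    g_sigma = if (is.matrix(sim$sigma_truth)) "heteroscedastic" else sim$sigma_truth
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
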