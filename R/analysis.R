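#' Per-segment expression profiles
#'
#' A segment's expression value in a tissue is the arithmetic mean of its
#' component genes' values in that tissue; the across-tissue mean and
#' (sample) standard deviation of those per-tissue values summarise the
#' segment's breadth of expression.
#'
#' @inheritParams segmentation_loglik
#' @return A `segment_profiles` tibble: `segment`, `n_genes`, one column per
#'   tissue (the per-tissue segment values), `across_tissue_mean`,
#'   `across_tissue_sd`.
#' @export
segment_profiles <- function(expr, lengths) {
  m <- expr_matrix(expr)
  if (is.null(colnames(m))) colnames(m) <- paste0("tissue", seq_len(ncol(m)))
  lengths <- check_lengths(lengths, nrow(m))
  seg <- rep.int(seq_along(lengths), lengths)
  means <- rowsum(m, seg, reorder = TRUE) / as.vector(lengths)
  rownames(means) <- NULL
  per_tissue <- as_tibble(means, .name_repair = "minimal")
  out <- bind_cols(
    tibble(segment = seq_along(lengths), n_genes = as.integer(lengths)),
    per_tissue
  )
  out$across_tissue_mean <- rowMeans(means)
  out$across_tissue_sd <- apply(means, 1L, sd)
  class(out) <- c("segment_profiles", class(out))
  attr(out, "tissues") <- colnames(m)
  attr(out, "dataset_median") <- median(m)
  out
}

#' Classify segments as housekeeping-like or tissue-restricted
#'
#' Only segments with at least `min_genes` genes are classified. Segments in
#' the top quartile of across-tissue standard deviation are
#' tissue-restricted candidates (ties at the cutoff are included); the rest
#' are housekeeping-like. For each segment, `restricted_tissues` lists the
#' tissues in which the segment value exceeds the dataset-wide median gene
#' expression value; a candidate expressed above the median in exactly one
#' tissue is flagged `single_tissue`.
#'
#' @param profiles A `segment_profiles` tibble from [segment_profiles()].
#' @param dataset_median Dataset-wide median of gene-level expression values;
#'   defaults to the value recorded by [segment_profiles()].
#' @param min_genes Minimum genes for a segment to be classified (default 3).
#' @return The profiles of eligible segments with added columns `class`
#'   (`"tissue-restricted"` or `"housekeeping-like"`), `restricted_tissues`
#'   (list column), `n_restricted_tissues` and `single_tissue`.
#' @export
classify_segments <- function(profiles, dataset_median = NULL, min_genes = 3L) {
  if (!inherits(profiles, "segment_profiles")) {
    abort("`profiles` must come from segment_profiles().")
  }
  if (is.null(dataset_median)) dataset_median <- attr(profiles, "dataset_median")
  if (is.null(dataset_median)) abort("`dataset_median` is required.")
  tissues <- attr(profiles, "tissues")
  eligible <- profiles[profiles$n_genes >= min_genes, , drop = FALSE]
  if (nrow(eligible) < 4L) {
    abort(sprintf("only %d segments with >= %d genes: top quartile undefined.",
                  nrow(eligible), min_genes))
  }
  cutoff <- quantile(eligible$across_tissue_sd, 0.75, names = FALSE)
  vals <- as.matrix(eligible[tissues])
  restricted <- lapply(seq_len(nrow(eligible)), function(i) {
    tissues[vals[i, ] > dataset_median]
  })
  eligible$class <- ifelse(eligible$across_tissue_sd >= cutoff,
                           "tissue-restricted", "housekeeping-like")
  eligible$restricted_tissues <- restricted
  eligible$n_restricted_tissues <- lengths(restricted)
  eligible$single_tissue <- eligible$class == "tissue-restricted" &
    eligible$n_restricted_tissues == 1L
  attr(eligible, "sd_cutoff") <- cutoff
  attr(eligible, "dataset_median") <- dataset_median
  attr(eligible, "tissues") <- tissues
  eligible
}

#' Compare within-segment and between-segment intergenic lengths
#'
#' Two-sample Kolmogorov-Smirnov test of the length distributions of
#' intergenic regions inside segments versus intersegment regions.
#'
#' @param within Numeric vector: lengths of intra-segment intergenic regions.
#' @param between Numeric vector: lengths of intersegment regions.
#' @return A one-row tibble: `statistic` (the KS D), `p_value`,
#'   `median_within`, `median_between`.
#' @export
compare_intergenic_lengths <- function(within, between) {
  if (!length(within) || !length(between)) {
    abort("both samples must be non-empty.")
  }
  ks <- suppressWarnings(ks.test(within, between))
  tibble(
    statistic = unname(ks$statistic), p_value = ks$p.value,
    median_within = median(within), median_between = median(between),
    n_within = length(within), n_between = length(between)
  )
}

#' Mark intergenic regions as within-segment or intersegment
#'
#' The intergenic region after gene `i` (between starts of genes `i` and
#' `i + 1`) is an intersegment region exactly when `i` is an internal
#' segment boundary.
#'
#' @param regions Intergenic regions of one arm, in gene order, from
#'   [intergenic_regions()].
#' @param lengths Segment lengths on the same arm.
#' @return `regions` with added columns `intersegment` (logical),
#'   `upstream_segment` and `downstream_segment` (segment indices flanking
#'   the region).
#' @export
mark_intersegment <- function(regions, lengths) {
  lengths <- check_lengths(lengths, nrow(regions) + 1L)
  bounds <- segment_boundaries(lengths)
  seg_of_gene <- rep.int(seq_along(lengths), lengths)
  i <- seq_len(nrow(regions))
  regions$intersegment <- i %in% bounds
  regions$upstream_segment <- seg_of_gene[i]
  regions$downstream_segment <- seg_of_gene[i + 1L]
  regions
}

#' Classify the relative orientation of an adjacent gene pair
#'
#' With genes ordered by transcription start: a pair is head-to-head
#' (divergent) when the upstream gene is on the minus strand and the
#' downstream gene on the plus strand; tail-to-tail (convergent) when the
#' reverse; otherwise the two genes read in the same orientation.
#'
#' @param upstream,downstream Strand characters (`"+"` or `"-"`); vectors.
#' @return Character vector: `"same"`, `"head-to-head"`, `"tail-to-tail"`,
#'   or `NA` for undefined strands.
#' @export
classify_orientation <- function(upstream, downstream) {
  out <- rep(NA_character_, length(upstream))
  ok <- upstream %in% c("+", "-") & downstream %in% c("+", "-")
  out[ok & upstream == downstream] <- "same"
  out[ok & upstream == "-" & downstream == "+"] <- "head-to-head"
  out[ok & upstream == "+" & downstream == "-"] <- "tail-to-tail"
  out
}

#' Orientation composition test between two pair classes
#'
#' Counts adjacent gene pairs by orientation (same / head-to-head /
#' tail-to-tail) within each pair class, and compares two requested classes
#' with a 2x3 chi-squared test (no continuity correction). Pairs with
#' undefined strand are excluded and reported.
#'
#' @param pairs Tibble with columns `upstream_strand`, `downstream_strand`
#'   and `class` (for example `"within-two-gene-segment"`,
#'   `"within-longer-segment"`, `"intersegment"`).
#' @param classes Length-2 character vector: the two classes to compare.
#'   Default compares the first two classes present.
#' @return A list with `counts` (tibble of per-class orientation counts over
#'   all classes), `table` (the 2x3 matrix tested), `statistic`, `df`,
#'   `p_value`, `n_excluded`.
#' @export
orientation_test <- function(pairs, classes = NULL) {
  need <- c("upstream_strand", "downstream_strand", "class")
  if (!all(need %in% names(pairs))) {
    abort(paste("`pairs` needs columns:", paste(need, collapse = ", ")))
  }
  ori <- classify_orientation(pairs$upstream_strand, pairs$downstream_strand)
  n_excluded <- sum(is.na(ori))
  keep <- !is.na(ori)
  df <- tibble(class = pairs$class[keep],
               orientation = factor(ori[keep],
                                    levels = c("same", "head-to-head",
                                               "tail-to-tail")))
  counts <- df %>%
    dplyr::count(.data$class, .data$orientation, .drop = FALSE) %>%
    tidyr::pivot_wider(names_from = "orientation", values_from = "n",
                       values_fill = 0L)
  if (is.null(classes)) classes <- head(unique(df$class), 2L)
  if (length(classes) != 2L || !all(classes %in% counts$class)) {
    abort("`classes` must name two pair classes present in the data.")
  }
  tab <- as.matrix(counts[match(classes, counts$class),
                          c("same", "head-to-head", "tail-to-tail")])
  rownames(tab) <- classes
  test <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(counts = counts, table = tab,
       statistic = unname(test$statistic), df = unname(test$parameter),
       p_value = test$p.value, n_excluded = n_excluded)
}

#' Endpoint sharing between segments and interaction domains
#'
#' Classifies every intergenic region by whether it is a segment endpoint
#' (intersegment region) and whether it is an interaction-domain endpoint,
#' and tests the association with a two-sided Fisher exact test on the 2x2
#' table (both / segment only / domain only / neither).
#'
#' @param is_segment_endpoint,is_domain_endpoint Logical vectors over the
#'   same intergenic regions.
#' @return A list with `table` (2x2 matrix), `p_value` (two-sided Fisher),
#'   `odds_ratio`, and `shared_fraction` (fraction of domain endpoints that
#'   are also segment endpoints).
#' @export
endpoint_sharing_test <- function(is_segment_endpoint, is_domain_endpoint) {
  if (length(is_segment_endpoint) != length(is_domain_endpoint)) {
    abort("endpoint flags must have equal length.")
  }
  if (anyNA(is_segment_endpoint) || anyNA(is_domain_endpoint)) {
    abort("endpoint flags must not contain NA.")
  }
  seg <- factor(is_segment_endpoint, levels = c(TRUE, FALSE))
  dom <- factor(is_domain_endpoint, levels = c(TRUE, FALSE))
  tab <- table(segment = seg, domain = dom)
  ft <- fisher.test(tab, alternative = "two.sided")
  shared <- if (sum(is_domain_endpoint) > 0) {
    sum(is_segment_endpoint & is_domain_endpoint) / sum(is_domain_endpoint)
  } else NA_real_
  list(table = unclass(tab), p_value = ft$p.value,
       odds_ratio = unname(ft$estimate), shared_fraction = shared)
}

# Count, for each interval set, how many peaks overlap it by >= 1 bp.
# A peak is counted once per region set even if it overlaps several regions.
count_overlapping_peaks <- function(regions, peaks) {
  hit <- rep(FALSE, nrow(peaks))
  for (a in unique(regions$arm)) {
    p <- which(peaks$arm == a)
    r <- regions[regions$arm == a, , drop = FALSE]
    if (!length(p) || !nrow(r)) next
    # overlap of half-open intervals: begin < r_end and end > r_begin
    for (j in seq_len(nrow(r))) {
      hit[p] <- hit[p] |
        (peaks$begin[p] < r$end[j] & peaks$end[p] > r$begin[j])
    }
  }
  sum(hit)
}

#' Peak density enrichment between two region sets
#'
#' Counts ChIP peaks overlapping (by at least 1 bp) each of two interval
#' sets, converts the counts to peaks per kilobase of total region span, and
#' reports their ratio together with a two-sided Fisher exact test. The 2x2
#' table rows are `[peak count, non-peak count]` per region set, where the
#' non-peak count expresses the remaining bases in peak-sized units:
#' `(region bases - peak count * mean peak length) / mean peak length`,
#' rounded to the nearest integer (floored at 0). The literal alternative
#' `(region bases - peak count) / mean peak length` is available with
#' `nonpeak_rule = "literal"`.
#'
#' @param regions_a,regions_b Interval tibbles (`arm`, `begin`, `end`).
#' @param peaks Peak interval tibble (`arm`, `begin`, `end`).
#' @param mask Optional interval tibble; peaks overlapping any mask interval
#'   are removed before counting (for example 2 kb windows centred on
#'   interaction-domain boundaries, see [boundary_windows()]).
#' @param nonpeak_rule How to derive the non-peak count (see above).
#' @return A one-row tibble: `peaks_a`, `peaks_b`, `kb_a`, `kb_b`,
#'   `density_a`, `density_b`, `enrichment`, `p_value`, `n_peaks_masked`.
#' @export
peak_enrichment <- function(regions_a, regions_b, peaks, mask = NULL,
                            nonpeak_rule = c("peak-units", "literal")) {
  nonpeak_rule <- arg_match(nonpeak_rule)
  for (nm in list(regions_a, regions_b, peaks)) {
    if (!all(c("arm", "begin", "end") %in% names(nm))) {
      abort("interval tibbles need `arm`, `begin`, `end` columns.")
    }
  }
  if (nrow(regions_a) == 0L || nrow(regions_b) == 0L) {
    abort("region sets must be non-empty.")
  }
  n_masked <- 0L
  if (!is.null(mask) && nrow(mask) > 0L && nrow(peaks) > 0L) {
    masked <- vapply(seq_len(nrow(peaks)), function(i) {
      any(mask$arm == peaks$arm[i] & mask$begin < peaks$end[i] &
            mask$end > peaks$begin[i])
    }, logical(1))
    n_masked <- sum(masked)
    peaks <- peaks[!masked, , drop = FALSE]
  }
  bases_a <- sum(regions_a$end - regions_a$begin)
  bases_b <- sum(regions_b$end - regions_b$begin)
  if (bases_a == 0 || bases_b == 0) abort("zero-length region set.")
  count_a <- count_overlapping_peaks(regions_a, peaks)
  count_b <- count_overlapping_peaks(regions_b, peaks)
  density_a <- count_a / (bases_a / 1000)
  density_b <- count_b / (bases_b / 1000)
  enrichment <- if (count_a == 0 && count_b == 0) NA_real_
                else density_a / density_b
  mean_peak <- if (nrow(peaks) > 0) mean(peaks$end - peaks$begin) else NA_real_
  if (is.na(mean_peak) || mean_peak <= 0) {
    p_value <- NA_real_
  } else {
    nonpeak <- function(bases, count) {
      raw <- if (nonpeak_rule == "peak-units") {
        (bases - count * mean_peak) / mean_peak
      } else {
        (bases - count) / mean_peak
      }
      max(0L, as.integer(round(raw)))
    }
    tab <- matrix(c(count_a, nonpeak(bases_a, count_a),
                    count_b, nonpeak(bases_b, count_b)),
                  nrow = 2L, byrow = TRUE)
    p_value <- fisher.test(tab, alternative = "two.sided")$p.value
  }
  tibble(
    peaks_a = count_a, peaks_b = count_b,
    kb_a = bases_a / 1000, kb_b = bases_b / 1000,
    density_a = density_a, density_b = density_b,
    enrichment = enrichment, p_value = p_value,
    n_peaks_masked = n_masked
  )
}

#' Windows centred on interval boundaries
#'
#' Builds fixed-width windows centred on the begin and end coordinate of
#' each interval (for example interaction-domain boundaries), to be used as
#' a peak mask in [peak_enrichment()].
#'
#' @param intervals Interval tibble (`arm`, `begin`, `end`).
#' @param width Total window width in bases (default 2000, i.e. +/- 1 kb).
#' @return An interval tibble with `label = "boundary-windows"`.
#' @export
boundary_windows <- function(intervals, width = 2000) {
  half <- width / 2
  pts <- c(intervals$begin, intervals$end)
  arms <- c(intervals$arm, intervals$arm)
  tibble(arm = arms, begin = pmax(0, pts - half), end = pts + half,
         label = "boundary-windows")
}

#' Shuffle a segmentation preserving its length multiset
#'
#' Randomly permutes the list of segment lengths (keeping gene order fixed)
#' and resamples until the shuffled segmentation shares no internal boundary
#' with the original. Fails explicitly when no valid shuffle is found within
#' `max_tries` (for example when all lengths are equal, where every
#' permutation reproduces every boundary).
#'
#' @param lengths Integer vector of segment lengths (>= 2 segments).
#' @param max_tries Attempts before giving up.
#' @return A permuted lengths vector whose internal boundaries are disjoint
#'   from the input's.
#' @export
shuffle_segmentation <- function(lengths, max_tries = 10000L) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 2L) abort("need >= 2 segments to shuffle.")
  orig <- segment_boundaries(lengths)
  for (i in seq_len(max_tries)) {
    perm <- sample(lengths)
    if (!length(intersect(segment_boundaries(perm), orig))) return(perm)
  }
  abort(sprintf(
    "no boundary-disjoint permutation found in %d tries (all lengths equal?).",
    max_tries))
}

#' Per-segment term enrichment with a shuffled-segmentation null
#'
#' For every multigenic segment and every annotation term present in it,
#' tests over-representation of the term among the segment's genes against
#' the genome-wide background with a hypergeometric upper-tail test,
#' Bonferroni-corrected within the segment. Significant results where only
#' one gene in the segment carries the term are removed. The count of
#' segments with at least one enriched term is then compared with the
#' pooled count over `n_shuffles` shuffled segmentations
#' ([shuffle_segmentation()]) by a two-sided Fisher exact test.
#'
#' @param lengths Segment lengths over the arm's genes, in gene order.
#' @param gene_ids Character vector of gene ids in chromosome order
#'   (`sum(lengths)` long).
#' @param gene_terms Tibble with columns `gene_id`, `term` (one row per
#'   annotation; genes may be unannotated).
#' @param alpha Significance level before Bonferroni correction.
#' @param n_shuffles Number of shuffled segmentations for the null.
#' @param seed Optional seed for the shuffles.
#' @return A list with `enriched` (tibble: `segment`, `term`, `k` genes with
#'   the term in the segment, `n` annotated segment genes, `K` genes with
#'   the term genome-wide, `N` annotated genes genome-wide, `p_value`,
#'   `p_adjusted`), `n_segments_enriched`, `null_segments_enriched` (pooled
#'   over shuffles), `n_shuffles`, `fisher_p`.
#' @export
term_enrichment <- function(lengths, gene_ids, gene_terms, alpha = 0.05,
                            n_shuffles = 10L, seed = NULL) {
  lengths <- check_lengths(lengths, length(gene_ids))
  if (!all(c("gene_id", "term") %in% names(gene_terms)) ||
      nrow(gene_terms) == 0L) {
    abort("`gene_terms` must be a non-empty tibble with `gene_id` and `term`.")
  }
  gene_terms <- distinct(gene_terms, .data$gene_id, .data$term)
  gene_terms <- gene_terms[gene_terms$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(gene_terms) == 0L) abort("no annotated genes on the arm.")
  annotated <- unique(gene_terms$gene_id)
  N <- length(annotated)
  term_sizes <- table(gene_terms$term)

  enrich_one <- function(lens) {
    seg_of_gene <- rep.int(seq_along(lens), lens)
    names(seg_of_gene) <- gene_ids
    rows <- list()
    for (s in which(lens >= 2L)) {
      genes_s <- gene_ids[seg_of_gene == s]
      ann_s <- gene_terms[gene_terms$gene_id %in% genes_s, , drop = FALSE]
      n_s <- length(intersect(genes_s, annotated))
      if (n_s == 0L) next
      terms_s <- table(ann_s$term)
      n_tests <- length(terms_s)
      for (tm in names(terms_s)) {
        k <- as.integer(terms_s[[tm]])
        K <- as.integer(term_sizes[[tm]])
        p <- phyper(k - 1L, K, N - K, n_s, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- tibble(
          segment = s, term = tm, k = k, n = n_s, K = K, N = N,
          p_value = p, p_adjusted = min(1, p * n_tests)
        )
      }
    }
    res <- if (length(rows)) bind_rows(rows) else
      tibble(segment = integer(), term = character(), k = integer(),
             n = integer(), K = integer(), N = integer(),
             p_value = numeric(), p_adjusted = numeric())
    # significant, and supported by more than one annotated gene
    res[res$p_adjusted < alpha & res$k >= 2L, , drop = FALSE]
  }

  enriched <- enrich_one(lengths)
  n_enriched <- length(unique(enriched$segment))
  n_segments <- length(lengths)

  null_counts <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      sh <- shuffle_segmentation(lengths)
      length(unique(enrich_one(sh)$segment))
    }, numeric(1))
  })
  null_enriched <- sum(null_counts)
  tab <- matrix(c(n_enriched, n_segments - n_enriched,
                  null_enriched, n_shuffles * n_segments - null_enriched),
                nrow = 2L, byrow = TRUE)
  fisher_p <- fisher.test(tab, alternative = "two.sided")$p.value
  list(enriched = enriched, n_segments_enriched = n_enriched,
       null_segments_enriched = null_enriched, n_shuffles = n_shuffles,
       n_segments = n_segments, fisher_p = fisher_p)
}
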