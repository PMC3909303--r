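test_that("segment profiles are per-tissue gene means with across-tissue stats", {
  m <- matrix(c(1, 3, 5, 7,
                2, 4, 6, 8), nrow = 4)
  colnames(m) <- c("ta", "tb")
  prof <- segment_profiles(m, c(2L, 1L, 1L))
  expect_equal(prof$ta, c(2, 5, 7))   # mean(1,3), then singletons
  expect_equal(prof$tb, c(3, 6, 8))
  expect_equal(prof$across_tissue_mean, c(2.5, 5.5, 7.5))
  expect_equal(prof$across_tissue_sd, rep(sd(c(0, 1)) * 1, 3))
  # constant matrix -> all SDs zero
  prof0 <- segment_profiles(matrix(4, 6, 3), c(3L, 3L))
  expect_equal(prof0$across_tissue_sd, c(0, 0))
})

test_that("profiles match a two-pass oracle and merge as weighted means", {
  set.seed(12)
  m <- matrix(rnorm(60, 5, 2), nrow = 12)
  colnames(m) <- paste0("t", 1:5)
  lengths <- c(3L, 1L, 5L, 3L)
  prof <- segment_profiles(m, lengths)
  seg <- rep.int(seq_along(lengths), lengths)
  for (s in seq_along(lengths)) {
    vals <- colMeans(m[seg == s, , drop = FALSE])
    expect_equal(unlist(prof[s, paste0("t", 1:5)]), vals, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(prof$across_tissue_mean[s], mean(vals), tolerance = 1e-12)
    expect_equal(prof$across_tissue_sd[s], sd(vals), tolerance = 1e-12)
  }
  # tissue reordering leaves means/SDs unchanged
  prof_perm <- segment_profiles(m[, c(3, 1, 5, 2, 4)], lengths)
  expect_equal(prof_perm$across_tissue_mean, prof$across_tissue_mean)
  expect_equal(prof_perm$across_tissue_sd, prof$across_tissue_sd)
  # merged segment = gene-count-weighted mean of the parts
  merged <- segment_profiles(m, c(4L, 5L, 3L))
  w <- (3 * unlist(prof[1, paste0("t", 1:5)]) +
          1 * unlist(prof[2, paste0("t", 1:5)])) / 4
  expect_equal(unlist(merged[1, paste0("t", 1:5)]), w, tolerance = 1e-12)
})

test_that("classification finds planted tissue-restricted segments", {
  # 8 segments x 4 tissues; plant 2 with one high-tissue spike
  tissues <- paste0("t", 1:4)
  base <- matrix(1, 8, 4)
  base[1, ] <- c(9, 1, 1, 1)    # restricted to t1
  base[2, ] <- c(1, 8, 8, 1)    # high sd, two tissues above median
  m <- base[rep(1:8, each = 3), ]  # 3 genes per segment, constant in segment
  colnames(m) <- tissues
  prof <- segment_profiles(m, rep(3L, 8))
  cls <- classify_segments(prof)
  expect_equal(sum(cls$class == "tissue-restricted"), 2)
  expect_true(all(which(cls$class == "tissue-restricted") %in% c(1, 2)))
  expect_true(cls$single_tissue[1])
  expect_false(cls$single_tissue[2])
  expect_equal(cls$restricted_tissues[[1]], "t1")
  # segments below min_genes are excluded from classification
  prof2 <- segment_profiles(rbind(m, m[1:2, ]), c(rep(3L, 8), 2L))
  cls2 <- classify_segments(prof2, min_genes = 3)
  expect_equal(nrow(cls2), 8)
  # all-identical SDs: ties at the cutoff are included
  profc <- segment_profiles(matrix(rep(c(1, 5), each = 12), 12, 2), rep(3L, 4))
  clsc <- classify_segments(profc)
  expect_true(all(clsc$class == "tissue-restricted"))
  expect_error(classify_segments(segment_profiles(m[1:9, ], rep(3L, 3))),
               "quartile")
})

test_that("intergenic KS comparison matches an ECDF gap oracle", {
  ident <- compare_intergenic_lengths(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  disj <- compare_intergenic_lengths(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disj$statistic, 1)
  set.seed(13)
  a <- rexp(20, 1 / 50)
  b <- rexp(20, 1 / 200)
  got <- compare_intergenic_lengths(a, b)
  expect_equal(got$statistic, ks_stat_oracle(a, b), tolerance = 1e-12)
  expect_error(compare_intergenic_lengths(numeric(0), b), "non-empty")
})

test_that("intersegment marking follows the segmentation boundaries", {
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                          start = c(0, 100, 250, 400, 600, 900))
  reg <- mark_intersegment(intergenic_regions(genes), c(2L, 3L, 1L))
  expect_equal(reg$intersegment, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(reg$upstream_segment, c(1, 1, 2, 2, 2))
  expect_equal(reg$downstream_segment, c(1, 2, 2, 2, 3))
})

test_that("pair orientations follow the strand definitions", {
  expect_equal(classify_orientation("+", "+"), "same")
  expect_equal(classify_orientation("-", "-"), "same")
  expect_equal(classify_orientation("-", "+"), "head-to-head")
  expect_equal(classify_orientation("+", "-"), "tail-to-tail")
  expect_true(is.na(classify_orientation(".", "+")))
})

test_that("the 2x3 orientation test matches the textbook chi-squared formula", {
  pairs <- tibble::tibble(
    upstream_strand = c(rep("+", 30), rep("-", 20), rep("+", 25),
                        rep("+", 40), rep("-", 10), rep("+", 15)),
    downstream_strand = c(rep("+", 30), rep("+", 20), rep("-", 25),
                          rep("+", 40), rep("+", 10), rep("-", 15)),
    class = c(rep("within", 75), rep("between", 65))
  )
  res <- orientation_test(pairs, classes = c("within", "between"))
  expect_equal(unname(res$table["within", ]), c(30, 20, 25))
  expect_equal(unname(res$table["between", ]), c(40, 10, 15))
  expect_equal(res$statistic, chisq_oracle(res$table), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(chisq_oracle(res$table), 2,
                                   lower.tail = FALSE), tolerance = 1e-10)
  # undefined strands are excluded and counted
  pairs$upstream_strand[1] <- "."
  res2 <- orientation_test(pairs, classes = c("within", "between"))
  expect_equal(res2$n_excluded, 1)
  expect_equal(sum(res2$table), 139)
})

test_that("endpoint sharing Fisher test matches hypergeometric enumeration", {
  # the [[3,1],[1,3]] spot check: two-sided p ~ 0.4857
  seg <- c(rep(TRUE, 4), rep(FALSE, 4))
  dom <- c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 3))
  res <- endpoint_sharing_test(seg, dom)
  expect_equal(unclass(res$table), matrix(c(3, 1, 1, 3), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(res$p_value, fisher_oracle(matrix(c(3, 1, 1, 3), 2)),
               tolerance = 1e-10)
  expect_equal(res$p_value, 0.4857, tolerance = 1e-3)
  expect_equal(res$shared_fraction, 3 / 4)
  # degenerate: every region is both endpoints
  res2 <- endpoint_sharing_test(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(res2$p_value, 1)
  expect_equal(res2$shared_fraction, 1)
  # domain endpoints subset of segment endpoints -> shared fraction 1
  res3 <- endpoint_sharing_test(c(TRUE, TRUE, TRUE, FALSE),
                                c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res3$shared_fraction, 1)
})

test_that("peak densities, enrichment and overlap counting are correct", {
  regions <- tibble::tibble(arm = "2L", begin = c(0, 6000), end = c(4000, 12000),
                            label = "x")  # 10 kb total
  peaks <- tibble::tibble(arm = "2L",
                          begin = c(100, 500, 900, 7000, 8000, 20000),
                          end = c(200, 600, 1000, 7100, 8100, 20100),
                          label = "peaks")
  res <- peak_enrichment(regions, regions, peaks)
  expect_equal(res$peaks_a, 5)          # the 20 kb peak misses
  expect_equal(res$density_a, 0.5)      # 5 peaks / 10 kb
  expect_equal(res$enrichment, 1)
  expect_equal(res$p_value, 1)
  # overlap counting equals a quadratic all-pairs oracle on a random fixture
  set.seed(19)
  ra <- tibble::tibble(arm = sample(c("2L", "2R"), 15, TRUE),
                       begin = runif(15, 0, 5e4))
  ra$end <- ra$begin + runif(15, 100, 3000)
  pk <- tibble::tibble(arm = sample(c("2L", "2R"), 40, TRUE),
                       begin = runif(40, 0, 5.2e4))
  pk$end <- pk$begin + runif(40, 50, 400)
  oracle <- sum(vapply(seq_len(nrow(pk)), function(i) {
    any(ra$arm == pk$arm[i] & pk$begin[i] < ra$end & pk$end[i] > ra$begin)
  }, logical(1)))
  res2 <- peak_enrichment(ra, ra, pk)
  expect_equal(res2$peaks_a, oracle)
  # masking removes peaks near domain boundaries
  domains <- tibble::tibble(arm = "2L", begin = 100, end = 3000, label = "d")
  mask <- boundary_windows(domains, width = 2000)
  expect_equal(mask$begin, c(0, 2000))
  res3 <- peak_enrichment(regions, regions, peaks, mask = mask)
  expect_equal(res3$n_peaks_masked, 3)  # the three peaks inside [0, 1100]
  expect_equal(res3$peaks_a, 2)         # 7000 and 8000 remain in-region
})

test_that("shuffled segmentations preserve lengths and avoid old boundaries", {
  expect_error(shuffle_segmentation(rep(1L, 5), max_tries = 50), "permutation")
  set.seed(23)
  for (i in 1:200) {
    sh <- shuffle_segmentation(c(3L, 2L, 5L))
    expect_equal(sort(sh), c(2L, 3L, 5L))
    expect_length(intersect(segment_boundaries(sh),
                            segment_boundaries(c(3L, 2L, 5L))), 0)
  }
})

test_that("accepted shuffles are uniform over the valid permutation set", {
  lengths <- c(1L, 2L, 3L, 4L, 2L, 3L)
  orig <- segment_boundaries(lengths)
  # exhaustively enumerate all 6! arrangements and keep the valid ones
  all_perms <- combinat_perms(lengths)
  valid_keys <- vapply(
    Filter(function(p) !length(intersect(segment_boundaries(p), orig)),
           all_perms),
    paste, "", collapse = ",")
  expect_gt(length(unique(valid_keys)), 1)
  # expected probability of each distinct valid vector is its multiplicity
  # (equal lengths are interchangeable) over the valid count
  expected <- table(valid_keys) / length(valid_keys)
  set.seed(29)
  draws <- replicate(6000, paste(shuffle_segmentation(lengths), collapse = ","))
  expect_true(all(draws %in% names(expected)))
  counts <- table(factor(draws, levels = names(expected)))
  gof <- chisq.test(as.vector(counts), p = as.vector(expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("term enrichment matches hypergeometric sums and filters singleton support", {
  genes <- sprintf("g%02d", 1:20)
  lengths <- c(4L, 5L, 5L, 6L)
  terms <- tibble::tibble(
    gene_id = c(genes[1:4], genes[6], genes[11:12], genes[16:20]),
    term = c(rep("membrane", 4), "membrane", "kinase", "kinase",
             rep("ribosome", 5))
  )
  res <- term_enrichment(lengths, genes, terms, alpha = 0.05, n_shuffles = 2,
                         seed = 1)
  # segment 1: 4/4 annotated genes carry "membrane" (4 of 5 genome-wide)
  mem <- res$enriched[res$enriched$term == "membrane", ]
  expect_equal(mem$segment, 1)
  expect_equal(mem$p_value,
               hyper_tail_oracle(4, 5, length(unique(terms$gene_id)), 4),
               tolerance = 1e-12)
  # segment 4: all 5 genes ribosome
  expect_true(4 %in% res$enriched$segment)
  # "kinase" in segment 3 has k = 2 -> kept only if significant; but a term
  # carried by one gene in a segment is always removed
  expect_true(all(res$enriched$k >= 2))
  expect_true(res$fisher_p >= 0 && res$fisher_p <= 1)
  expect_error(term_enrichment(lengths, genes,
                               tibble::tibble(gene_id = character(),
                                              term = character())),
               "non-empty")
})
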