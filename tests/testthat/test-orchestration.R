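make_run_inputs <- function(dir, n_genes = 40, n_tissues = 3, seed = 7) {
  sim <- simulate_dataset(n_genes, n_tissues, seed = seed, arm_id = "2L")
  write_expression_tsv(sim$expr, file.path(dir, "expr.tsv"))
  starts <- cumsum(c(0, rep(1000, n_genes - 1)))
  bed <- sprintf("2L\t%d\t%d\t%s\t0\t%s", starts, starts + 500,
                 sim$expr$gene_id,
                 rep_len(c("+", "-"), n_genes))
  writeLines(bed, file.path(dir, "genes.bed"))
  write_model_params(sim$f, NULL, file.path(dir, "params.txt"))
  sim
}

test_that("cmd_fit writes reproducible parameter files and diagnostics", {
  dir <- withr::local_tempdir()
  make_run_inputs(dir, n_genes = 200, n_tissues = 4)
  cfg <- run_config(matrix = file.path(dir, "expr.tsv"),
                    out = file.path(dir, "fit1"), seed = 3L)
  fit1 <- cmd_fit(cfg)
  cfg2 <- run_config(matrix = file.path(dir, "expr.tsv"),
                     out = file.path(dir, "fit2"), seed = 3L)
  cmd_fit(cfg2)
  expect_identical(readLines(file.path(dir, "fit1", "mixture_params.txt")),
                   readLines(file.path(dir, "fit2", "mixture_params.txt")))
  expect_true(file.exists(file.path(dir, "fit1", "fit_diagnostics.tsv")))
  manifest <- yaml::read_yaml(file.path(dir, "fit1", "manifest.yaml"))
  expect_equal(manifest$command, "fit")
  expect_equal(manifest$config$seed, 3)
  # recovered mixture is close to the generating one (pooled values)
  p <- fit1$params
  expect_lt(abs(p$mu2 - 7.5) / 7.5, 0.1)
  # missing input is a user-facing error
  expect_error(cmd_fit(run_config(matrix = file.path(dir, "absent.tsv"))))
})

test_that("cmd_segment trains per arm and the exact mode bounds the greedy", {
  dir <- withr::local_tempdir()
  sim <- make_run_inputs(dir, n_genes = 60, n_tissues = 4, seed = 21)
  cfg <- run_config(matrix = file.path(dir, "expr.tsv"),
                    genes = file.path(dir, "genes.bed"),
                    params = file.path(dir, "params.txt"),
                    out = file.path(dir, "seg"), seed = 11L,
                    replicates = 16L, sigma_init = 1)
  res <- cmd_segment(cfg)
  expect_named(res, "2L")
  report <- readr::read_tsv(file.path(dir, "seg", "run_report.tsv"),
                            show_col_types = FALSE)
  expect_equal(report$n_segments, length(res[["2L"]]$lengths))
  expect_true(all(c("sigma_trained", "shared_best_second") %in% names(report)))
  asg <- readr::read_tsv(file.path(dir, "seg", "gene_segments.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(asg), 60)
  expect_true(file.exists(file.path(dir, "seg", "segments.bed")))
  # deterministic given the seed
  cfg2 <- run_config(matrix = file.path(dir, "expr.tsv"),
                     genes = file.path(dir, "genes.bed"),
                     params = file.path(dir, "params.txt"),
                     out = file.path(dir, "seg2"), seed = 11L,
                     replicates = 16L, sigma_init = 1)
  res2 <- cmd_segment(cfg2)
  expect_identical(res[["2L"]]$lengths, res2[["2L"]]$lengths)
  # exact DP at the trained sd scores no worse than the greedy result
  cfg3 <- run_config(matrix = file.path(dir, "expr.tsv"),
                     genes = file.path(dir, "genes.bed"),
                     params = file.path(dir, "params.txt"),
                     out = file.path(dir, "seg3"), seed = 11L, exact = TRUE,
                     sigma_init = report$sigma_trained[1])
  res3 <- cmd_segment(cfg3)
  expect_lte(res3[["2L"]]$score, res[["2L"]]$score + 1e-9)
})

test_that("cmd_simulate and cmd_validate produce self-consistent reports", {
  dir <- withr::local_tempdir()
  cfg <- run_config(out = file.path(dir, "sim"), n_genes = 50L,
                    n_tissues = 3L, seed = 5L)
  sim <- cmd_simulate(cfg)
  expect_true(file.exists(file.path(dir, "sim", "matrix.tsv")))
  back <- read_expression_tsv(file.path(dir, "sim", "matrix.tsv"))
  expect_equal(nrow(back), 50)
  # validate at a deliberately small scale
  vcfg <- run_config(out = file.path(dir, "val"), n_datasets = 2L,
                     n_genes = 60L, n_tissues = 4L, replicates = 8L,
                     seed = 9L)
  report <- cmd_validate(vcfg)
  expect_equal(nrow(report), 2)
  expect_true(all(report$sigma_rel_error >= 0))
  expect_true(all(report$f1 > 0.5))
  # report round-trips through its own reader
  back2 <- readr::read_tsv(file.path(dir, "val", "validation_report.tsv"),
                           show_col_types = FALSE)
  expect_equal(back2$sigma_trained, report$sigma_trained)
  manifest <- yaml::read_yaml(file.path(dir, "val", "manifest.yaml"))
  expect_equal(manifest$n_exact, sum(report$exact))
})

test_that("cmd_analyze writes the downstream characterization tables", {
  dir <- withr::local_tempdir()
  make_run_inputs(dir, n_genes = 80, n_tissues = 4, seed = 31)
  cfg <- run_config(matrix = file.path(dir, "expr.tsv"),
                    genes = file.path(dir, "genes.bed"),
                    params = file.path(dir, "params.txt"),
                    out = file.path(dir, "seg"), seed = 13L,
                    replicates = 16L)
  cmd_segment(cfg)
  # interval annotations: peaks everywhere, domains aligned to gene starts
  peaks <- sprintf("2L\t%d\t%d", seq(0, 76000, by = 4000),
                   seq(0, 76000, by = 4000) + 300)
  writeLines(peaks, file.path(dir, "peaks.bed"))
  writeLines(c("2L\t0\t20000", "2L\t20000\t50000"), file.path(dir, "domains.bed"))
  terms <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    term = rep(c("membrane", "kinase"), each = 20))
  readr::write_tsv(terms, file.path(dir, "terms.tsv"))
  acfg <- run_config(matrix = file.path(dir, "expr.tsv"),
                     genes = file.path(dir, "genes.bed"),
                     params = file.path(dir, "seg", "gene_segments.tsv"),
                     peaks = file.path(dir, "peaks.bed"),
                     domains = file.path(dir, "domains.bed"),
                     terms = file.path(dir, "terms.tsv"),
                     mask_boundary_window = 2000,
                     out = file.path(dir, "ana"), seed = 17L)
  out <- cmd_analyze(acfg)
  expect_true(file.exists(file.path(dir, "ana", "segment_profiles.tsv")))
  expect_true(file.exists(file.path(dir, "ana", "intergenic_length_test.tsv")))
  expect_true(file.exists(file.path(dir, "ana", "orientation_counts.tsv")))
  expect_true(file.exists(file.path(dir, "ana", "peak_enrichment.tsv")))
  expect_true(file.exists(file.path(dir, "ana", "endpoint_sharing.tsv")))
  expect_s3_class(out$profiles, "tbl_df")
  expect_true(out$peak_enrichment$kb_a > 0)
})

test_that("run_config rejects unknown keys and layers file and overrides", {
  expect_error(run_config(bogus = 1), "unknown")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(replicates = 32L, aggregator = "best"), path)
  cfg <- run_config(path, aggregator = "mean")
  expect_equal(cfg$replicates, 32)
  expect_equal(cfg$aggregator, "mean")   # override wins
  expect_equal(cfg$mean_len, 2)          # default preserved
})

test_that("tidiers and autoplot methods produce well-formed output", {
  sim <- simulate_dataset(40, 4, seed = 3)
  fit <- fit_mixture_em(as.vector(sim$matrix) + rnorm(160, 0, 0.01), seed = 2)
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(glance(fit)$n, 160)
  expect_s3_class(autoplot(fit), "ggplot")

  rr <- run_replicates(sim$matrix, sim$f, sim$g, n_replicates = 4,
                       master_seed = 8)
  td <- tidy(rr)
  expect_equal(nrow(td), 4)
  expect_true(all(c("score", "n_segments") %in% names(td)))
  expect_equal(glance(rr)$n_replicates, 4)

  sc <- rr$best
  expect_equal(sum(tidy(sc)$n_genes), 40)
  expect_equal(glance(sc)$score, sc$score)
  aug <- augment(sc, sim$expr)
  expect_equal(nrow(aug), 40)
  expect_true("segment" %in% names(aug))
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(autoplot(sc, expr = sim$matrix), "ggplot")

  tr <- train_sigma(sim$expr, sim$f, n_replicates = 4, master_seed = 5)
  expect_true(all(c("sigma", "score") %in% names(tidy(tr))))
  expect_equal(glance(tr)$sigma, tr$sigma)
  expect_s3_class(autoplot(tr), "ggplot")

  prof <- segment_profiles(sim$matrix, sim$truth)
  expect_s3_class(autoplot(prof), "ggplot")
})
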