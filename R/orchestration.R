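# Reproducible end-to-end runs: each command takes a flat config (named
# list or YAML file), writes its outputs plus a manifest that records the
# full effective configuration, and returns its results invisibly. All
# randomness flows from the single `seed` entry, so a run is reproducible
# from its manifest alone.

default_config <- list(
  matrix = NULL, genes = NULL, out = ".",
  params = NULL, sigma_init = 1, replicates = 1024L, aggregator = "median",
  mean_len = 2, seed = 1L, exact = FALSE, k_dist_params = 1,
  n_genes = 2000L, n_tissues = 27L, sigma = 0.6, heteroscedastic = FALSE,
  sigma_spread = 1.5, n_datasets = 40L,
  peaks = NULL, domains = NULL, terms = NULL, mask_boundary_window = 0,
  qc_threshold = 0.98
)

#' Assemble a run configuration
#'
#' Reads an optional YAML config file and merges command-line style
#' overrides on top of the package defaults (file < overrides).
#'
#' @param file Optional path to a flat YAML config file.
#' @param ... Named overrides (for example `matrix = "X.tsv"`,
#'   `replicates = 64`).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- default_config
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown)) {
      abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
    }
    cfg[names(from_file)] <- from_file
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

write_manifest <- function(cfg, out_dir, command, extra = list()) {
  manifest <- c(list(command = command,
                     package_version = as.character(utils::packageVersion("coexseg"))),
                list(config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))]),
                extra)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

load_arm_data <- function(cfg) {
  if (is.null(cfg$matrix)) abort("config needs `matrix` (expression TSV path).")
  expr <- read_expression_tsv(cfg$matrix)
  layout <- replicate_layout(setdiff(names(expr), "gene_id"))
  if (any(duplicated(layout$tissue) )) {
    qc <- qc_filter_tissues(expr, threshold = cfg$qc_threshold)
    expr <- average_replicates(expr, keep = qc$tissue[qc$kept])
  }
  if (is.null(cfg$genes)) {
    return(tibble(arm = "arm", data = list(expr)))
  }
  annot <- read_gene_bed(cfg$genes)
  order_genes_by_start(expr, annot)
}

#' Fit the segment-effect mixture from an expression matrix
#'
#' Pools all expression values (after replicate QC and averaging, when
#' replicate columns are present), fits the two-component normal mixture by
#' EM, and writes the parameter file plus fit diagnostics.
#'
#' @param cfg A [run_config()]; uses `matrix`, `out`, `seed`.
#' @return The `mixture_em_fit`, invisibly.
#' @export
cmd_fit <- function(cfg) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  arms <- load_arm_data(cfg)
  values <- unlist(lapply(arms$data, function(d) as.vector(expr_matrix(d))))
  fit <- fit_mixture_em(values, seed = cfg$seed)
  write_model_params(fit$params, g = NULL,
                     path = file.path(cfg$out, "mixture_params.txt"))
  readr::write_tsv(glance(fit), file.path(cfg$out, "fit_diagnostics.tsv"))
  write_manifest(cfg, cfg$out, "fit",
                 list(loglik = fit$loglik, n_iter = fit$n_iter,
                      converged = fit$converged))
  invisible(fit)
}

#' Segment each chromosome arm
#'
#' For every arm, trains the deviation sd by simplex search over replicate
#' scores (or, with `exact = TRUE`, runs the exact dynamic program at
#' `sigma_init`) and writes per-arm segment BED spans, per-gene segment
#' assignments, and a run report with score, K, trained sd and replicate
#' agreement.
#'
#' @param cfg A [run_config()]; uses `matrix`, `genes`, `params`, `out`,
#'   `sigma_init`, `replicates`, `aggregator`, `mean_len`, `seed`, `exact`,
#'   `k_dist_params`.
#' @return Named list of per-arm results, invisibly.
#' @export
cmd_segment <- function(cfg) {
  if (is.null(cfg$params)) abort("config needs `params` (fitted mixture file).")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  f <- read_model_params(cfg$params)$f
  arms <- load_arm_data(cfg)
  report <- list()
  results <- list()
  assignments <- list()
  beds <- list()
  for (i in seq_len(nrow(arms))) {
    arm <- arms$arm[i]
    dat <- arms$data[[i]]
    seed_arm <- derive_seed(cfg$seed, i)
    if (isTRUE(cfg$exact)) {
      best <- dp_optimal_segmentation(dat, f, deviation_params(cfg$sigma_init),
                                      n_free_dist_params = cfg$k_dist_params,
                                      arm_id = arm)
      agreement <- NULL
      sigma_hat <- cfg$sigma_init
    } else {
      tr <- train_sigma(dat, f, sigma_init = cfg$sigma_init,
                        n_replicates = cfg$replicates, master_seed = seed_arm,
                        aggregator = cfg$aggregator, mean_len = cfg$mean_len,
                        n_free_dist_params = cfg$k_dist_params, arm_id = arm)
      best <- tr$best
      sigma_hat <- tr$sigma
      agreement <- replicate_agreement(tr$replicates)
    }
    results[[arm]] <- best
    gl <- glance(best)
    gl$arm <- arm
    gl$sigma_trained <- sigma_hat
    if (!is.null(agreement)) gl <- bind_cols(gl, agreement)
    report[[arm]] <- gl
    assigned <- augment(best, dat)
    assigned$arm <- arm
    keep_cols <- intersect(c("arm", "gene_id", "start", "segment"),
                           names(assigned))
    assignments[[arm]] <- assigned[keep_cols]
    if ("start" %in% names(dat)) {
      td <- tidy(best)
      beds[[arm]] <- tibble(
        chrom = arm,
        start = dat$start[td$first_gene],
        end = dat$start[td$last_gene] + 1,
        name = sprintf("%s_seg%04d", arm, td$segment),
        score = 0L,
        strand = "."
      )
    }
  }
  readr::write_tsv(bind_rows(report), file.path(cfg$out, "run_report.tsv"))
  readr::write_tsv(bind_rows(assignments),
                   file.path(cfg$out, "gene_segments.tsv"))
  if (length(beds)) {
    readr::write_tsv(bind_rows(beds), file.path(cfg$out, "segments.bed"),
                     col_names = FALSE)
  }
  write_manifest(cfg, cfg$out, "segment",
                 list(arms = as.list(setNames(vapply(results, function(r)
                   r$score, numeric(1)), names(results)))))
  invisible(results)
}

#' Simulate a dataset to disk
#'
#' @param cfg A [run_config()]; uses `n_genes`, `n_tissues`, `mean_len`,
#'   `sigma`, `heteroscedastic`, `sigma_spread`, `seed`, `out`.
#' @return The `simulated_dataset`, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  f <- if (!is.null(cfg$params)) read_model_params(cfg$params)$f
       else mixture_params(0.4, 3.5, 1.2, 7.5, 1.8)
  sim <- simulate_dataset(cfg$n_genes, cfg$n_tissues, mean_len = cfg$mean_len,
                          f = f, g = deviation_params(cfg$sigma),
                          heteroscedastic = isTRUE(cfg$heteroscedastic),
                          sigma_spread = cfg$sigma_spread, seed = cfg$seed)
  write_simulated_dataset(sim, cfg$out)
  write_manifest(cfg, cfg$out, "simulate",
                 list(n_segments = length(sim$truth)))
  invisible(sim)
}

#' Simulation study: simulate, retrain, score recovery
#'
#' Simulates `n_datasets` single-arm datasets under the generative model,
#' reruns the full deviation-sd training on each (with the mixture fixed at
#' its generating values), and reports the relative sd errors and exact
#' recovery of the generating segmentation.
#'
#' @param cfg A [run_config()]; uses `n_datasets`, `n_genes`, `n_tissues`,
#'   `mean_len`, `sigma`, `replicates`, `aggregator`, `seed`, `out`,
#'   `sigma_init`.
#' @return The per-dataset report tibble, invisibly.
#' @export
cmd_validate <- function(cfg) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  f <- if (!is.null(cfg$params)) read_model_params(cfg$params)$f
       else mixture_params(0.4, 3.5, 1.2, 7.5, 1.8)
  g <- deviation_params(cfg$sigma)
  rows <- lapply(seq_len(cfg$n_datasets), function(i) {
    sim <- simulate_dataset(cfg$n_genes, cfg$n_tissues,
                            mean_len = cfg$mean_len, f = f, g = g,
                            seed = derive_seed(cfg$seed, i),
                            arm_id = sprintf("sim%02d", i))
    tr <- train_sigma(sim$expr, f, sigma_init = cfg$sigma_init,
                      n_replicates = cfg$replicates,
                      master_seed = derive_seed(cfg$seed, 10000L + i),
                      aggregator = cfg$aggregator, mean_len = cfg$mean_len,
                      arm_id = sim$arm_id)
    rec <- score_against_truth(tr$best, sim$truth)
    bind_cols(
      tibble(dataset = i, sigma_true = g$sigma, sigma_trained = tr$sigma,
             sigma_rel_error = abs(tr$sigma - g$sigma) / g$sigma,
             score = tr$best$score, n_segments_true = length(sim$truth),
             n_segments_found = length(tr$best$lengths)),
      rec
    )
  })
  report <- bind_rows(rows)
  readr::write_tsv(report, file.path(cfg$out, "validation_report.tsv"))
  write_manifest(cfg, cfg$out, "validate",
                 list(n_exact = sum(report$exact),
                      max_sigma_rel_error = max(report$sigma_rel_error)))
  invisible(report)
}

#' Downstream characterization of a segmentation
#'
#' Reads a segmentation (per-gene assignments from [cmd_segment()]), the
#' expression matrix and gene annotation, and writes segment profiles and
#' classification, the within/between intergenic-length comparison and the
#' orientation counts; optionally peak enrichment (with boundary-window
#' masking), domain endpoint sharing, and per-segment term enrichment.
#'
#' @param cfg A [run_config()]; uses `matrix`, `genes`, `out`, and the
#'   optional `peaks`, `domains`, `mask_boundary_window`, `terms`, `seed`.
#'   `params` must point at the `gene_segments.tsv` of a segment run.
#' @return Named list of result tables, invisibly.
#' @export
cmd_analyze <- function(cfg) {
  if (is.null(cfg$params)) {
    abort("config needs `params` (gene_segments.tsv from cmd_segment).")
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  assignments <- readr::read_tsv(
    cfg$params, show_col_types = FALSE,
    col_types = readr::cols(arm = "c", gene_id = "c", .default = "d"))
  arms <- load_arm_data(cfg)
  out <- list()
  profiles_all <- list()
  classified_all <- list()
  intergenic_all <- list()
  pair_rows <- list()
  for (i in seq_len(nrow(arms))) {
    arm <- arms$arm[i]
    dat <- arms$data[[i]]
    asg <- assignments[assignments$arm == arm, , drop = FALSE]
    asg <- asg[match(dat$gene_id, asg$gene_id), , drop = FALSE]
    if (anyNA(asg$segment)) abort(sprintf("arm %s: missing segment assignments.", arm))
    lengths <- as.integer(table(factor(asg$segment, levels = unique(asg$segment))))
    prof <- segment_profiles(dat, lengths)
    cls <- tryCatch(classify_segments(prof), error = function(e) NULL)
    prof$arm <- arm
    if (!is.null(cls)) {
      cls$arm <- arm
      classified_all[[arm]] <- cls
    }
    profiles_all[[arm]] <- prof
    if (nrow(dat) >= 2L) {
      reg <- mark_intersegment(intergenic_regions(dat), lengths)
      reg$arm <- arm   # the nested per-arm tables carry no arm column
      intergenic_all[[arm]] <- reg
      if ("strand" %in% names(dat)) {
        n <- nrow(dat)
        pair_class <- ifelse(reg$intersegment, "intersegment",
                             ifelse(lengths[reg$upstream_segment] == 2L,
                                    "within-two-gene-segment",
                                    "within-longer-segment"))
        pair_rows[[arm]] <- tibble(
          arm = arm,
          upstream_strand = dat$strand[-n], downstream_strand = dat$strand[-1],
          class = pair_class
        )
      }
    }
  }
  profiles <- bind_rows(profiles_all)
  readr::write_tsv(select(profiles, -any_of("restricted_tissues")),
                   file.path(cfg$out, "segment_profiles.tsv"))
  out$profiles <- profiles
  if (length(classified_all)) {
    classified <- bind_rows(classified_all)
    classified$restricted_tissues <- vapply(
      classified$restricted_tissues, paste, "", collapse = ",")
    readr::write_tsv(classified, file.path(cfg$out, "segment_classes.tsv"))
    out$classified <- classified
  }
  intergenic <- bind_rows(intergenic_all)
  if (nrow(intergenic)) {
    out$intergenic_lengths <- compare_intergenic_lengths(
      intergenic$length[!intergenic$intersegment],
      intergenic$length[intergenic$intersegment])
    readr::write_tsv(out$intergenic_lengths,
                     file.path(cfg$out, "intergenic_length_test.tsv"))
  }
  if (length(pair_rows)) {
    pairs <- bind_rows(pair_rows)
    counts <- orientation_test(pairs,
                               classes = head(unique(pairs$class), 2L))$counts
    readr::write_tsv(counts, file.path(cfg$out, "orientation_counts.tsv"))
    out$orientation <- counts
  }
  if (!is.null(cfg$peaks) && nrow(intergenic)) {
    peaks <- read_intervals_bed(cfg$peaks, "peaks")
    mask <- NULL
    if (!is.null(cfg$domains) && cfg$mask_boundary_window > 0) {
      mask <- boundary_windows(read_intervals_bed(cfg$domains, "domains"),
                               width = cfg$mask_boundary_window)
    }
    inter <- intergenic[intergenic$intersegment, , drop = FALSE]
    within <- intergenic[!intergenic$intersegment, , drop = FALSE]
    if (nrow(inter) && nrow(within)) {
      out$peak_enrichment <- peak_enrichment(inter, within, peaks, mask = mask)
      readr::write_tsv(out$peak_enrichment,
                       file.path(cfg$out, "peak_enrichment.tsv"))
    }
  }
  if (!is.null(cfg$domains) && nrow(intergenic)) {
    domains <- read_intervals_bed(cfg$domains, "domains")
    is_dom <- vapply(seq_len(nrow(intergenic)), function(j) {
      any(domains$arm == intergenic$arm[j] &
            (abs(domains$begin - intergenic$begin[j]) <= 0 |
               abs(domains$end - intergenic$end[j]) <= 0))
    }, logical(1))
    es <- endpoint_sharing_test(intergenic$intersegment, is_dom)
    out$endpoint_sharing <- es
    readr::write_tsv(tibble(p_value = es$p_value,
                            odds_ratio = es$odds_ratio,
                            shared_fraction = es$shared_fraction),
                     file.path(cfg$out, "endpoint_sharing.tsv"))
  }
  if (!is.null(cfg$terms)) {
    terms <- readr::read_tsv(cfg$terms, show_col_types = FALSE)
    te_rows <- list()
    for (i in seq_len(nrow(arms))) {
      arm <- arms$arm[i]
      dat <- arms$data[[i]]
      asg <- assignments[assignments$arm == arm, , drop = FALSE]
      asg <- asg[match(dat$gene_id, asg$gene_id), , drop = FALSE]
      lengths <- as.integer(table(factor(asg$segment,
                                         levels = unique(asg$segment))))
      te <- tryCatch(
        term_enrichment(lengths, dat$gene_id, terms,
                        seed = derive_seed(cfg$seed, 20000L + i)),
        error = function(e) NULL)
      if (!is.null(te) && nrow(te$enriched)) {
        te$enriched$arm <- arm
        te_rows[[arm]] <- te$enriched
      }
    }
    if (length(te_rows)) {
      out$term_enrichment <- bind_rows(te_rows)
      readr::write_tsv(out$term_enrichment,
                       file.path(cfg$out, "term_enrichment.tsv"))
    }
  }
  write_manifest(cfg, cfg$out, "analyze")
  invisible(out)
}
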