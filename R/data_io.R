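#' Read an expression matrix from TSV
#'
#' Expects a tab-separated UTF-8 file whose first column is `gene_id` and
#' whose remaining columns are tissue measurements, with biological
#' replicates encoded as a `tissue.rep` column-name suffix (for example
#' `brain.1`, `brain.2`). Values must be numeric with `.` decimals;
#' malformed cells are rejected with their line numbers.
#'
#' @param path Path to the TSV file.
#' @return A tibble: `gene_id` plus one numeric column per measurement.
#' @export
read_expression_tsv <- function(path) {
  # read as character and convert via base strtod: exact round-trip of
  # full-precision decimal renderings, which vroom's fast parser is not
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = character(),
                        col_types = readr::cols(.default = "c"))
  if (ncol(df) < 2L) abort("expression TSV needs gene_id plus >= 1 tissue column.")
  names(df)[1] <- "gene_id"
  for (col in names(df)[-1]) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed))
    if (length(bad)) {
      abort(sprintf(
        "malformed expression TSV: line %d, column '%s' is not a number ('%s').",
        bad[1] + 1L, col, df[[col]][bad[1]]))
    }
    df[[col]] <- parsed
  }
  as_tibble(df)
}

#' Write an expression matrix to TSV
#'
#' Values are rendered with full precision so that writing and re-reading
#' reproduces them bit-identically.
#'
#' @param expr Tibble with `gene_id` plus numeric columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  out <- expr
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Collapse probeset values to gene values
#'
#' Microarray platforms often measure a gene with several probesets. Each
#' gene's expression in each tissue is taken as the median over its
#' probesets' values; probes with no gene assignment are dropped.
#'
#' @param probe_values Tibble: `probe_id` plus one numeric column per
#'   tissue/measurement.
#' @param probe_map Tibble with columns `probe_id`, `gene_id`; each probe
#'   may map to at most one gene.
#' @return A tibble: `gene_id` plus the same measurement columns, one row
#'   per gene, sorted by `gene_id`.
#' @export
collapse_probesets <- function(probe_values, probe_map) {
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` needs columns `probe_id` and `gene_id`.")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    abort("a probe maps to more than one gene.")
  }
  if (!"probe_id" %in% names(probe_values)) {
    abort("`probe_values` needs a `probe_id` column.")
  }
  joined <- inner_join(probe_values, probe_map, by = "probe_id")
  if (nrow(joined) == 0L) {
    abort("unusable probe map: no probe maps to any gene in the data.")
  }
  joined %>%
    select(-"probe_id") %>%
    group_by(.data$gene_id) %>%
    summarise(across(dplyr::everything(), median), .groups = "drop") %>%
    arrange(.data$gene_id)
}

# Split replicate-suffixed measurement columns into (tissue, replicate).
# Columns without a ".rep" suffix are single-replicate tissues.
replicate_layout <- function(cols) {
  has_rep <- grepl("\\.[^.]+$", cols)
  tibble(
    column = cols,
    tissue = ifelse(has_rep, sub("\\.[^.]+$", "", cols), cols),
    replicate = ifelse(has_rep, sub("^.*\\.", "", cols), "1")
  )
}

#' Replicate-correlation quality control of tissues
#'
#' A tissue is kept only if the Pearson correlation across genes of every
#' pair of its biological replicates is at least `threshold` (default 0.98).
#' A replicate with zero variance makes the correlation undefined; such
#' tissues are dropped with a warning. Single-replicate tissues pass
#' vacuously.
#'
#' @param expr Tibble: `gene_id` plus replicate columns named `tissue.rep`.
#' @param threshold Minimum pairwise replicate correlation, in `(0, 1]`.
#' @return A tibble with one row per tissue: `tissue`, `n_replicates`,
#'   `min_correlation`, `kept`.
#' @seealso [average_replicates()] to collapse the kept tissues.
#' @export
qc_filter_tissues <- function(expr, threshold = 0.98) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  layout <- replicate_layout(setdiff(names(expr), "gene_id"))
  per_tissue <- split(layout$column, layout$tissue)
  res <- purrr::map_dfr(names(per_tissue), function(ts) {
    cols <- per_tissue[[ts]]
    if (length(cols) < 2L) {
      return(tibble(tissue = ts, n_replicates = length(cols),
                    min_correlation = NA_real_, kept = TRUE))
    }
    m <- as.matrix(expr[cols])
    if (any(apply(m, 2L, sd) == 0)) {
      warn(sprintf("tissue '%s': constant replicate, correlation undefined; dropped.", ts))
      return(tibble(tissue = ts, n_replicates = length(cols),
                    min_correlation = NA_real_, kept = FALSE))
    }
    cors <- cor(m)
    min_cor <- min(cors[upper.tri(cors)])
    tibble(tissue = ts, n_replicates = length(cols),
           min_correlation = min_cor, kept = min_cor >= threshold)
  })
  res[order(res$tissue), ]
}

#' Average biological replicates per tissue
#'
#' Per gene and tissue, the arithmetic mean over that tissue's replicate
#' columns (any replicate count, including one).
#'
#' @param expr Tibble: `gene_id` plus replicate columns named `tissue.rep`.
#' @param keep Optional character vector of tissues to keep (for example
#'   `qc_filter_tissues(expr)$tissue[qc$kept]`); default keeps all.
#' @return A tibble: `gene_id` plus one numeric column per tissue.
#' @export
average_replicates <- function(expr, keep = NULL) {
  layout <- replicate_layout(setdiff(names(expr), "gene_id"))
  if (!is.null(keep)) layout <- layout[layout$tissue %in% keep, , drop = FALSE]
  if (nrow(layout) == 0L) abort("no tissues left to average.")
  out <- tibble(gene_id = expr$gene_id)
  for (ts in unique(layout$tissue)) {
    cols <- layout$column[layout$tissue == ts]
    out[[ts]] <- rowMeans(as.matrix(expr[cols]))
  }
  out
}

#' Read gene annotations from BED
#'
#' BED6 (tab-separated: chrom, start, end, name, score, strand; BED
#' coordinates are 0-based half-open and are kept as-is internally). The
#' `name` field is the gene id and `start` is taken as the annotated
#' transcription start for `+`-strand reading; for genes the model orders by
#' transcription start, see [order_genes_by_start()], which uses `start`
#' for `+` genes and `end` for `-` genes when `tss_by_strand = TRUE`.
#' Malformed lines are rejected with their line numbers.
#'
#' @param path Path to a BED6 file.
#' @return A tibble: `gene_id`, `arm`, `start`, `end`, `strand`.
#' @export
read_gene_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: expected >= 6 tab-separated fields.",
                  idx[bad[1]]))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  strand <- vapply(fields, `[`, "", 6L)
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start |
                 !strand %in% c("+", "-", "."))
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: bad coordinates or strand.",
                  idx[bad[1]]))
  }
  tibble(
    gene_id = vapply(fields, `[`, "", 4L),
    arm = vapply(fields, `[`, "", 1L),
    start = start, end = end, strand = strand
  )
}

#' Read gene annotations from GFF3
#'
#' Keeps `gene`-type lines; the gene id is the `ID` (or `Name`) attribute.
#' GFF3 1-based inclusive coordinates are converted to the package's
#' internal 0-based half-open convention on read. Requires the rtracklayer
#' package.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble: `gene_id`, `arm`, `start`, `end`, `strand`.
#' @export
read_gene_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[!is.na(df$type) & as.character(df$type) == "gene", , drop = FALSE]
  if (nrow(df) == 0L) abort("no gene-type records in GFF3 file.")
  ids <- if (!is.null(df$ID)) as.character(df$ID) else as.character(df$Name)
  tibble(
    gene_id = ids,
    arm = as.character(df$seqnames),
    start = df$start - 1,   # to 0-based half-open
    end = df$end,
    strand = as.character(df$strand)
  )
}

#' Read an interval set from BED3+
#'
#' @param path Path to a BED file with at least chrom, start, end.
#' @param label Role tag for the intervals (`"peaks"`, `"domains"`, ...).
#' @return A tibble: `arm`, `begin`, `end`, `label`.
#' @export
read_intervals_bed <- function(path, label = "peaks") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: expected >= 3 tab-separated fields.",
                  idx[bad[1]]))
  }
  begin <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(begin) | is.na(end) | begin < 0 | end <= begin)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: end must exceed begin >= 0.",
                  idx[bad[1]]))
  }
  tibble(arm = vapply(fields, `[`, "", 1L), begin = begin, end = end,
         label = label)
}

#' Order expression rows by transcription start, per arm
#'
#' Joins gene annotations onto the expression table, drops (with a warning)
#' matrix genes that lack an annotation, ignores annotated genes absent
#' from the matrix, and returns one ordered expression table per chromosome
#' arm. Rows are sorted by ascending transcription start; equal starts are
#' broken deterministically by gene id.
#'
#' @param expr Tibble: `gene_id` plus numeric tissue columns.
#' @param annot Gene annotation tibble (`gene_id`, `arm`, `start`, `end`,
#'   `strand`), as from [read_gene_bed()].
#' @param tss_by_strand Use `end` as the transcription start for `-`-strand
#'   genes (default `FALSE`: `start` is assumed to already be the annotated
#'   transcription start coordinate).
#' @return A nested tibble with one row per arm: `arm`, `data` (ordered
#'   expression tibble with `gene_id`, `start`, `strand` plus tissue
#'   columns).
#' @export
order_genes_by_start <- function(expr, annot, tss_by_strand = FALSE) {
  need <- c("gene_id", "arm", "start", "strand")
  if (!all(need %in% names(annot))) {
    abort(paste("`annot` needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(annot$gene_id)) {
    abort("a gene has more than one annotation record.")
  }
  missing <- setdiff(expr$gene_id, annot$gene_id)
  if (length(missing)) {
    warn(sprintf("%d matrix gene(s) without annotation dropped (e.g. %s).",
                 length(missing), missing[1]))
    expr <- expr[!expr$gene_id %in% missing, , drop = FALSE]
  }
  if (nrow(expr) == 0L) abort("no annotated genes left in the matrix.")
  ann <- annot
  if (tss_by_strand && "end" %in% names(ann)) {
    ann$start <- ifelse(ann$strand == "-", ann$end, ann$start)
  }
  joined <- inner_join(expr, ann[c("gene_id", "arm", "start", "strand")],
                       by = "gene_id") %>%
    arrange(.data$arm, .data$start, .data$gene_id)
  joined %>%
    group_by(.data$arm) %>%
    tidyr::nest(.key = "data") %>%
    ungroup() %>%
    arrange(.data$arm)
}

#' Intergenic regions between adjacent gene starts
#'
#' The intergenic region between two adjacent genes is the span between
#' their annotated transcription start coordinates (start-to-start, not
#' end-to-start); an arm with `n` genes yields exactly `n - 1` regions.
#' Zero-length regions (equal starts after the tie-break) are permitted and
#' flagged.
#'
#' @param ordered Expression-with-annotation tibble for one arm, ordered by
#'   start (one `data` element of [order_genes_by_start()]), or any tibble
#'   with `gene_id` and `start` ordered by `start`; an `arm` column is
#'   carried through if present.
#' @return A tibble with one row per adjacent pair: `arm`, `begin`, `end`,
#'   `length`, `upstream_gene`, `downstream_gene`, `zero_length`, and
#'   `label = "intergenic"`.
#' @export
intergenic_regions <- function(ordered) {
  if (!all(c("gene_id", "start") %in% names(ordered))) {
    abort("`ordered` needs `gene_id` and `start` columns.")
  }
  n <- nrow(ordered)
  if (n < 2L) abort("need at least 2 genes to form intergenic regions.")
  if (is.unsorted(ordered$start)) abort("`ordered` must be sorted by start.")
  s <- ordered$start
  tibble(
    arm = if ("arm" %in% names(ordered)) ordered$arm[-n] else NA_character_,
    begin = s[-n], end = s[-1L], length = s[-1L] - s[-n],
    upstream_gene = ordered$gene_id[-n],
    downstream_gene = ordered$gene_id[-1L],
    zero_length = s[-1L] - s[-n] == 0,
    label = "intergenic"
  )
}
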