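#' Assemble a validated count matrix
#'
#' Bundles a genes-by-lanes table of raw counts with the sample sheet that
#' maps each lane to its tissue, condition (treatment or control solution),
#' contrast and biological replicate.
#'
#' @param counts Tibble with a `gene_id` column followed by one integer
#'   column per lane.
#' @param samples Sample sheet tibble with columns `lane`, `tissue`,
#'   `condition`, `contrast`, `replicate`. Every lane column of `counts`
#'   must appear exactly once.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `samples` and (after [quantile_normalize()]) `normalized`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as_tibble(counts)
  samples <- as_tibble(samples)
  assert_cols(counts, "gene_id", "counts table")
  assert_cols(samples, c("lane", "tissue", "condition", "contrast", "replicate"),
              "sample sheet")
  lanes <- setdiff(names(counts), "gene_id")
  if (length(lanes) == 0L) abort_format("counts table has no lane columns")
  if (anyDuplicated(counts$gene_id)) {
    abort_format("duplicate gene ids in counts table")
  }
  vals <- as.matrix(counts[lanes])
  if (!is.numeric(vals) || anyNA(vals)) {
    abort_format("counts must be numeric and complete")
  }
  if (any(vals < 0) || any(vals != floor(vals))) {
    abort_format("raw counts must be non-negative integers")
  }
  if (anyDuplicated(samples$lane)) {
    abort_design("sample sheet lists a lane more than once")
  }
  if (!setequal(lanes, samples$lane)) {
    abort_design(sprintf(
      "lane mismatch between counts and sample sheet: counts-only [%s], sheet-only [%s]",
      paste(setdiff(lanes, samples$lane), collapse = ","),
      paste(setdiff(samples$lane, lanes), collapse = ",")
    ))
  }
  samples <- samples[match(lanes, samples$lane), ]
  structure(
    list(counts = counts, samples = samples, normalized = NULL),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d lanes (%s)\n",
    nrow(x$counts), nrow(x$samples),
    if (is.null(x$normalized)) "raw" else "raw + normalized"
  ))
  invisible(x)
}

lane_ids <- function(cm) cm$samples$lane

count_values <- function(cm, normalized = FALSE) {
  tbl <- if (normalized) {
    if (is.null(cm$normalized)) abort_design("counts have not been normalized yet")
    cm$normalized
  } else {
    cm$counts
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  rownames(m) <- tbl$gene_id
  m
}

#' Read counts and sample sheet from TSV files
#'
#' @param counts_path TSV with a `gene_id` column and one column per lane.
#' @param samples_path TSV sample sheet (`lane`, `tissue`, `condition`,
#'   `contrast`, `replicate`).
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  for (p in c(counts_path, samples_path)) {
    if (!file.exists(p)) abort_format(sprintf("file not found: %s", p))
  }
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  count_matrix(counts, samples)
}

#' Summarise a lane-level read-accounting table
#'
#' Consumes per-lane totals for the standard read-accounting categories of a
#' short-read experiment (total reads, purity-filtered reads, repeat-masked,
#' unmatched, uniquely mapped, mapped to annotated genes) and emits
#' per-sample totals, grand totals, and the derived mapping fractions. All
#' derived percentages are rounded to one decimal.
#'
#' @param lane_summary Tibble with a `sample` column and one numeric column
#'   per category; at minimum `total_reads`, `purity_filtered` and
#'   `uniquely_mapped`.
#' @return A list with `by_sample` (the validated input), `grand`
#'   (category grand totals) and `fractions` (derived percentages;
#'   `NA` when a denominator is zero).
#' @export
qc_summary <- function(lane_summary) {
  lane_summary <- as_tibble(lane_summary)
  assert_cols(lane_summary, c("sample", "total_reads", "purity_filtered", "uniquely_mapped"),
              "lane summary")
  cat_cols <- setdiff(names(lane_summary), "sample")
  grand <- tibble(
    category = cat_cols,
    total = vapply(cat_cols, function(cc) sum(lane_summary[[cc]]), numeric(1))
  )
  tot <- grand$total[grand$category == "total_reads"]
  pf <- grand$total[grand$category == "purity_filtered"]
  uniq <- grand$total[grand$category == "uniquely_mapped"]
  pct <- function(num, den) if (den > 0) round1(100 * num / den) else NA_real_
  fractions <- tibble(
    name = c("pct_unique_of_total", "pct_unique_of_purity_filtered",
             "pct_purity_filtered_of_total"),
    value = c(pct(uniq, tot), pct(uniq, pf), pct(pf, tot))
  )
  list(by_sample = lane_summary, grand = grand, fractions = fractions)
}

#' Call transcriptionally active genes
#'
#' A gene is transcriptionally active when its raw counts summed across all
#' lanes of the experiment reach `min_raw` (default 2 uniquely mapped raw
#' counts). The breakdown reports expressed counts and percentages per
#' annotation confidence class.
#'
#' @param cm A [count_matrix()].
#' @param annotation Gene annotation tibble with `gene_id` and `confidence`
#'   columns. Genes present in the counts but absent from the annotation are
#'   reported as `unclassified` with a warning.
#' @param min_raw Minimum summed raw count (default 2).
#' @return List with `expressed` (character vector of gene ids) and
#'   `breakdown` (tibble: confidence, n_expressed, n_annotated, pct).
#' @export
call_expressed <- function(cm, annotation, min_raw = 2) {
  vals <- count_values(cm)
  totals <- rowSums(vals)
  expressed <- names(totals)[totals >= min_raw]
  ann <- as_tibble(annotation)
  assert_cols(ann, c("gene_id", "confidence"), "annotation")
  missing <- setdiff(cm$counts$gene_id, ann$gene_id)
  if (length(missing) > 0L) {
    warn(sprintf("%d genes in counts missing from annotation; counted as unclassified",
                 length(missing)))
    ann <- bind_rows(ann, tibble(gene_id = missing, confidence = "unclassified"))
  }
  status <- tibble(gene_id = names(totals), expressed = totals >= min_raw) |>
    left_join(select(ann, "gene_id", "confidence"), by = "gene_id")
  breakdown <- status |>
    group_by(.data$confidence) |>
    summarise(
      n_expressed = sum(.data$expressed),
      n_annotated = n(),
      pct = round1(100 * sum(.data$expressed) / n()),
      .groups = "drop"
    )
  list(expressed = expressed, breakdown = breakdown)
}

#' Percentage breakdown helper
#'
#' Printed-precision percentage of a count over a denominator, the rounding
#' convention used throughout the QC reports (one decimal).
#'
#' @param x Numerator count.
#' @param total Denominator count.
#' @return `round(100 * x / total, 1)`, `NA` for a zero denominator.
#' @export
pct_of <- function(x, total) {
  ifelse(total > 0, round1(100 * x / total), NA_real_)
}

#' Quantile-normalize counts across lanes
#'
#' Forces every lane to share the same empirical distribution: the mean of
#' the cross-lane order statistics. Run once over all lanes jointly so every
#' sample is comparable, which also equalizes library sizes ahead of the
#' exact test. Ties within a lane receive the mean of the quantile span they
#' occupy.
#'
#' @param cm A [count_matrix()].
#' @return The count matrix with a `normalized` table added.
#' @export
quantile_normalize <- function(cm) {
  vals <- count_values(cm)
  if (ncol(vals) < 2L) {
    warn("single lane: quantile normalization is a no-op")
    norm <- vals
  } else {
    norm <- limma::normalizeQuantiles(vals, ties = TRUE)
  }
  out <- as_tibble(norm)
  out <- bind_cols(tibble(gene_id = cm$counts$gene_id), out)
  cm$normalized <- out
  cm
}

#' Per-group median sequencing depth
#'
#' Sequencing depth of a gene in a lane is `count * read_length /
#' exonic_length` (coverage, in X units); the profile reports the median
#' across the biological replicates of each tissue/condition sample. A raw
#' count mode (depth = count) is available for sensitivity checks.
#'
#' @param cm A [count_matrix()].
#' @param annotation Annotation tibble with `gene_id` and `length` columns.
#' @param read_length Read length in bp (default 50).
#' @param mode `"coverage"` (default) or `"raw_count"`.
#' @param normalized Use normalized counts when available (default TRUE).
#' @return Tibble: `gene_id`, `tissue`, `condition`, `group`, `median_depth`.
#' @export
depth_profile <- function(cm, annotation, read_length = 50,
                          mode = c("coverage", "raw_count"),
                          normalized = TRUE) {
  mode <- match.arg(mode)
  ann <- as_tibble(annotation)
  assert_cols(ann, c("gene_id", "length"), "annotation")
  if (any(ann$length <= 0)) abort_format("gene lengths must be positive")
  use_norm <- normalized && !is.null(cm$normalized)
  vals <- count_values(cm, normalized = use_norm)
  len <- ann$length[match(rownames(vals), ann$gene_id)]
  if (anyNA(len)) abort_design("annotation is missing lengths for some genes in counts")
  depth <- if (mode == "coverage") vals * read_length / len else vals
  grp <- paste(cm$samples$tissue, cm$samples$condition, sep = ".")
  out <- lapply(unique(grp), function(g) {
    sub <- depth[, grp == g, drop = FALSE]
    tibble(
      gene_id = rownames(vals),
      tissue = cm$samples$tissue[match(g, grp)],
      condition = cm$samples$condition[match(g, grp)],
      group = g,
      median_depth = as.numeric(apply(sub, 1L, median))
    )
  })
  bind_rows(out)
}

#' Bin genes by median sequencing depth
#'
#' Partitions genes of each sample group into depth bins. The default edges
#' reproduce the conventional summary binning: exactly zero, (0,1], (1,2],
#' (2,5], (5,10], (10,50], >50 (in X units).
#'
#' @param profile Output of [depth_profile()].
#' @param edges Increasing positive bin edges (default `c(1, 2, 5, 10, 50)`).
#' @return Tibble: `group`, `bin`, `n`; bins partition all genes.
#' @export
depth_bins <- function(profile, edges = c(1, 2, 5, 10, 50)) {
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0)) {
    abort_config("depth bin edges must be strictly increasing and positive")
  }
  brk <- c(0, edges, Inf)
  labels <- c(
    sprintf("<=%gx", edges[1]),
    sprintf("(%gx,%gx]", edges[-length(edges)], edges[-1]),
    sprintf(">%gx", edges[length(edges)])
  )
  profile |>
    mutate(bin = if_else(
      .data$median_depth == 0, "0x",
      as.character(cut(.data$median_depth, breaks = brk, labels = labels,
                       include.lowest = FALSE, right = TRUE))
    )) |>
    mutate(bin = factor(.data$bin, levels = c("0x", labels))) |>
    count(.data$group, .data$bin, .drop = FALSE, name = "n")
}

#' Between-replicate correlation of counts
#'
#' For each tissue/condition group, correlation of per-gene counts between
#' every pair of biological replicates. Both Spearman and Pearson
#' coefficients are reported.
#'
#' @param cm A [count_matrix()].
#' @param normalized Use normalized counts when available (default TRUE).
#' @return Tibble: `group`, `lane_a`, `lane_b`, `spearman`, `pearson`.
#' @export
replicate_correlation <- function(cm, normalized = TRUE) {
  use_norm <- normalized && !is.null(cm$normalized)
  vals <- count_values(cm, normalized = use_norm)
  grp <- paste(cm$samples$tissue, cm$samples$condition, sep = ".")
  res <- list()
  for (g in unique(grp)) {
    lanes <- cm$samples$lane[grp == g]
    if (length(lanes) < 2L) next
    prs <- utils::combn(lanes, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1L, j]; b <- prs[2L, j]
      res[[length(res) + 1L]] <- tibble(
        group = g, lane_a = a, lane_b = b,
        spearman = cor(vals[, a], vals[, b], method = "spearman"),
        pearson = cor(vals[, a], vals[, b], method = "pearson")
      )
    }
  }
  bind_rows(res)
}
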