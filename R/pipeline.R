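#' Assemble a pipeline run configuration
#'
#' Collects input paths and thresholds for an end-to-end run. All
#' thresholds default to the standard filter cascade: adjusted p < 0.05,
#' |log2FC| >= 1, median depth >= 2X, enrichment criterion Z >= 2 with
#' expected count > 1.
#'
#' @param counts,samples,annotation,pathways,collapse_map,go,tf,motifs,genome,gff,orthologs
#'   Input file paths (TSV, FASTA, GFF3). `collapse_map`, `go`, `tf`,
#'   `motifs`, `genome`, `gff`, `orthologs` may be `NULL` to skip the
#'   corresponding stage.
#' @param drought_lists Named list (species -> path to one-column TSV of
#'   drought-responsive ortholog ids).
#' @param out_dir Output directory.
#' @param alpha,min_lfc,min_depth DE filter thresholds.
#' @param z_min,min_expected Enrichment criterion thresholds.
#' @param variance Variance model for the Z-score engine.
#' @param read_length Read length for depth computation.
#' @param seed Seed for any stochastic step.
#' @return List of class `run_config`.
#' @export
run_config <- function(counts, samples, annotation,
                       pathways = NULL, collapse_map = NULL,
                       go = NULL, tf = NULL, motifs = NULL,
                       genome = NULL, gff = NULL,
                       orthologs = NULL, drought_lists = NULL,
                       out_dir = "droughtseq_out",
                       alpha = 0.05, min_lfc = 1, min_depth = 2,
                       z_min = 2, min_expected = 1,
                       variance = "hypergeometric",
                       read_length = 50, seed = 1) {
  structure(
    list(
      counts = counts, samples = samples, annotation = annotation,
      pathways = pathways, collapse_map = collapse_map, go = go, tf = tf,
      motifs = motifs, genome = genome, gff = gff, orthologs = orthologs,
      drought_lists = drought_lists, out_dir = out_dir,
      alpha = alpha, min_lfc = min_lfc, min_depth = min_depth,
      z_min = z_min, min_expected = min_expected, variance = variance,
      read_length = read_length, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML document
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Validate a run configuration
#'
#' Report-only exhaustive check: referenced files must exist, thresholds
#' must lie in their documented ranges, and the sample sheet must give
#' every contrast at least two replicates per group.
#'
#' @param config A `run_config`.
#' @return Tibble of problems (`field`, `problem`); zero rows when valid.
#' @export
validate_config <- function(config) {
  probs <- list()
  note <- function(field, problem) {
    probs[[length(probs) + 1L]] <<- tibble(field = field, problem = problem)
  }
  required_files <- c("counts", "samples", "annotation")
  optional_files <- c("pathways", "collapse_map", "go", "tf", "motifs",
                      "genome", "gff", "orthologs")
  for (f in required_files) {
    if (is.null(config[[f]])) note(f, "missing required input path")
    else if (!file.exists(config[[f]])) note(f, sprintf("file not found: %s", config[[f]]))
  }
  for (f in optional_files) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      note(f, sprintf("file not found: %s", config[[f]]))
    }
  }
  if (!is.null(config$drought_lists)) {
    for (sp in names(config$drought_lists)) {
      if (!file.exists(config$drought_lists[[sp]])) {
        note(paste0("drought_lists$", sp),
             sprintf("file not found: %s", config$drought_lists[[sp]]))
      }
    }
  }
  if (config$alpha <= 0 || config$alpha > 1) note("alpha", "must lie in (0, 1]")
  if (config$min_lfc < 0) note("min_lfc", "must be >= 0")
  if (config$min_depth < 0) note("min_depth", "must be >= 0")
  if (config$z_min < 0) note("z_min", "must be >= 0")
  if (config$read_length <= 0) note("read_length", "must be > 0")
  if (!config$variance %in% c("hypergeometric", "poisson")) {
    note("variance", "must be 'hypergeometric' or 'poisson'")
  }
  if (!is.null(config$samples) && file.exists(config$samples)) {
    sheet <- tryCatch(
      readr::read_tsv(config$samples, show_col_types = FALSE, progress = FALSE),
      error = function(e) NULL
    )
    if (!is.null(sheet) && all(c("tissue", "condition", "contrast") %in% names(sheet))) {
      reps <- sheet |>
        count(.data$tissue, .data$condition)
      if (any(reps$n < 2L)) {
        note("samples", "a contrast group has fewer than 2 replicates")
      }
    }
  }
  if (length(probs) == 0L) {
    return(tibble(field = character(), problem = character()))
  }
  bind_rows(probs)
}

write_stage <- function(tbl, dir, name, manifest) {
  path <- file.path(dir, name)
  readr::write_tsv(tbl, path)
  manifest$outputs <- c(manifest$outputs, path)
  manifest$rows[[name]] <- nrow(tbl)
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes normalize -> differential expression (per tissue/contrast) ->
#' pathway, TF, GO and cis-element enrichment -> reaction coverage ->
#' cross-talk network -> ortholog triage, writing one TSV per stage plus a
#' JSON manifest recording input hashes, thresholds and output files.
#' Stages whose inputs are not configured are skipped. Deterministic:
#' rerunning with the same inputs and seed reproduces every table byte for
#' byte.
#'
#' @param config A `run_config` (see [run_config()], [read_run_config()]).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_all <- function(config) {
  probs <- validate_config(config)
  if (nrow(probs) > 0L) {
    abort_config(paste0(
      "invalid configuration:\n",
      paste(sprintf("- %s: %s", probs$field, probs$problem), collapse = "\n")
    ))
  }
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  in_files <- purrr::compact(config[c("counts", "samples", "annotation",
                                      "pathways", "collapse_map", "go", "tf",
                                      "motifs", "genome", "gff", "orthologs")])
  manifest <- list(
    package_version = as.character(utils::packageVersion("droughtseq")),
    seed = config$seed,
    thresholds = config[c("alpha", "min_lfc", "min_depth", "z_min",
                          "min_expected", "variance", "read_length")],
    inputs = lapply(in_files, function(p) unname(tools::md5sum(p))),
    outputs = character(), rows = list()
  )
  stage <- function(name) message(sprintf("[droughtseq] stage: %s", name))

  stage("load + normalize")
  cm <- read_counts(config$counts, config$samples)
  annotation <- readr::read_tsv(config$annotation, show_col_types = FALSE,
                                progress = FALSE)
  cm <- quantile_normalize(cm)
  manifest <- write_stage(cm$normalized, config$out_dir,
                          "normalized_counts.tsv", manifest)

  stage("expressed genes")
  expr <- call_expressed(cm, annotation)
  manifest <- write_stage(expr$breakdown, config$out_dir,
                          "expressed_breakdown.tsv", manifest)

  stage("depth profile")
  prof <- depth_profile(cm, annotation, read_length = config$read_length)
  bins <- depth_bins(prof)
  manifest <- write_stage(bins, config$out_dir, "depth_bins.tsv", manifest)

  stage("differential expression")
  contexts <- distinct(cm$samples, .data$tissue, .data$contrast)
  de_tables <- list()
  for (i in seq_len(nrow(contexts))) {
    tis <- contexts$tissue[i]; ctr <- contexts$contrast[i]
    conds <- cm$samples |>
      filter(.data$tissue == tis, .data$contrast == ctr) |>
      pull(.data$condition) |>
      unique()
    if (length(conds) != 2L) next
    # treatment condition shares the contrast's name in the sample sheet
    treat <- if (ctr %in% conds) ctr else conds[1L]
    ctrl <- setdiff(conds, treat)
    con <- define_contrast(cm, tis, treat, ctrl)
    disp <- estimate_common_dispersion(cm, con)
    fit <- exact_test(cm, con, disp)
    det <- apply_de_filters(fit, prof, min_median_depth = config$min_depth,
                            min_abs_lfc = config$min_lfc, alpha = config$alpha)
    de_tables[[con$name]] <- det
    manifest <- write_stage(det, config$out_dir,
                            sprintf("de_%s.tsv", con$name), manifest)
  }
  de_lists <- purrr::map(de_tables, ~ filter(.x, .data$is_de))
  if (length(de_lists) >= 2L) {
    ov <- overlap_sets(purrr::map(de_lists, ~ select(.x, "gene_id", "logFC")))
    manifest <- write_stage(ov$pairwise, config$out_dir,
                            "de_overlaps.tsv", manifest)
  }
  de_union <- unique(unlist(purrr::map(de_lists, "gene_id")))

  if (!is.null(config$pathways)) {
    stage("pathway enrichment + network")
    ptab <- readr::read_tsv(config$pathways, show_col_types = FALSE,
                            progress = FALSE)
    cmap <- if (!is.null(config$collapse_map)) {
      readr::read_tsv(config$collapse_map, show_col_types = FALSE,
                      progress = FALSE)
    }
    db <- pathway_db(ptab, collapse_map = cmap)
    pe <- enrich(de_union, pathway_categories(db), variance = config$variance,
                 z_min = config$z_min, alpha = config$alpha,
                 min_expected = config$min_expected)
    manifest <- write_stage(pe, config$out_dir, "enrich_pathways.tsv", manifest)
    rc <- reaction_coverage(db, de_union)
    manifest <- write_stage(rc, config$out_dir, "reaction_coverage.tsv", manifest)
    cdb <- collapse_pathways(db)
    de_dir <- bind_rows(de_lists) |>
      distinct(.data$gene_id, .keep_all = TRUE) |>
      select("gene_id", "direction")
    pg <- build_network(cdb, de_dir)
    paths <- export_network(pg, config$out_dir, "network")
    manifest$outputs <- c(manifest$outputs, unname(paths))
    if (sum(pg$nodes$is_hormone) >= 2L) {
      hs <- hormone_subnetwork(pg)
      hpaths <- export_network(hs, config$out_dir, "hormone_network")
      manifest$outputs <- c(manifest$outputs, unname(hpaths))
    }
  }

  if (!is.null(config$tf)) {
    stage("TF family enrichment")
    tf <- readr::read_tsv(config$tf, show_col_types = FALSE, progress = FALSE)
    tdb <- category_db(rename(tf, category = "family"), kind = "tf_family")
    te <- enrich(de_union, tdb, variance = config$variance,
                 z_min = config$z_min, alpha = config$alpha,
                 min_expected = config$min_expected)
    manifest <- write_stage(te, config$out_dir, "enrich_tf.tsv", manifest)
  }

  if (!is.null(config$go)) {
    stage("GO enrichment (length-bias corrected)")
    go <- readr::read_tsv(config$go, show_col_types = FALSE, progress = FALSE)
    gdb <- load_go_pairs(go)
    ge <- go_enrich(de_union, gdb,
                    select(annotation, "gene_id", "length"),
                    alpha = config$alpha)
    manifest <- write_stage(ge, config$out_dir, "enrich_go.tsv", manifest)
  }

  if (!is.null(config$genome) && !is.null(config$gff) && !is.null(config$motifs)) {
    stage("promoter scan + cis-element enrichment")
    mot <- readr::read_tsv(config$motifs, show_col_types = FALSE,
                           progress = FALSE)
    prom <- extract_upstream(config$genome, config$gff)
    hits <- scan_motifs(prom, mot)
    manifest <- write_stage(hits, config$out_dir, "motif_hits.tsv", manifest)
    me <- motif_enrichment(hits, de_union, universe = prom$gene_id,
                           variance = config$variance, z_min = config$z_min,
                           alpha = config$alpha,
                           min_expected = config$min_expected)
    manifest <- write_stage(me, config$out_dir, "enrich_motifs.tsv", manifest)
  }

  if (!is.null(config$orthologs) && length(config$drought_lists) > 0L) {
    stage("ortholog decision tree")
    orth <- readr::read_tsv(config$orthologs, show_col_types = FALSE,
                            progress = FALSE)
    dlists <- lapply(config$drought_lists, function(p) {
      readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)[[1L]]
    })
    unk <- call_unknown(select(annotation, "gene_id", "description"))
    pairs <- ortholog_decision_tree(de_union, unk, orth, dlists)
    manifest <- write_stage(pairs, config$out_dir, "ortholog_pairs.tsv", manifest)
    if (dplyr::n_distinct(pairs$species) >= 2L) {
      ovl <- species_overlap(pairs)
      jsonlite::write_json(
        list(regions = select(ovl$regions, "region", "n"),
             all_species = ovl$all_species,
             two_or_more = ovl$two_or_more),
        file.path(config$out_dir, "ortholog_overlap.json"),
        auto_unbox = TRUE, digits = NA
      )
      manifest$outputs <- c(manifest$outputs,
                            file.path(config$out_dir, "ortholog_overlap.json"))
    }
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
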