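#' Configuration for the synthetic experiment generator
#'
#' Describes the simulated study design: two tissues, each with a
#' treatment/control contrast pair (hormone treatment vs its solvent
#' control, osmoticum vs water), three biological replicate runs, and
#' negative-binomially distributed gene counts with spiked log2 fold
#' changes. Defaults emulate a typical deep bulk RNA-seq experiment of this
#' design: log-normal baseline expression around 50 counts per lane,
#' common dispersion 0.1, 17% of gene models silent everywhere, 5% of
#' genes spiked per contrast at |log2FC| in {1.5, 2}, 50-bp reads and
#' ~1-kb exonic gene lengths. One replicate run is scaled x1.3 to inject
#' the library-size imbalance that quantile normalization must remove
#' (mirroring a base-caller upgrade between runs).
#'
#' @param n_genes Number of gene models (default 10000).
#' @param tissues Tissue labels (default shoot, root).
#' @param contrasts Tibble with `contrast`, `treatment`, `control` columns
#'   (default ABA vs NaOH and PEG vs H2O).
#' @param n_reps Biological replicates per condition (default 3; >= 2
#'   required).
#' @param mean_meanlog,mean_sdlog Log-normal parameters for baseline gene
#'   means.
#' @param dispersion Common NB dispersion phi (>= 0; 0 gives Poisson
#'   counts).
#' @param spike_fraction Fraction of genes given a true nonzero log2 fold
#'   change per contrast.
#' @param spike_lfc_values True log2 fold changes sampled for spiked genes.
#' @param silent_fraction Fraction of genes with zero expression
#'   everywhere.
#' @param read_length Read length in bp (default 50).
#' @param length_meanlog,length_sdlog Log-normal parameters for exonic gene
#'   lengths (bp; truncated below at `min_length`).
#' @param min_length Minimum exonic length (default 200).
#' @param lane_scale_run Per-run library scale factors, length `n_reps`.
#' @param promoter_window Upstream window length for the synthetic genome
#'   (default 1000).
#' @param n_pathways,n_hormone_pathways,n_go_terms,n_tf_families Category
#'   database sizes.
#' @param enrichment_odds Odds with which planted enriched categories
#'   prefer true-DE genes (default 5; 1 = null construction).
#' @param motif_background_rate Probability a background promoter receives
#'   a planted instance of the enriched motif (default 0.1).
#' @param n_conserved_unknown Size of the planted conserved
#'   unknown-function ortholog set (default 12).
#' @param species Non-focal species for the ortholog tables.
#' @param seed Global seed; all sub-generators derive deterministic child
#'   seeds from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10000,
                              tissues = c("shoot", "root"),
                              contrasts = tibble(
                                contrast = c("ABA", "PEG"),
                                treatment = c("ABA", "PEG"),
                                control = c("NaOH", "H2O")
                              ),
                              n_reps = 3,
                              mean_meanlog = log(50), mean_sdlog = 1,
                              dispersion = 0.1,
                              spike_fraction = 0.05,
                              spike_lfc_values = c(-2, -1.5, 1.5, 2),
                              silent_fraction = 0.17,
                              read_length = 50,
                              length_meanlog = log(1000), length_sdlog = 0.35,
                              min_length = 200,
                              lane_scale_run = NULL,
                              promoter_window = 1000,
                              n_pathways = 60,
                              n_hormone_pathways = 6,
                              n_go_terms = 80,
                              n_tf_families = 20,
                              enrichment_odds = 5,
                              motif_background_rate = 0.1,
                              n_conserved_unknown = 12,
                              species = c("rice", "maize", "arabidopsis"),
                              seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), tissues = tissues,
    contrasts = as_tibble(contrasts), n_reps = as.integer(n_reps),
    mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
    dispersion = dispersion, spike_fraction = spike_fraction,
    spike_lfc_values = spike_lfc_values, silent_fraction = silent_fraction,
    read_length = read_length, length_meanlog = length_meanlog,
    length_sdlog = length_sdlog, min_length = min_length,
    lane_scale_run = lane_scale_run %||%
      c(rep(1, max(0L, as.integer(n_reps) - 1L)), 1.3),
    promoter_window = as.integer(promoter_window),
    n_pathways = n_pathways, n_hormone_pathways = n_hormone_pathways,
    n_go_terms = n_go_terms, n_tf_families = n_tf_families,
    enrichment_odds = enrichment_odds,
    motif_background_rate = motif_background_rate,
    n_conserved_unknown = n_conserved_unknown, species = species,
    seed = as.integer(seed)
  )
  assert_cols(cfg$contrasts, c("contrast", "treatment", "control"), "contrasts")
  if (cfg$n_reps < 2L) abort_config("any tested contrast needs >= 2 replicates")
  if (any(duplicated(c(cfg$contrasts$treatment, cfg$contrasts$control)))) {
    abort_config("conditions must be distinct across contrasts")
  }
  if (nrow(cfg$contrasts) == 0L || any(is.na(cfg$contrasts$control)) ||
      any(cfg$contrasts$control == "")) {
    abort_config("every contrast needs a control condition")
  }
  if (cfg$spike_fraction + cfg$silent_fraction > 1) {
    abort_config("spike_fraction + silent_fraction must be <= 1")
  }
  if (cfg$dispersion < 0) abort_config("dispersion must be >= 0")
  if (cfg$min_length <= 0 || cfg$promoter_window <= 0 || cfg$read_length <= 0) {
    abort_config("lengths must be positive")
  }
  if (length(cfg$lane_scale_run) != cfg$n_reps) {
    abort_config("lane_scale_run must have one entry per replicate run")
  }
  structure(cfg, class = "simulation_config")
}

# sample() treats a scalar first argument as 1:x; this sampler always
# samples from the elements of x.
sample_from <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

sim_gene_ids <- function(n) {
  chr <- ((seq_len(n) - 1L) %/% ceiling(n / 10)) + 1L
  idx <- seq_len(n)
  sprintf("Sb%02dg%06d", chr, idx * 10L)
}

#' Simulate lane-level gene counts with ground truth
#'
#' Draws negative-binomial counts for the full design (every tissue,
#' condition and replicate run), with a planted fraction of silent genes
#' and a planted set of spiked genes per tissue/contrast whose true log2
#' fold changes are recorded. The spike pools of the contrasts overlap so
#' that cross-contrast DE overlaps are non-trivial. Deterministic under a
#' fixed seed.
#'
#' @param config A [simulation_config()].
#' @return List: `cm` (a [count_matrix()]), `truth` (list with `lfc`
#'   tibble (`gene_id`, `tissue`, `contrast`, `lfc`), `silent` gene ids,
#'   `baseline_mean`, `lengths` tibble).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_config("config must come from simulation_config()")
  }
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_genes
  genes <- sim_gene_ids(n)
  lengths <- pmax(config$min_length,
                  round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
  base_mean <- rlnorm(n, config$mean_meanlog, config$mean_sdlog)
  silent <- sort(sample.int(n, floor(config$silent_fraction * n)))
  base_mean[silent] <- 0
  active <- setdiff(seq_len(n), silent)
  n_spike <- floor(config$spike_fraction * n)
  pool <- sample_from(active, min(length(active), ceiling(1.5 * n_spike)))
  contexts <- tidyr::expand_grid(
    tissue = config$tissues,
    contrast = config$contrasts$contrast
  )
  truth_lfc <- purrr::pmap_dfr(contexts, function(tissue, contrast) {
    idx <- sample_from(pool, min(n_spike, length(pool)))
    tibble(
      gene_id = genes[idx], tissue = tissue, contrast = contrast,
      lfc = sample_from(config$spike_lfc_values, length(idx), replace = TRUE)
    )
  })
  cond_map <- bind_rows(
    tibble(condition = config$contrasts$treatment,
           contrast = config$contrasts$contrast, is_treatment = TRUE),
    tibble(condition = config$contrasts$control,
           contrast = config$contrasts$contrast, is_treatment = FALSE)
  )
  samples <- tidyr::expand_grid(
    tissue = config$tissues,
    condition = cond_map$condition,
    replicate = seq_len(config$n_reps)
  ) |>
    left_join(cond_map, by = "condition") |>
    mutate(lane = sprintf("%s_%s_r%d", .data$tissue, .data$condition,
                          .data$replicate))
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(genes, samples$lane))
  phi <- config$dispersion
  for (j in seq_len(nrow(samples))) {
    s <- samples[j, ]
    mu <- base_mean * config$lane_scale_run[s$replicate]
    if (s$is_treatment) {
      spk <- truth_lfc |>
        filter(.data$tissue == s$tissue, .data$contrast == s$contrast)
      if (nrow(spk) > 0L) {
        idx <- match(spk$gene_id, genes)
        mu[idx] <- mu[idx] * 2^spk$lfc
      }
    }
    pos <- mu > 0
    draw <- integer(n)
    if (phi > 0) {
      draw[pos] <- rnbinom(sum(pos), mu = mu[pos], size = 1 / phi)
    } else {
      draw[pos] <- stats::rpois(sum(pos), mu[pos])
    }
    counts[, j] <- draw
  }
  cm <- count_matrix(
    bind_cols(tibble(gene_id = genes), as_tibble(counts)),
    select(samples, "lane", "tissue", "condition", "contrast", "replicate")
  )
  list(
    cm = cm,
    truth = list(
      lfc = truth_lfc,
      silent = genes[silent],
      baseline_mean = setNames(base_mean, genes),
      lengths = tibble(gene_id = genes, length = lengths)
    )
  )
}

# Sample category members, preferring true-DE genes at the given odds.
# odds = 1 gives a membership independent of DE status (null construction).
plant_category <- function(genes, size, de_genes, odds) {
  if (size > length(genes)) {
    abort_config("requested category size exceeds available genes")
  }
  w <- ifelse(genes %in% de_genes, odds, 1)
  genes[sample.int(length(genes), size, prob = w)]
}

UNKNOWN_DESCRIPTIONS <- c(
  "hypothetical protein", "similar to expressed protein",
  "predicted protein", "putative uncharacterized protein"
)

KNOWN_DESCRIPTIONS <- c(
  "peroxidase", "late embryogenesis abundant protein", "dehydrin",
  "sugar transporter", "aquaporin", "heat shock protein",
  "cytochrome P450", "protein kinase", "glycosyl hydrolase",
  "ABC transporter", "zinc finger protein", "ubiquitin ligase"
)

#' Simulate annotation, category, promoter and ortholog resources
#'
#' Generates every non-count input the pipeline consumes, sharing the gene
#' id namespace of a [simulate_counts()] result and planting recoverable
#' signal: category databases (pathways with reactions and a collapse map,
#' GO terms, TF families) with planted enriched categories biased toward
#' the true-DE genes at the configured odds; a synthetic genome FASTA plus
#' GFF3 gene models whose upstream windows contain planted IUPAC motif
#' instances at recorded positions; and a cross-species ortholog table
#' with a planted conserved unknown-function set that passes every branch
#' of the decision tree, plus distractors failing each branch.
#'
#' @param config A [simulation_config()].
#' @param sim A [simulate_counts()] result.
#' @return List: `annotation`, `pathway_table`, `collapse_map`, `go_pairs`,
#'   `tf_pairs`, `motifs`, `genome` (DNAStringSet), `genes_gff` (GRanges),
#'   `ortholog_table`, `drought_lists`, `truth` (planted ground truth).
#' @export
simulate_annotations <- function(config, sim) {
  genes <- sim$cm$counts$gene_id
  n <- length(genes)
  true_de <- unique(sim$truth$lfc$gene_id)

  # --- annotation table ------------------------------------------------
  set.seed(child_seed(config$seed, 2L))
  confidence <- sample(c("high", "low", "noncoding"), n, replace = TRUE,
                       prob = c(0.8, 0.19, 0.01))
  is_unknown_desc <- runif(n) < 0.35
  description <- ifelse(
    is_unknown_desc,
    sample(UNKNOWN_DESCRIPTIONS, n, replace = TRUE),
    paste(sample(KNOWN_DESCRIPTIONS, n, replace = TRUE),
          sample(1:9, n, replace = TRUE))
  )
  annotation <- tibble(
    gene_id = genes,
    description = description,
    confidence = confidence,
    length = sim$truth$lengths$length,
    chromosome = sub("^Sb([0-9]+)g.*$", "\\1", genes),
    pericentromeric = runif(n) < 0.1
  )

  # --- pathway database ------------------------------------------------
  set.seed(child_seed(config$seed, 3L))
  # restrict to a sub-pool so pathways share genes and the network has edges
  pw_pool <- sample_from(genes, min(n, max(500L, round(n * 0.2))))
  pathway_ids <- sprintf("PWY-%03d", seq_len(config$n_pathways))
  hormone_ids <- sample_from(pathway_ids, config$n_hormone_pathways)
  planted_pathways <- sample_from(setdiff(pathway_ids, hormone_ids), 2L)
  pathway_table <- purrr::map_dfr(pathway_ids, function(pid) {
    planted <- pid %in% planted_pathways
    n_rxn <- if (planted) 8L else sample(2:8, 1L)
    odds <- if (planted) config$enrichment_odds else 1
    members <- plant_category(pw_pool, n_rxn * if (planted) 5L else sample(2:4, 1L),
                              true_de, odds)
    tibble(
      pathway_id = pid,
      reaction_id = sprintf("%s.RXN-%02d", pid,
                            sample(seq_len(n_rxn), length(members), replace = TRUE)),
      gene_id = members,
      is_hormone = pid %in% hormone_ids
    )
  })
  # collapse map merges a few variant pairs into family nodes
  variant_pairs <- matrix(sample_from(setdiff(pathway_ids, planted_pathways), 8L),
                          ncol = 2L)
  collapse_map <- tibble(
    pathway_id = as.vector(variant_pairs),
    collapsed_id = rep(sprintf("PWY-FAM-%02d", seq_len(nrow(variant_pairs))),
                       times = 2L)
  )

  # --- GO terms --------------------------------------------------------
  set.seed(child_seed(config$seed, 4L))
  go_ids <- sprintf("GO:%07d", sample.int(1e6, config$n_go_terms))
  planted_go <- sample_from(go_ids, 2L)
  go_pairs <- purrr::map_dfr(go_ids, function(term) {
    odds <- if (term %in% planted_go) config$enrichment_odds else 1
    tibble(gene_id = plant_category(genes, sample(10:100, 1L), true_de, odds),
           term = term)
  })

  # --- TF families -----------------------------------------------------
  set.seed(child_seed(config$seed, 5L))
  tf_ids <- c("AP2-EREBP", "bZIP", "MYB", "NAC", "WRKY", "bHLH", "C2H2",
              "HSF", "GRAS", "ARF")
  tf_ids <- c(tf_ids, sprintf("TF-%02d", seq_len(max(0L, config$n_tf_families -
                                                       length(tf_ids)))))
  tf_ids <- tf_ids[seq_len(config$n_tf_families)]
  planted_tf <- tf_ids[1L]
  tf_pairs <- purrr::map_dfr(tf_ids, function(fam) {
    odds <- if (fam == planted_tf) config$enrichment_odds else 1
    tibble(gene_id = plant_category(genes, sample(10:80, 1L), true_de, odds),
           family = fam)
  })

  # --- motifs, promoters, genome --------------------------------------
  set.seed(child_seed(config$seed, 6L))
  motifs <- tibble(
    name = c("ABRE", "DRE-core", "LTRE", "CGTCA-motif", "MOTIF-R1", "MOTIF-R2"),
    pattern = c("ACGTGGC", "RCCGAC", "CCGAAA", "CGTCA", "TTGACW", "CANNTG")
  )
  planted_motif <- "ABRE"
  win <- config$promoter_window
  p_bg <- config$motif_background_rate
  p_de <- min(1, p_bg * config$enrichment_odds)
  pat <- motifs$pattern[motifs$name == planted_motif]
  plant_p <- ifelse(genes %in% true_de, p_de, p_bg)
  planted <- runif(n) < plant_p
  pos <- ifelse(planted, sample.int(win - nchar(pat) + 1L, n, replace = TRUE),
                NA_integer_)
  promoter_seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), win, replace = TRUE)
    if (planted[i]) {
      inst <- expand_iupac_instance(pat)
      s[pos[i]:(pos[i] + nchar(pat) - 1L)] <- strsplit(inst, "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))
  motif_truth <- tibble(gene_id = genes[planted], motif = planted_motif,
                        position = pos[planted])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  body_len <- annotation$length
  chrom <- paste0("chr", annotation$chromosome)
  spacer <- 50L
  seg_len <- win + body_len + spacer
  genome_parts <- list()
  gff_rows <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    offs <- cumsum(c(0L, seg_len[idx][-length(idx)]))
    parts <- character(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      body <- paste(sample(c("A", "C", "G", "T"), body_len[i], replace = TRUE),
                    collapse = "")
      spc <- paste(sample(c("A", "C", "G", "T"), spacer, replace = TRUE),
                   collapse = "")
      if (strand[i] == "+") {
        parts[k] <- paste0(promoter_seqs[i], body, spc)
        g_start <- offs[k] + win + 1L
        g_end <- offs[k] + win + body_len[i]
      } else {
        parts[k] <- paste0(
          revcomp_chr(body), revcomp_chr(promoter_seqs[i]), spc
        )
        g_start <- offs[k] + 1L
        g_end <- offs[k] + body_len[i]
      }
      gff_rows[[length(gff_rows) + 1L]] <- tibble(
        seqnames = ch, start = g_start, end = g_end,
        strand = strand[i], gene_id = genes[i]
      )
    }
    genome_parts[[ch]] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(genome_parts))
  gff_tbl <- bind_rows(gff_rows)
  genes_gff <- GenomicRanges::GRanges(
    seqnames = gff_tbl$seqnames,
    ranges = IRanges::IRanges(gff_tbl$start, gff_tbl$end),
    strand = gff_tbl$strand,
    type = "gene", ID = gff_tbl$gene_id,
    seqlengths = setNames(Biostrings::width(genome), names(genome))
  )

  # --- orthologs -------------------------------------------------------
  set.seed(child_seed(config$seed, 7L))
  unknown_focal <- annotation$gene_id[
    call_unknown(annotation)$is_unknown
  ]
  cand <- intersect(true_de, unknown_focal)
  if (length(cand) < config$n_conserved_unknown) {
    abort_config("not enough unknown-function true-DE genes to plant the conserved set")
  }
  planted_cons <- sort(sample_from(cand, config$n_conserved_unknown))
  take <- function(x, k) sample_from(x, min(k, length(x)))
  distract_b <- take(setdiff(cand, planted_cons), 5L) # fails all-unknown
  distract_c <- take(setdiff(cand, c(planted_cons, distract_b)), 5L) # fails drought
  distract_nonde <- take(setdiff(unknown_focal, true_de), 5L) # not DE
  prefix <- c(rice = "Os", maize = "Zm", arabidopsis = "At")
  orth_counter <- 0L
  mk_orth <- function(sp, k) {
    orth_counter <<- orth_counter + k
    sprintf("%s_%06d", prefix[[sp]], seq.int(orth_counter - k + 1L, orth_counter))
  }
  rows <- list()
  drought_lists <- setNames(vector("list", length(config$species)), config$species)
  for (sp in config$species) {
    for (g in planted_cons) {
      o <- mk_orth(sp, sample(1:2, 1L))
      rows[[length(rows) + 1L]] <- tibble(
        focal_gene = g, species = sp, ortholog_gene = o,
        ortholog_description = sample(UNKNOWN_DESCRIPTIONS, length(o),
                                      replace = TRUE)
      )
      drought_lists[[sp]] <- c(drought_lists[[sp]], o)
    }
    for (g in distract_b) {
      o <- mk_orth(sp, 2L)
      rows[[length(rows) + 1L]] <- tibble(
        focal_gene = g, species = sp, ortholog_gene = o,
        ortholog_description = c(sample(UNKNOWN_DESCRIPTIONS, 1L),
                                 "peroxidase 6")
      )
      drought_lists[[sp]] <- c(drought_lists[[sp]], o)
    }
    for (g in distract_c) {
      o <- mk_orth(sp, 1L)
      rows[[length(rows) + 1L]] <- tibble(
        focal_gene = g, species = sp, ortholog_gene = o,
        ortholog_description = sample(UNKNOWN_DESCRIPTIONS, 1L)
      )
    }
    for (g in distract_nonde) {
      o <- mk_orth(sp, 1L)
      rows[[length(rows) + 1L]] <- tibble(
        focal_gene = g, species = sp, ortholog_gene = o,
        ortholog_description = sample(UNKNOWN_DESCRIPTIONS, 1L)
      )
      drought_lists[[sp]] <- c(drought_lists[[sp]], o)
    }
    drought_lists[[sp]] <- sort(unique(c(
      drought_lists[[sp]], mk_orth(sp, 10L) # drought genes with no focal ortholog
    )))
  }
  ortholog_table <- bind_rows(rows)

  list(
    annotation = annotation,
    pathway_table = pathway_table,
    collapse_map = collapse_map,
    go_pairs = go_pairs,
    tf_pairs = tf_pairs,
    motifs = motifs,
    genome = genome,
    genes_gff = genes_gff,
    ortholog_table = ortholog_table,
    drought_lists = drought_lists,
    truth = list(
      enriched_pathways = planted_pathways,
      enriched_go = planted_go,
      enriched_tf = planted_tf,
      enriched_motif = planted_motif,
      motif_positions = motif_truth,
      conserved_unknown = planted_cons
    )
  )
}

# One concrete instance of an IUPAC pattern (random choice per degenerate
# position), used when planting motifs into synthetic promoters.
expand_iupac_instance <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(pattern, "")[[1]]
  paste(vapply(ch, function(c1) {
    opts <- strsplit(map[[c1]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate a complete experiment
#'
#' Runs [simulate_counts()] and [simulate_annotations()] under one seed.
#'
#' @param config A [simulation_config()].
#' @return List: `cm`, `annotation`, `pathway_table`, `collapse_map`,
#'   `go_pairs`, `tf_pairs`, `motifs`, `genome`, `genes_gff`,
#'   `ortholog_table`, `drought_lists`, `truth` (counts + planted truth
#'   merged), `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  sim <- simulate_counts(config)
  ann <- simulate_annotations(config, sim)
  truth <- c(sim$truth, ann$truth)
  c(list(cm = sim$cm, truth = truth, config = config),
    ann[setdiff(names(ann), "truth")])
}

#' Write a simulated experiment to disk
#'
#' Serializes every generated input in the pipeline's plain-text formats:
#' counts and sample sheet TSV, annotation TSV, pathway and collapse-map
#' TSV, GO and TF pair TSVs, motif TSV, genome FASTA, gene models GFF3,
#' ortholog TSV, one drought-list TSV per species, and the ground truth as
#' JSON.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    counts = p("counts.tsv"), samples = p("samples.tsv"),
    annotation = p("annotation.tsv"), pathways = p("pathways.tsv"),
    collapse_map = p("collapse_map.tsv"), go = p("go_pairs.tsv"),
    tf = p("tf_pairs.tsv"), motifs = p("motifs.tsv"),
    genome = p("genome.fa"), gff = p("genes.gff3"),
    orthologs = p("orthologs.tsv"), truth = p("ground_truth.json")
  )
  readr::write_tsv(sim$cm$counts, paths[["counts"]])
  readr::write_tsv(sim$cm$samples, paths[["samples"]])
  readr::write_tsv(sim$annotation, paths[["annotation"]])
  readr::write_tsv(sim$pathway_table, paths[["pathways"]])
  readr::write_tsv(sim$collapse_map, paths[["collapse_map"]])
  readr::write_tsv(sim$go_pairs, paths[["go"]])
  readr::write_tsv(sim$tf_pairs, paths[["tf"]])
  readr::write_tsv(sim$motifs, paths[["motifs"]])
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  rtracklayer::export(sim$genes_gff, paths[["gff"]], format = "gff3")
  readr::write_tsv(sim$ortholog_table, paths[["orthologs"]])
  for (sp in names(sim$drought_lists)) {
    dp <- p(sprintf("drought_%s.tsv", sp))
    readr::write_tsv(tibble(ortholog_gene = sim$drought_lists[[sp]]), dp)
    paths[[paste0("drought_", sp)]] <- dp
  }
  truth_json <- list(
    lfc = sim$truth$lfc,
    silent = sim$truth$silent,
    enriched_pathways = sim$truth$enriched_pathways,
    enriched_go = sim$truth$enriched_go,
    enriched_tf = sim$truth$enriched_tf,
    enriched_motif = sim$truth$enriched_motif,
    motif_positions = sim$truth$motif_positions,
    conserved_unknown = sim$truth$conserved_unknown
  )
  jsonlite::write_json(truth_json, paths[["truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
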