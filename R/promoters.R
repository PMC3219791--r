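IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Validate and load an IUPAC motif table
#'
#' Checks every pattern against the IUPAC degenerate nucleotide alphabet and
#' collapses motifs whose sequences are identical (the first name is kept
#' and aliases recorded).
#'
#' @param motifs Tibble with columns `name` and `pattern` (and optionally
#'   `source`).
#' @return Tibble: `name`, `pattern`, `aliases`.
#' @export
load_motifs <- function(motifs) {
  motifs <- as_tibble(motifs)
  assert_cols(motifs, c("name", "pattern"), "motif table")
  motifs <- mutate(motifs, pattern = toupper(.data$pattern))
  bad <- !vapply(strsplit(motifs$pattern, ""),
                 function(ch) length(ch) > 0 && all(ch %in% IUPAC_LETTERS),
                 logical(1))
  if (any(bad)) {
    abort_format(sprintf("invalid IUPAC pattern(s): %s",
                         paste(head(motifs$name[bad], 5), collapse = ", ")))
  }
  motifs |>
    group_by(.data$pattern) |>
    summarise(
      aliases = paste(.data$name[-1], collapse = ","),
      name = .data$name[1],
      .groups = "drop"
    ) |>
    select("name", "pattern", "aliases")
}

#' Extract upstream promoter regions
#'
#' Cuts the `window` bases immediately upstream of each gene's start from
#' the genome, oriented 5'->3' toward the gene: for plus-strand genes the
#' window `[start-window, start-1]` as-is, for minus-strand genes the
#' reverse complement of `[end+1, end+window]`. Windows are truncated at
#' contig boundaries; genes on missing contigs or without strand are
#' skipped with a warning.
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param gff A `GenomicRanges::GRanges` or path to a GFF3 file.
#' @param window Upstream window size in bp (default 1000).
#' @param feature GFF3 feature type to anchor on (default `"gene"`).
#' @param id_attr Attribute holding the gene id (default `"ID"`).
#' @return Tibble: `gene_id`, `seq`, `length`, `truncated`, `strand`,
#'   `contig`.
#' @export
extract_upstream <- function(genome, gff, window = 1000,
                             feature = "gene", id_attr = "ID") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(gff)) gff <- rtracklayer::import(gff, format = "gff3")
  gr <- gff[as.character(gff$type) == feature]
  ids <- S4Vectors::mcols(gr)[[id_attr]]
  if (is.null(ids)) abort_format(sprintf("GFF3 lacks the %s attribute", id_attr))
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  miss <- !(contig %in% names(genome))
  nostrand <- !(strand %in% c("+", "-"))
  if (any(miss)) warn(sprintf("%d genes on contigs absent from the genome; skipped",
                              sum(miss)))
  if (any(nostrand & !miss)) warn(sprintf("%d genes without strand; skipped",
                                          sum(nostrand & !miss)))
  keep <- !miss & !nostrand
  gr <- gr[keep]; ids <- ids[keep]; contig <- contig[keep]; strand <- strand[keep]
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  clen <- Biostrings::width(genome)[match(contig, names(genome))]
  from <- ifelse(strand == "+", pmax(1L, start - window), end + 1L)
  to <- ifelse(strand == "+", start - 1L, pmin(clen, end + window))
  w <- pmax(0L, to - from + 1L)
  seqs <- character(length(gr))
  nonempty <- w > 0L
  if (any(nonempty)) {
    ext <- Biostrings::subseq(genome[contig[nonempty]],
                              start = from[nonempty], end = to[nonempty])
    neg <- strand[nonempty] == "-"
    if (any(neg)) ext[neg] <- Biostrings::reverseComplement(ext[neg])
    seqs[nonempty] <- as.character(ext)
  }
  tibble(
    gene_id = as.character(ids),
    seq = seqs,
    length = w,
    truncated = w < window,
    strand = strand,
    contig = contig
  )
}

#' Scan promoters for IUPAC motifs
#'
#' Reports every (possibly overlapping) match of each degenerate motif in
#' each promoter. Positions are 1-based offsets from the 5' end of the
#' upstream window. In both-strand mode the reverse complement of each
#' motif is also matched and reported on strand `-` (positions still index
#' the forward window and mark the 5'-most base of the matched span). An
#' `N` in the promoter sequence never matches any motif symbol.
#'
#' @param promoters Output of [extract_upstream()] (needs `gene_id`,
#'   `seq`).
#' @param motifs Motif table (validated through [load_motifs()]).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return Tibble: `gene_id`, `motif`, `position`, `strand`.
#' @export
scan_motifs <- function(promoters, motifs, both_strands = TRUE) {
  promoters <- as_tibble(promoters)
  assert_cols(promoters, c("gene_id", "seq"), "promoter set")
  motifs <- load_motifs(motifs)
  keep <- nchar(promoters$seq) > 0L
  subj <- Biostrings::DNAStringSet(promoters$seq[keep])
  names(subj) <- promoters$gene_id[keep]
  seq_by_gene <- setNames(promoters$seq[keep], promoters$gene_id[keep])
  scan_one <- function(pattern, strand_label) {
    hits <- Biostrings::vmatchPattern(pattern, subj, fixed = "subject")
    st <- Biostrings::startIndex(hits)
    lens <- lengths(st)
    if (sum(lens) == 0L) return(NULL)
    out <- tibble(
      gene_id = rep(names(subj), lens),
      position = unlist(st, use.names = FALSE),
      strand = strand_label
    )
    # an N in the promoter must not satisfy any motif symbol, including an
    # N in the motif itself (masked regions never generate hits)
    w <- nchar(pattern)
    span <- substr(seq_by_gene[out$gene_id], out$position, out$position + w - 1L)
    out[!grepl("N", span, fixed = TRUE), ]
  }
  out <- purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    pat <- motifs$pattern[i]
    res <- scan_one(pat, "+")
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
      res <- bind_rows(res, scan_one(rc, "-"))
    }
    if (is.null(res)) return(NULL)
    mutate(res, motif = motifs$name[i])
  })
  if (nrow(out) == 0L) {
    return(tibble(gene_id = character(), motif = character(),
                  position = integer(), strand = character()))
  }
  out |>
    select("gene_id", "motif", "position", "strand") |>
    arrange(.data$motif, .data$gene_id, .data$position)
}

#' Gene-level motif presence
#'
#' Collapses motif hits to one row per (gene, motif): presence means at
#' least one match anywhere in the promoter, so duplicated hits within a
#' promoter do not inflate enrichment counts.
#'
#' @param hits Output of [scan_motifs()].
#' @return Tibble: `gene_id`, `motif`, `n_hits`.
#' @export
motif_presence <- function(hits) {
  hits |>
    count(.data$gene_id, .data$motif, name = "n_hits")
}

#' cis-element enrichment of a DE gene list
#'
#' Treats each motif's presence set (genes whose promoter contains at least
#' one match) as a category over the universe of genes with extracted
#' promoters, and scores it with the Z-score engine under the three-part
#' criterion with a BH-adjusted exact hypergeometric p-value.
#'
#' @param hits Output of [scan_motifs()] computed over the full universe.
#' @param de_genes Character vector of DE gene ids.
#' @param universe All genes with promoters (defaults to the genes present
#'   in `hits`; pass the full promoter set so motif-free genes count).
#' @param ... Passed to [enrich()] (criterion thresholds, variance model).
#' @return An [enrich()] result tibble.
#' @export
motif_enrichment <- function(hits, de_genes, universe = NULL, ...) {
  presence <- motif_presence(hits)
  pairs <- select(presence, "gene_id", category = "motif")
  db <- category_db(pairs, kind = "motif", scaffold_pattern = NULL)
  if (!is.null(universe)) {
    db$universe <- unique(universe)
    outside <- setdiff(db$pairs$gene_id, db$universe)
    if (length(outside) > 0L) {
      db$pairs <- filter(db$pairs, .data$gene_id %in% db$universe)
    }
  }
  enrich(de_genes, db, p_source = "hypergeometric", adjust = "BH", ...)
}
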