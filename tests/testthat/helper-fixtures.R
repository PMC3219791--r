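# Shared fixture builders and independent oracles. Oracles are deliberately
# written with different machinery than the implementation they check.

# Minimal count matrix: counts given as a genes x lanes matrix.
toy_count_matrix <- function(counts, tissue = NULL, condition = NULL,
                             contrast = NULL) {
  n_lane <- ncol(counts)
  lanes <- colnames(counts) %||% paste0("L", seq_len(n_lane))
  colnames(counts) <- lanes
  genes <- rownames(counts) %||% paste0("g", seq_len(nrow(counts)))
  samples <- tibble::tibble(
    lane = lanes,
    tissue = tissue %||% rep("shoot", n_lane),
    condition = condition %||% rep(c("trt", "ctl"), length.out = n_lane),
    contrast = contrast %||% rep("trt", n_lane),
    replicate = stats::ave(seq_len(n_lane),
                           paste(tissue %||% "shoot", condition %||% ""),
                           FUN = seq_along)
  )
  count_matrix(
    dplyr::bind_cols(tibble::tibble(gene_id = genes),
                     tibble::as_tibble(counts)),
    samples
  )
}

# A balanced two-group count matrix (n vs n lanes, one tissue).
two_group_cm <- function(counts_trt, counts_ctl) {
  m <- cbind(counts_trt, counts_ctl)
  n1 <- ncol(counts_trt); n2 <- ncol(counts_ctl)
  colnames(m) <- c(paste0("T", seq_len(n1)), paste0("C", seq_len(n2)))
  toy_count_matrix(
    m,
    tissue = rep("shoot", n1 + n2),
    condition = rep(c("trt", "ctl"), c(n1, n2)),
    contrast = rep("trt", n1 + n2)
  )
}

# Independent quantile-normalization oracle: explicit rank-average dialect
# (ties get the mean of the reference means their ranks span).
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "average")
    lo <- floor(rk); hi <- ceiling(rk)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

# IUPAC regex oracle: expand degenerate codes into character classes and
# find all overlapping matches with a lookahead regex.
IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_regex_scan <- function(seqs, pattern) {
  rex <- paste(IUPAC_REGEX[strsplit(pattern, "")[[1]]], collapse = "")
  hits <- gregexpr(paste0("(?=", rex, ")"), seqs, perl = TRUE)
  lapply(hits, function(h) {
    p <- as.integer(h)
    p[p > 0]
  })
}

revcomp_str <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Sequential biased-urn Monte-Carlo oracle for the Wallenius distribution:
# draw n balls one at a time, category balls with odds omega.
urn_simulate <- function(n_draws, N, K, n, omega, seed) {
  set.seed(seed)
  k_rem <- rep(K, n_draws)
  m_rem <- rep(N - K, n_draws)
  taken <- integer(n_draws)
  for (i in seq_len(n)) {
    p_cat <- omega * k_rem / (omega * k_rem + m_rem)
    hit <- stats::runif(n_draws) < p_cat
    k_rem <- k_rem - hit
    m_rem <- m_rem - !hit
    taken <- taken + hit
  }
  taken
}

# Brute-force pairwise shared-DE-gene oracle for the cross-talk network.
network_oracle_edges <- function(pathway_genes, de_genes) {
  ids <- names(pathway_genes)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      shared <- length(intersect(
        intersect(pathway_genes[[i]], de_genes),
        intersect(pathway_genes[[j]], de_genes)
      ))
      if (shared >= 1) {
        out[[length(out) + 1L]] <- tibble::tibble(
          from = ids[i], to = ids[j], weight = shared
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = integer()))
  }
  dplyr::bind_rows(out)
}

# Exhaustive enumeration of all simple paths (for shortest-path tie checks
# on small graphs).
all_simple_paths_nodes <- function(edges, from, to, max_len = 10) {
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  paths <- list()
  walk <- function(node, visited) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())
    }
    if (length(visited) > max_len) return(invisible())
    for (nb in adj[[node]] %||% character(0)) {
      if (!nb %in% visited) walk(nb, c(visited, nb))
    }
  }
  walk(from, from)
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a
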