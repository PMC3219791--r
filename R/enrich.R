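#' Build a gene-category database
#'
#' Generic gene-to-category mapping used for metabolic pathways, TF
#' families, GO terms and cis-element presence sets. Pairs are deduplicated;
#' gene models on unassembled scaffolds are removed on load; the enrichment
#' universe is the set of unique genes across all categories (never the sum
#' of category sizes).
#'
#' @param pairs Tibble with columns `gene_id` and `category`.
#' @param kind One of `"pathway"`, `"tf_family"`, `"motif"`, `"go"`,
#'   `"other"`.
#' @param scaffold_pattern Regular expression for scaffold gene ids to drop
#'   (default matches the `Sb###s######` shape); `NULL` disables.
#' @return List of class `category_db`: `pairs`, `universe`, `kind`.
#' @export
category_db <- function(pairs, kind = c("pathway", "tf_family", "motif", "go", "other"),
                        scaffold_pattern = SCAFFOLD_PATTERN) {
  kind <- match.arg(kind)
  pairs <- as_tibble(pairs)
  assert_cols(pairs, c("gene_id", "category"), "category pairs")
  pairs <- distinct(pairs, .data$gene_id, .data$category)
  if (!is.null(scaffold_pattern)) {
    pairs <- filter(pairs, !is_scaffold_id(.data$gene_id, scaffold_pattern))
  }
  structure(
    list(pairs = pairs, universe = unique(pairs$gene_id), kind = kind),
    class = "category_db"
  )
}

#' @export
print.category_db <- function(x, ...) {
  cat(sprintf("<category_db:%s> %d categories, %d genes in universe\n",
              x$kind, dplyr::n_distinct(x$pairs$category), length(x$universe)))
  invisible(x)
}

#' Expected category count under a random draw
#'
#' `E = n * K / N`: the number of DE genes expected inside a category of
#' size `K` when `n` DE genes are drawn from a universe of `N` genes.
#'
#' @param n Number of DE genes in the universe.
#' @param K Category size.
#' @param N Universe size.
#' @return Expected count (numeric).
#' @export
expected_count <- function(n, K, N) {
  if (any(N == 0)) abort_config("empty universe")
  n * K / N
}

# Variance of the category overlap under the configured null model.
overlap_variance <- function(n, K, N, model = c("hypergeometric", "poisson")) {
  model <- match.arg(model)
  if (model == "poisson") return(expected_count(n, K, N))
  n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
}

#' Z-score for category enrichment
#'
#' `Z = (O - E) / sqrt(V)` with `E = n K / N` and `V` from the configured
#' variance model: hypergeometric (sampling without replacement; default) or
#' Poisson (`V = E`). The accompanying p-value is the one-sided upper-tail
#' normal probability (enrichment direction only). Degenerate cases
#' (`V = 0`) are flagged rather than scored.
#'
#' @param O Observed overlap.
#' @param n,K,N Overlap-model parameters as in [expected_count()].
#' @param variance `"hypergeometric"` or `"poisson"`.
#' @return Tibble: `expected`, `z`, `p_z`, `degenerate`.
#' @export
zscore <- function(O, n, K, N, variance = c("hypergeometric", "poisson")) {
  variance <- match.arg(variance)
  E <- expected_count(n, K, N)
  V <- overlap_variance(n, K, N, variance)
  z <- suppressWarnings((O - E) / sqrt(V))
  degenerate <- rep_len(V <= 0, length(z))
  z[degenerate] <- NA_real_
  tibble(
    expected = rep_len(E, length(z)), z = z,
    p_z = pnorm(z, lower.tail = FALSE),
    degenerate = degenerate
  )
}

#' Exact hypergeometric enrichment p-value
#'
#' Upper-tail probability `P[X >= O]` of seeing at least `O` category genes
#' among `n` draws from a universe of `N` genes containing `K` category
#' members, under the central hypergeometric distribution.
#'
#' @inheritParams zscore
#' @return Numeric p-value(s).
#' @export
hypergeom_p <- function(O, n, K, N) {
  phyper(O - 1, K, N - K, n, lower.tail = FALSE)
}

#' Category enrichment of a DE gene list
#'
#' Scores every category of a [category_db()] against a DE gene list with
#' the Z-score engine and its exact hypergeometric companion. DE genes
#' outside the database universe are dropped before computing `n`. A
#' category is significant when `Z >= z_min`, its p-value is at most
#' `alpha`, and the expected count exceeds `min_expected` — the three-part
#' criterion. For cis-element runs set `adjust = "BH"` and
#' `p_source = "hypergeometric"` so the criterion uses the BH-adjusted
#' exact p.
#'
#' @param de_genes Character vector of DE gene ids.
#' @param db A [category_db()].
#' @param variance Variance model for the Z-score.
#' @param z_min,alpha,min_expected The three-part significance criterion
#'   (defaults 2, 0.05, 1).
#' @param p_source Which p enters the criterion: the one-sided normal p of
#'   the Z-score (default) or the exact hypergeometric p.
#' @param adjust `"none"` (default) or `"BH"` applied to the chosen p
#'   across categories within the run.
#' @return Tibble: `category`, `n_category` (K), `observed` (O),
#'   `expected` (E), `z`, `p_z`, `p_hyper`, `p_used`, `p_adj`,
#'   `degenerate`, `significant`; metadata in attributes `n_de`,
#'   `n_universe`, `adjust_method`.
#' @export
enrich <- function(de_genes, db,
                   variance = c("hypergeometric", "poisson"),
                   z_min = 2, alpha = 0.05, min_expected = 1,
                   p_source = c("normal", "hypergeometric"),
                   adjust = c("none", "BH")) {
  variance <- match.arg(variance)
  p_source <- match.arg(p_source)
  adjust <- match.arg(adjust)
  if (!inherits(db, "category_db")) abort_config("db must be a category_db")
  if (length(db$universe) == 0L) abort_design("empty category universe")
  if (length(de_genes) == 0L) abort_design("empty DE gene list")
  de_in <- unique(intersect(de_genes, db$universe))
  n <- length(de_in)
  N <- length(db$universe)
  res <- db$pairs |>
    group_by(.data$category) |>
    summarise(
      n_category = n(),
      observed = sum(.data$gene_id %in% de_in),
      .groups = "drop"
    )
  zs <- zscore(res$observed, n, res$n_category, N, variance)
  res <- bind_cols(res, zs)
  res$p_hyper <- hypergeom_p(res$observed, n, res$n_category, N)
  res$p_used <- if (p_source == "normal") res$p_z else res$p_hyper
  res$p_adj <- if (adjust == "BH") bh_adjust(res$p_used) else res$p_used
  res$significant <- !res$degenerate &
    !is.na(res$z) & res$z >= z_min &
    res$p_adj <= alpha &
    res$expected > min_expected
  attr(res, "n_de") <- n
  attr(res, "n_universe") <- N
  attr(res, "adjust_method") <- adjust
  attr(res, "variance_model") <- variance
  res
}
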