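#' Clean gene-model ids for annotation joins
#'
#' Collapses gene-model suffixes (the number trailing the final `.`) and
#' optionally drops scaffold-pattern ids, the canonicalization applied to
#' gene-GO annotation pairs on load.
#'
#' @param ids Character vector of gene ids.
#' @param drop_scaffolds Remove scaffold-pattern ids (default TRUE).
#' @param scaffold_pattern Scaffold id regex.
#' @return Character vector (with `NA` for dropped scaffold ids removed by
#'   the callers that use this on tables).
#' @export
clean_gene_ids <- function(ids, drop_scaffolds = TRUE,
                           scaffold_pattern = SCAFFOLD_PATTERN) {
  out <- sub("\\.[0-9]+$", "", ids)
  if (drop_scaffolds) out[is_scaffold_id(out, scaffold_pattern)] <- NA_character_
  out
}

#' Load gene-GO annotation pairs
#'
#' Canonicalizes gene ids (suffix collapse, scaffold removal) and retains
#' only unique gene-GO pairs, so each unique gene contributes at most once
#' to each category.
#'
#' @param pairs Tibble with columns `gene_id` and `term`.
#' @return A [category_db()] of kind `"go"`.
#' @export
load_go_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  assert_cols(pairs, c("gene_id", "term"), "GO pairs")
  pairs |>
    mutate(gene_id = clean_gene_ids(.data$gene_id)) |>
    filter(!is.na(.data$gene_id)) |>
    rename(category = "term") |>
    distinct(.data$gene_id, .data$category) |>
    category_db(kind = "go", scaffold_pattern = NULL)
}

#' Fit the probability weighting function of gene length
#'
#' Estimates how the probability of being called DE depends on gene length:
#' genes are split into equal-occupancy length bins, the DE proportion is
#' computed per bin, and a monotone (isotonic, non-decreasing) fit smooths
#' the bin proportions. The fitted function is evaluated at arbitrary
#' lengths by interpolation between bin centers and clamped away from 0
#' and 1.
#'
#' @param lengths Numeric gene lengths.
#' @param de Logical DE indicator, same length.
#' @param n_bins Number of equal-occupancy bins (default 20).
#' @param eps Clamp margin (default 1e-6).
#' @return Object of class `pwf`: list with `fun` (vectorized length ->
#'   probability), `bins` (tibble: center, prop, fitted, n) and `overall`
#'   (overall DE fraction).
#' @export
fit_pwf <- function(lengths, de, n_bins = 20, eps = 1e-6) {
  if (length(lengths) != length(de)) abort_format("lengths and de must align")
  if (length(lengths) < 2L) abort_format("need >= 2 genes to fit a PWF")
  de <- as.logical(de)
  overall <- mean(de)
  if (all(de) || !any(de) || length(unique(lengths)) < 2L) {
    if (length(unique(lengths)) < 2L) {
      warn("degenerate lengths (all equal); PWF is constant")
    } else {
      warn("degenerate DE status (all or none DE); PWF is constant")
    }
    const <- min(max(overall, eps), 1 - eps)
    return(structure(
      list(fun = function(l) rep(const, length(l)),
           bins = tibble(center = mean(lengths), prop = overall,
                         fitted = const, n = length(lengths)),
           overall = overall),
      class = "pwf"
    ))
  }
  n_bins <- max(1L, min(n_bins, length(unique(lengths))))
  brks <- unique(quantile(lengths, probs = seq(0, 1, length.out = n_bins + 1)))
  grp <- cut(lengths, breaks = brks, include.lowest = TRUE)
  bins <- tibble(length = lengths, de = de, bin = grp) |>
    group_by(.data$bin) |>
    summarise(center = mean(.data$length), prop = mean(.data$de), n = n(),
              .groups = "drop") |>
    arrange(.data$center)
  fitted <- if (nrow(bins) > 1L) isoreg(bins$center, bins$prop)$yf else bins$prop
  bins$fitted <- pmin(pmax(fitted, eps), 1 - eps)
  fun <- function(l) {
    if (nrow(bins) == 1L) return(rep(bins$fitted, length(l)))
    approx(bins$center, bins$fitted, xout = l, rule = 2)$y
  }
  structure(list(fun = fun, bins = bins, overall = overall), class = "pwf")
}

#' @export
print.pwf <- function(x, ...) {
  cat(sprintf("<pwf> %d bins, overall DE fraction %.4f, range [%.4f, %.4f]\n",
              nrow(x$bins), x$overall, min(x$bins$fitted), max(x$bins$fitted)))
  invisible(x)
}

#' Wallenius noncentral hypergeometric pmf
#'
#' Probability of drawing `k` category genes in `n` biased draws without
#' replacement from a universe of `N` genes containing `K` category
#' members, where category genes are drawn with odds `omega` relative to
#' the rest. Evaluated by adaptive numerical integration of the Wallenius
#' integral representation; `omega = 1` reduces to the central
#' hypergeometric distribution.
#'
#' @param k Integer count(s), `0 <= k <= min(K, n)`.
#' @param N,K,n Population size, category size, number of draws.
#' @param omega Odds ratio, `> 0`.
#' @return Probability (vectorized over `k`).
#' @export
wallenius_pmf <- function(k, N, K, n, omega) {
  if (omega <= 0) abort_config("omega must be > 0")
  if (n > N || K > N || n < 0 || K < 0) abort_config("invalid Wallenius parameters")
  vapply(k, function(kk) {
    if (kk < max(0, n - (N - K)) || kk > min(K, n)) return(0)
    if (n == N) return(as.numeric(kk == K))
    if (abs(omega - 1) < 1e-9) return(dhyper(kk, K, N - K, n))
    d <- omega * (K - kk) + (N - K) - (n - kk)
    if (d <= 0) return(as.numeric(kk == min(K, n)))
    lc <- lchoose(K, kk) + lchoose(N - K, n - kk)
    # substitute u = t^(1/d): I = d * int_0^1 (1-u^w)^k (1-u)^(n-k) u^(d-1) du,
    # a beta-like kernel evaluated in log space so large draws do not
    # underflow the integrand
    lf <- function(u) {
      kk * log1p(-u^omega) + (n - kk) * log1p(-u) + (d - 1) * log(u)
    }
    grid <- seq(1e-9, 1 - 1e-9, length.out = 2001L)
    M <- max(lf(grid))
    f <- function(u) exp(lf(u) - M)
    val <- tryCatch(
      integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0, subdivisions = 1000L)$value,
      error = function(e) NA_real_
    )
    if (is.na(val)) {
      # fallback: Simpson on a fine mesh
      w <- rep(c(4, 2), length.out = length(grid) - 2L)
      val <- sum(c(1, w, 1) * f(grid)) * (grid[2] - grid[1]) / 3
    }
    exp(lc + log(d) + M + log(val))
  }, numeric(1))
}

#' Wallenius upper-tail p-value
#'
#' `P[X >= O]` under the Wallenius noncentral hypergeometric distribution.
#'
#' @param O Observed overlap.
#' @inheritParams wallenius_pmf
#' @return Numeric p-value.
#' @export
wallenius_p <- function(O, N, K, n, omega) {
  kmax <- min(K, n)
  if (O <= max(0, n - (N - K))) return(1)
  if (O > kmax) return(0)
  min(1, sum(wallenius_pmf(O:kmax, N, K, n, omega)))
}

#' Length-bias-corrected GO enrichment
#'
#' Scores GO categories against a DE gene list with the Wallenius
#' noncentral hypergeometric distribution, using a fitted probability
#' weighting function (PWF) of gene length to set each category's odds
#' ratio: `omega = mean PWF over member genes / mean PWF over non-members`.
#' This corrects the selection bias whereby longer genes are more likely to
#' be called DE. Significance is flagged on the raw p-value at `alpha`
#' (matching the convention of flat-annotation GO runs); BH-adjusted
#' p-values are reported alongside.
#'
#' @param de_genes Character vector of DE gene ids.
#' @param go_db A [category_db()] (e.g. from [load_go_pairs()]).
#' @param gene_lengths Tibble with `gene_id` and `length` columns covering
#'   the universe.
#' @param n_bins Bins for the PWF fit (default 20).
#' @param alpha Significance level on the raw Wallenius p (default 0.05).
#' @return Tibble: `category`, `n_category`, `observed`, `expected_central`,
#'   `omega`, `p_wallenius`, `p_adj`, `significant`; the fitted `pwf` and
#'   universe metadata in attributes.
#' @export
go_enrich <- function(de_genes, go_db, gene_lengths, n_bins = 20, alpha = 0.05) {
  if (!inherits(go_db, "category_db")) abort_config("go_db must be a category_db")
  gene_lengths <- as_tibble(gene_lengths)
  assert_cols(gene_lengths, c("gene_id", "length"), "gene lengths")
  universe <- intersect(go_db$universe, gene_lengths$gene_id)
  dropped <- go_db$pairs |>
    group_by(.data$category) |>
    summarise(outside = all(!.data$gene_id %in% universe), .groups = "drop")
  if (any(dropped$outside)) {
    warn(sprintf("%d categories lie entirely outside the length-annotated universe; skipped",
                 sum(dropped$outside)))
  }
  pairs <- filter(go_db$pairs, .data$gene_id %in% universe)
  N <- length(universe)
  de_in <- unique(intersect(de_genes, universe))
  n <- length(de_in)
  len <- gene_lengths$length[match(universe, gene_lengths$gene_id)]
  is_de <- universe %in% de_in
  pwf <- fit_pwf(len, is_de, n_bins = n_bins)
  w <- pwf$fun(len)
  names(w) <- universe
  res <- pairs |>
    group_by(.data$category) |>
    summarise(
      n_category = n(),
      observed = sum(.data$gene_id %in% de_in),
      mean_w_in = mean(w[.data$gene_id]),
      .groups = "drop"
    ) |>
    mutate(
      sum_w_in = .data$mean_w_in * .data$n_category,
      mean_w_out = (sum(w) - .data$sum_w_in) / (N - .data$n_category),
      omega = .data$mean_w_in / .data$mean_w_out,
      expected_central = expected_count(n, .data$n_category, N)
    )
  res$p_wallenius <- purrr::pmap_dbl(
    list(res$observed, res$n_category, res$omega),
    function(O, K, om) wallenius_p(O, N, K, n, om)
  )
  res$p_adj <- bh_adjust(res$p_wallenius)
  res$significant <- res$p_wallenius <= alpha
  res <- select(res, -"mean_w_in", -"mean_w_out", -"sum_w_in")
  attr(res, "pwf") <- pwf
  attr(res, "n_de") <- n
  attr(res, "n_universe") <- N
  res
}
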