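#' Define a two-group contrast
#'
#' Selects the treatment and control lanes of one tissue for an exact-test
#' comparison (e.g. ABA-treated vs NaOH control in shoots).
#'
#' @param cm A [count_matrix()].
#' @param tissue Tissue to compare within.
#' @param treatment,control Condition labels of the two groups.
#' @return List of class `de_contrast` with the lane ids of each group.
#' @export
define_contrast <- function(cm, tissue, treatment, control) {
  s <- cm$samples
  t_lanes <- s$lane[s$tissue == tissue & s$condition == treatment]
  c_lanes <- s$lane[s$tissue == tissue & s$condition == control]
  if (length(t_lanes) < 2L || length(c_lanes) < 2L) {
    abort_design(sprintf(
      "contrast %s: %s/%s needs >= 2 replicates per group (found %d and %d)",
      tissue, treatment, control, length(t_lanes), length(c_lanes)
    ))
  }
  if (length(intersect(t_lanes, c_lanes)) > 0L) {
    abort_design("treatment and control groups overlap")
  }
  structure(
    list(
      name = paste(tissue, treatment, "vs", control, sep = "."),
      tissue = tissue, treatment = treatment, control = control,
      treat_lanes = t_lanes, control_lanes = c_lanes
    ),
    class = "de_contrast"
  )
}

# Summed conditional NB log-likelihood of one group of lanes given the group
# total, as a function of the dispersion. For iid NB(size r, same mean) the
# counts given their sum follow a Dirichlet-multinomial whose likelihood is
# free of the mean, which is what makes the 1-D profile over the dispersion
# well posed.
cond_loglik_group <- function(y, r) {
  # y: genes x lanes matrix; r: NB size (1/phi) per lane
  nlane <- ncol(y)
  z <- rowSums(y)
  keep <- z > 0
  if (!any(keep)) return(0)
  y <- y[keep, , drop = FALSE]
  z <- z[keep]
  sum(lgamma(y + r)) - nrow(y) * nlane * lgamma(r) -
    sum(lgamma(z + nlane * r)) + length(z) * lgamma(nlane * r)
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood, summed over genes and over the
#' two groups of the contrast, over a single dispersion shared by all genes.
#' The search is a 1-D bounded optimization on the shrunken scale
#' `delta = phi / (1 + phi)` in `[0, 1)`. Counts must already be on
#' equalized library sizes (use [quantile_normalize()] first); normalized
#' values are rounded to integers for the conditional likelihood.
#'
#' @param cm A [count_matrix()], normalized.
#' @param contrast A [define_contrast()] object.
#' @return List of class `dispersion_fit`: `phi`, `delta`, `loglik`,
#'   `n_genes` (genes with a positive total in at least one group).
#' @export
estimate_common_dispersion <- function(cm, contrast) {
  vals <- round(count_values(cm, normalized = !is.null(cm$normalized)))
  y1 <- vals[, contrast$treat_lanes, drop = FALSE]
  y2 <- vals[, contrast$control_lanes, drop = FALSE]
  if (all(y1 == 0) && all(y2 == 0)) {
    abort_design("all counts are zero; cannot estimate dispersion")
  }
  nll <- function(delta) {
    r <- (1 - delta) / delta # 1/phi
    -(cond_loglik_group(y1, r) + cond_loglik_group(y2, r))
  }
  opt <- optimize(nll, interval = c(1e-6, 1 - 1e-6), tol = 1e-8)
  delta <- opt$minimum
  phi <- delta / (1 - delta)
  # Flat-likelihood guard: if the boundary value is as good, report ~Poisson.
  if (nll(1e-6) <= opt$objective + 1e-8) {
    delta <- 1e-6
    phi <- delta / (1 - delta)
  }
  structure(
    list(phi = phi, delta = delta, loglik = -nll(delta),
         n_genes = sum(rowSums(vals) > 0)),
    class = "dispersion_fit"
  )
}

# Exact two-sided NB test p-value for one gene, conditional on the total.
# Group sums of n iid NB(mu, phi) lanes are NB(size n/phi, mean n*mu); under
# the null of a common mean and equal library sizes, the conditional
# distribution of the group-1 sum given the grand total does not depend on
# the mean. Two-sided p sums the probabilities of all partitions of the
# total at most as probable as the observed one. phi = 0 degenerates to the
# conditional binomial (Poisson limit).
nb_exact_pval <- function(y1, total, n1, n2, phi) {
  if (total == 0) return(1)
  y <- 0:total
  if (phi <= 0) {
    probs <- dbinom(y, total, n1 / (n1 + n2))
  } else {
    mu <- total / (n1 + n2) # per-lane mean under the null; cancels on normalizing
    lp <- dnbinom(y, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(total - y, size = n2 / phi, mu = n2 * mu, log = TRUE)
    lp <- lp - max(lp)
    probs <- exp(lp)
    probs <- probs / sum(probs)
  }
  p_obs <- probs[y1 + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Negative-binomial exact test
#'
#' Per-gene two-group exact test at a common dispersion, conditioning on
#' each gene's total count across both groups (valid because quantile
#' normalization equalizes library sizes). The two-sided p-value sums the
#' probabilities of all partitions of the total at most as probable as the
#' observed partition. The log2 fold change is computed from per-lane group
#' means of the normalized counts with a pseudo-count of 0.5 per group
#' mean. Genes with zero total get p = 1 and log2FC = 0 by convention.
#'
#' @param cm A [count_matrix()], normalized.
#' @param contrast A [define_contrast()] object.
#' @param dispersion A `dispersion_fit` or a bare numeric dispersion phi.
#' @param pseudo Pseudo-count added to each group mean for the fold change
#'   (default 0.5).
#' @return Object of class `de_fit`: list with `table` (tibble `gene_id`,
#'   `mean_treat`, `mean_control`, `logFC`, `pvalue`, `padj`), `phi`,
#'   `contrast`.
#' @export
exact_test <- function(cm, contrast, dispersion, pseudo = 0.5) {
  phi <- if (inherits(dispersion, "dispersion_fit")) dispersion$phi else dispersion
  if (!is.numeric(phi) || phi < 0) abort_config("dispersion must be >= 0")
  vals <- count_values(cm, normalized = !is.null(cm$normalized))
  y1m <- vals[, contrast$treat_lanes, drop = FALSE]
  y2m <- vals[, contrast$control_lanes, drop = FALSE]
  n1 <- ncol(y1m); n2 <- ncol(y2m)
  s1 <- round(rowSums(y1m)); s2 <- round(rowSums(y2m))
  tot <- s1 + s2
  # p depends only on (y1, total): dedupe to avoid recomputing shared cases
  key <- paste(s1, tot)
  ukey <- !duplicated(key)
  up <- vapply(which(ukey), function(i) nb_exact_pval(s1[i], tot[i], n1, n2, phi),
               numeric(1))
  pvals <- up[match(key, key[ukey])]
  m1 <- unname(rowMeans(y1m)); m2 <- unname(rowMeans(y2m))
  lfc <- ifelse(tot == 0, 0, log2((m1 + pseudo) / (m2 + pseudo)))
  tbl <- tibble(
    gene_id = rownames(vals),
    mean_treat = m1, mean_control = m2,
    logFC = unname(lfc), pvalue = unname(pvals),
    padj = bh_adjust(pvals)
  )
  structure(
    list(table = tbl, phi = phi, contrast = contrast),
    class = "de_fit"
  )
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("<de_fit> %s: %d genes, common dispersion %.4g\n",
              x$contrast$name, nrow(x$table), x$phi))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (thin wrapper over
#' `p.adjust(..., method = "BH")`, kept as a named surface so the
#' adjustment used by the pipeline is explicit and swappable).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_format("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Apply the three-part differential-expression filter
#'
#' A gene is called differentially expressed when (1) its median sequencing
#' depth reaches `min_median_depth` (2X) in at least one of the two compared
#' groups, (2) |log2 fold change| >= `min_abs_lfc` (1.0), and (3) the
#' BH-adjusted p-value is below `alpha` (0.05).
#'
#' @param fit A `de_fit` from [exact_test()].
#' @param profile Depth profile from [depth_profile()] covering the two
#'   groups of the contrast.
#' @param min_median_depth Depth gate in X units (default 2).
#' @param min_abs_lfc Fold-change gate on the log2 scale (default 1).
#' @param alpha Adjusted-p gate (default 0.05).
#' @param p_prefilter Optional raw-p pre-filter applied before the adjusted
#'   threshold (default `NULL`, i.e. none); retained as an optional knob
#'   because some published workflows shortlist at raw p < 0.01 first.
#' @return Tibble: the `de_fit` table plus `depth_treat`, `depth_control`,
#'   `depth_pass`, `lfc_pass`, `p_pass`, `is_de`, `direction`.
#' @export
apply_de_filters <- function(fit, profile, min_median_depth = 2,
                             min_abs_lfc = 1, alpha = 0.05,
                             p_prefilter = NULL) {
  ctr <- fit$contrast
  g_t <- paste(ctr$tissue, ctr$treatment, sep = ".")
  g_c <- paste(ctr$tissue, ctr$control, sep = ".")
  prof <- profile |>
    filter(.data$group %in% c(g_t, g_c)) |>
    select("gene_id", "group", "median_depth") |>
    tidyr::pivot_wider(names_from = "group", values_from = "median_depth")
  if (!all(c(g_t, g_c) %in% names(prof))) {
    abort_design("depth profile does not cover both groups of the contrast")
  }
  out <- fit$table |>
    left_join(prof, by = "gene_id") |>
    rename(depth_treat = all_of(g_t), depth_control = all_of(g_c)) |>
    mutate(
      depth_pass = .data$depth_treat >= min_median_depth |
        .data$depth_control >= min_median_depth,
      lfc_pass = abs(.data$logFC) >= min_abs_lfc,
      p_pass = .data$padj < alpha &
        (if (is.null(p_prefilter)) TRUE else .data$pvalue < p_prefilter),
      is_de = .data$depth_pass & .data$lfc_pass & .data$p_pass,
      direction = dplyr::case_when(
        .data$is_de & .data$logFC >= min_abs_lfc ~ "up",
        .data$is_de & .data$logFC <= -min_abs_lfc ~ "down",
        TRUE ~ "ns"
      )
    )
  out
}

#' Overlaps between differential-expression gene lists
#'
#' Region counts (exclusive and shared, per direction when available) and
#' pairwise overlap percentages between DE lists from different contrasts,
#' with both denominator conventions reported: the union of the two lists
#' and each list separately.
#'
#' @param de_lists Named list of character vectors (or of tibbles carrying
#'   `gene_id` and optionally `direction`).
#' @param top_k Number of top genes (by |log2FC|) reported per exclusive or
#'   shared region when tibbles with `logFC` are supplied (default 5).
#' @return List with `regions` (tibble: region, n, genes), `pairwise`
#'   (tibble: list_a, list_b, n_shared, pct_of_union, pct_of_a, pct_of_b),
#'   and `top` (tibble of top-|logFC| genes per region, when available).
#' @export
overlap_sets <- function(de_lists, top_k = 5) {
  if (length(de_lists) < 2L) abort_design("need at least two DE lists")
  if (is.null(names(de_lists)) || any(names(de_lists) == "")) {
    abort_design("DE lists must be named")
  }
  tables <- purrr::map(de_lists, function(x) {
    if (is.data.frame(x)) as_tibble(x) else tibble(gene_id = x)
  })
  sets <- purrr::map(tables, ~ unique(.x$gene_id))
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, names(sets)))
  region_of <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- tibble(gene_id = all_genes, region = region_of) |>
    group_by(.data$region) |>
    summarise(n = n(), genes = list(.data$gene_id), .groups = "drop")
  prs <- utils::combn(names(sets), 2L)
  pairwise <- purrr::map_dfr(seq_len(ncol(prs)), function(j) {
    a <- prs[1L, j]; b <- prs[2L, j]
    sh <- length(intersect(sets[[a]], sets[[b]]))
    un <- length(union(sets[[a]], sets[[b]]))
    tibble(
      list_a = a, list_b = b, n_shared = sh,
      pct_of_union = if (un > 0) round1(100 * sh / un) else NA_real_,
      pct_of_a = if (length(sets[[a]]) > 0) round1(100 * sh / length(sets[[a]])) else NA_real_,
      pct_of_b = if (length(sets[[b]]) > 0) round1(100 * sh / length(sets[[b]])) else NA_real_
    )
  })
  top <- NULL
  if (all(vapply(tables, function(x) "logFC" %in% names(x), logical(1)))) {
    lfc <- bind_rows(tables, .id = "list") |>
      group_by(.data$gene_id) |>
      summarise(logFC = .data$logFC[which.max(abs(.data$logFC))], .groups = "drop")
    top <- tibble(gene_id = all_genes, region = region_of) |>
      left_join(lfc, by = "gene_id") |>
      group_by(.data$region) |>
      arrange(desc(abs(.data$logFC)), .by_group = TRUE) |>
      dplyr::slice_head(n = top_k) |>
      ungroup()
  }
  list(regions = regions, pairwise = pairwise, top = top)
}
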