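#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression fit
#'
#' One row per gene: means, log2 fold change, raw and BH-adjusted exact-test
#' p-values.
#'
#' @param x A `de_fit` from [exact_test()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy de_fit
#' @export
tidy.de_fit <- function(x, ...) {
  x$table
}

#' One-row summary of a differential-expression fit
#'
#' @param x A `de_fit`.
#' @param alpha Adjusted-p threshold used for the `n_signif` column
#'   (default 0.05).
#' @param ... Unused.
#' @return Tibble: `contrast`, `n_genes`, `dispersion`, `n_signif`.
#' @method glance de_fit
#' @export
glance.de_fit <- function(x, alpha = 0.05, ...) {
  tibble(
    contrast = x$contrast$name,
    n_genes = nrow(x$table),
    dispersion = x$phi,
    n_signif = sum(x$table$padj < alpha, na.rm = TRUE)
  )
}

#' Tidy a fitted probability weighting function
#'
#' @param x A `pwf` from [fit_pwf()].
#' @param ... Unused.
#' @return Tibble of bins: `center`, `prop`, `fitted`, `n`.
#' @method tidy pwf
#' @export
tidy.pwf <- function(x, ...) {
  select(x$bins, "center", "prop", "fitted", "n")
}

#' One-row summary of a probability weighting function
#'
#' @param x A `pwf`.
#' @param ... Unused.
#' @return Tibble: `n_bins`, `overall_de_fraction`, `min_fitted`,
#'   `max_fitted`.
#' @method glance pwf
#' @export
glance.pwf <- function(x, ...) {
  tibble(
    n_bins = nrow(x$bins),
    overall_de_fraction = x$overall,
    min_fitted = min(x$bins$fitted),
    max_fitted = max(x$bins$fitted)
  )
}

#' Tidy a pathway cross-talk graph
#'
#' @param x A `pathway_graph`.
#' @param what `"nodes"` (default) or `"edges"`.
#' @param ... Unused.
#' @return A tibble of nodes or edges.
#' @method tidy pathway_graph
#' @export
tidy.pathway_graph <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of a pathway cross-talk graph
#'
#' @param x A `pathway_graph`.
#' @param ... Unused.
#' @return Tibble: `n_pathways`, `n_edges`, `n_hormone`,
#'   `max_shared_de_genes`.
#' @method glance pathway_graph
#' @export
glance.pathway_graph <- function(x, ...) {
  tibble(
    n_pathways = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_hormone = sum(x$nodes$is_hormone),
    max_shared_de_genes = if (nrow(x$edges) > 0) max(x$edges$weight) else 0L
  )
}
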