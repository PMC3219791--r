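#' MA plot of a differential-expression result
#'
#' Mean normalized expression against log2 fold change, with the DE calls
#' highlighted when the filtered table from [apply_de_filters()] is given.
#'
#' @param de A `de_fit` or a filtered DE tibble.
#' @param alpha Used only when `de` is an unfiltered fit, to color by
#'   adjusted p (default 0.05).
#' @return A ggplot object.
#' @export
plot_ma <- function(de, alpha = 0.05) {
  tbl <- if (inherits(de, "de_fit")) tidy(de) else as_tibble(de)
  tbl <- mutate(tbl, mean_expr = (.data$mean_treat + .data$mean_control) / 2)
  col <- if ("is_de" %in% names(tbl)) {
    dplyr::if_else(tbl$is_de, "DE", "not DE")
  } else {
    dplyr::if_else(tbl$padj < alpha, "padj < alpha", "ns")
  }
  ggplot2::ggplot(tbl, ggplot2::aes(x = log2(.data$mean_expr + 0.5),
                                    y = .data$logFC, colour = col)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-1, 0, 1), linetype = c(2, 1, 2),
                        linewidth = 0.3) +
    ggplot2::labs(x = "log2 mean normalized count", y = "log2 fold change",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of enrichment results
#'
#' Z-scores (or -log10 Wallenius p for GO results) per category, colored by
#' significance.
#'
#' @param res An [enrich()] or [go_enrich()] result tibble.
#' @param top Show at most this many categories, best first (default 20).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(res, top = 20) {
  res <- as_tibble(res)
  if ("z" %in% names(res)) {
    res <- res |> arrange(desc(.data$z)) |> head(top)
    ggplot2::ggplot(res, ggplot2::aes(
      x = stats::reorder(.data$category, .data$z), y = .data$z,
      fill = .data$significant
    )) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = 2, linetype = 2, linewidth = 0.3) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "enrichment Z-score", fill = "significant") +
      ggplot2::theme_minimal()
  } else {
    res <- res |> arrange(.data$p_wallenius) |> head(top)
    ggplot2::ggplot(res, ggplot2::aes(
      x = stats::reorder(.data$category, -.data$p_wallenius),
      y = -log10(.data$p_wallenius), fill = .data$significant
    )) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "-log10 Wallenius p", fill = "significant") +
      ggplot2::theme_minimal()
  }
}

#' Depth-bin summary plot
#'
#' Number of gene models per median-sequencing-depth bin, by sample group.
#'
#' @param bins Output of [depth_bins()].
#' @return A ggplot object.
#' @export
plot_depth_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$n,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "median sequencing depth", y = "gene models",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Probability weighting function plot
#'
#' Binned DE proportions and the monotone fit against gene length.
#'
#' @param x A `pwf` from [fit_pwf()].
#' @param object,... For the `autoplot` method.
#' @return A ggplot object.
#' @export
plot_pwf <- function(x) {
  ggplot2::ggplot(x$bins, ggplot2::aes(x = .data$center)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "gene length (bp)", y = "P(DE)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pwf
#' @importFrom ggplot2 autoplot
#' @method autoplot pwf
#' @export
autoplot.pwf <- function(object, ...) plot_pwf(object)
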