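#' Build a pathway database
#'
#' Holds the pathway -> reaction -> gene mapping together with per-pathway
#' metadata (hormone flag) and an optional collapse map merging closely
#' related pathway variants. Scaffold-pattern genes are removed on load.
#'
#' @param pathway_table Tibble with columns `pathway_id`, `reaction_id`,
#'   `gene_id` and optionally `is_hormone` (logical).
#' @param collapse_map Optional tibble with columns `pathway_id`,
#'   `collapsed_id`.
#' @param scaffold_pattern Scaffold gene-id regex; `NULL` disables removal.
#' @return List of class `pathway_db`: `table`, `collapse_map`.
#' @export
pathway_db <- function(pathway_table, collapse_map = NULL,
                       scaffold_pattern = SCAFFOLD_PATTERN) {
  tbl <- as_tibble(pathway_table)
  assert_cols(tbl, c("pathway_id", "reaction_id", "gene_id"), "pathway table")
  if (!"is_hormone" %in% names(tbl)) tbl$is_hormone <- FALSE
  if (!is.null(scaffold_pattern)) {
    tbl <- filter(tbl, !is_scaffold_id(.data$gene_id, scaffold_pattern))
  }
  tbl <- distinct(tbl, .data$pathway_id, .data$reaction_id, .data$gene_id,
                  .data$is_hormone)
  if (!is.null(collapse_map)) {
    collapse_map <- as_tibble(collapse_map)
    assert_cols(collapse_map, c("pathway_id", "collapsed_id"), "collapse map")
  }
  structure(list(table = tbl, collapse_map = collapse_map), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways, %d reactions, %d genes\n",
              dplyr::n_distinct(x$table$pathway_id),
              dplyr::n_distinct(x$table$reaction_id),
              dplyr::n_distinct(x$table$gene_id)))
  invisible(x)
}

#' Gene-category pairs of a pathway database
#'
#' Flattens a [pathway_db()] into the two-column form consumed by the
#' enrichment engine (one row per unique gene-pathway pair).
#'
#' @param db A [pathway_db()].
#' @return A [category_db()] of kind `"pathway"`.
#' @export
pathway_categories <- function(db) {
  db$table |>
    select(gene_id = "gene_id", category = "pathway_id") |>
    distinct() |>
    category_db(kind = "pathway", scaffold_pattern = NULL)
}

#' Collapse related pathway variants
#'
#' Applies the collapse map: mapped pathways are merged under their
#' collapsed id with unions of reactions and genes; unmapped pathways pass
#' through unchanged. A map whose targets are themselves mapped (a chain or
#' cycle) is rejected.
#'
#' @param db A [pathway_db()].
#' @param map Collapse map tibble (`pathway_id`, `collapsed_id`); defaults
#'   to the one stored in the database.
#' @return A collapsed [pathway_db()].
#' @export
collapse_pathways <- function(db, map = NULL) {
  map <- map %||% db$collapse_map
  if (is.null(map)) return(db)
  map <- as_tibble(map)
  assert_cols(map, c("pathway_id", "collapsed_id"), "collapse map")
  chained <- intersect(map$collapsed_id, map$pathway_id[map$pathway_id != map$collapsed_id])
  if (length(chained) > 0L) {
    abort_config(sprintf("collapse map targets are themselves remapped: %s",
                         paste(head(chained, 3), collapse = ", ")))
  }
  tbl <- db$table |>
    left_join(map, by = "pathway_id") |>
    mutate(pathway_id = dplyr::coalesce(.data$collapsed_id, .data$pathway_id)) |>
    select(-"collapsed_id") |>
    group_by(.data$pathway_id) |>
    mutate(is_hormone = any(.data$is_hormone)) |>
    ungroup() |>
    distinct(.data$pathway_id, .data$reaction_id, .data$gene_id, .data$is_hormone)
  pathway_db(tbl, collapse_map = NULL, scaffold_pattern = NULL)
}

#' Reaction coverage of DE genes per pathway
#'
#' The fraction of a pathway's reactions that contain at least one DE gene.
#' Pathways with fewer than `min_reactions` reactions are excluded from the
#' report (small pathways make the ratio uninformative); pathways with zero
#' reactions are dropped with a warning.
#'
#' @param db A [pathway_db()].
#' @param de_genes Character vector of DE gene ids.
#' @param min_reactions Minimum reaction count to report (default 3).
#' @return Tibble: `pathway_id`, `n_reactions`, `n_reactions_de`, `ratio`.
#' @export
reaction_coverage <- function(db, de_genes, min_reactions = 3) {
  per_rxn <- db$table |>
    group_by(.data$pathway_id, .data$reaction_id) |>
    summarise(has_de = any(.data$gene_id %in% de_genes), .groups = "drop")
  out <- per_rxn |>
    group_by(.data$pathway_id) |>
    summarise(
      n_reactions = n(),
      n_reactions_de = sum(.data$has_de),
      ratio = sum(.data$has_de) / n(),
      .groups = "drop"
    )
  filter(out, .data$n_reactions >= min_reactions)
}

# Weight class thresholds follow the published cross-talk network
# convention: <=5, 6-9, >=10 shared DE genes.
edge_weight_class <- function(w) {
  dplyr::case_when(w >= 10 ~ ">=10", w >= 6 ~ "6-9", w >= 1 ~ "<=5",
                   TRUE ~ NA_character_)
}

#' Build the pathway cross-talk network
#'
#' Nodes are (collapsed) pathways scored by the number of up-regulated
#' minus down-regulated DE genes they contain; an edge joins two pathways
#' exactly when they share at least one DE gene, weighted by the number of
#' shared DE genes and classed at the <=5 / 6-9 / >=10 thresholds. A
#' shared DE gene counts once per pathway pair regardless of how many
#' reactions carry it.
#'
#' @param db A (collapsed) [pathway_db()].
#' @param de_table Tibble with `gene_id` and `direction` (`"up"`/`"down"`)
#'   for DE genes of the contrast under analysis.
#' @return Object of class `pathway_graph`: list with `nodes` (tibble:
#'   `pathway_id`, `n_up`, `n_down`, `score`, `score_class`, `is_hormone`),
#'   `edges` (tibble: `from`, `to`, `weight`, `class`) and `graph`
#'   (igraph).
#' @export
build_network <- function(db, de_table) {
  de_table <- as_tibble(de_table)
  assert_cols(de_table, c("gene_id", "direction"), "DE table")
  de_table <- filter(de_table, .data$direction %in% c("up", "down"))
  membership <- db$table |>
    distinct(.data$pathway_id, .data$gene_id, .data$is_hormone) |>
    group_by(.data$pathway_id) |>
    mutate(is_hormone = any(.data$is_hormone)) |>
    ungroup()
  nodes <- membership |>
    left_join(select(de_table, "gene_id", "direction"), by = "gene_id") |>
    group_by(.data$pathway_id) |>
    summarise(
      n_up = sum(.data$direction == "up", na.rm = TRUE),
      n_down = sum(.data$direction == "down", na.rm = TRUE),
      is_hormone = any(.data$is_hormone),
      .groups = "drop"
    ) |>
    mutate(
      score = .data$n_up - .data$n_down,
      score_class = dplyr::case_when(
        .data$score > 0 ~ "up", .data$score < 0 ~ "down", TRUE ~ "neutral"
      )
    )
  de_member <- membership |>
    semi_join(de_table, by = "gene_id") |>
    select("pathway_id", "gene_id")
  edges <- de_member |>
    inner_join(de_member, by = "gene_id", relationship = "many-to-many") |>
    filter(.data$pathway_id.x < .data$pathway_id.y) |>
    count(from = .data$pathway_id.x, to = .data$pathway_id.y, name = "weight") |>
    mutate(class = edge_weight_class(.data$weight))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = as.data.frame(select(nodes, "pathway_id", "score", "is_hormone"))
  )
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d pathways, %d edges (%d hormone pathways)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$is_hormone)))
  invisible(x)
}

#' Hormone cross-talk subnetwork
#'
#' Restricts the network to the hormone-related pathways and the nodes
#' connecting them: in `"shortest_path"` mode (default) the subgraph is
#' induced by the union, over all hormone-pathway pairs, of every node on
#' at least one unweighted shortest path between the pair (all ties
#' included); in `"neighborhood"` mode it is the hormone pathways plus
#' their direct neighbors. Hormone pathways are always retained, even when
#' isolated.
#'
#' @param pg A [build_network()] result.
#' @param hormones Character vector of hormone pathway ids; defaults to the
#'   nodes flagged `is_hormone`.
#' @param mode `"shortest_path"` or `"neighborhood"`.
#' @return A `pathway_graph` restricted to the selected nodes.
#' @export
hormone_subnetwork <- function(pg, hormones = NULL,
                               mode = c("shortest_path", "neighborhood")) {
  mode <- match.arg(mode)
  hormones <- hormones %||% pg$nodes$pathway_id[pg$nodes$is_hormone]
  if (length(hormones) < 2L) abort_design("need >= 2 hormone pathways")
  g <- pg$graph
  keep <- hormones
  if (mode == "shortest_path") {
    prs <- utils::combn(hormones, 2L)
    for (j in seq_len(ncol(prs))) {
      sp <- suppressWarnings(igraph::all_shortest_paths(
        g, from = prs[1L, j], to = prs[2L, j], weights = NA
      ))
      keep <- union(keep, unique(unlist(lapply(sp$vpaths, function(p) names(p)))))
    }
  } else {
    nb <- igraph::adjacent_vertices(g, hormones)
    keep <- union(keep, unique(unlist(lapply(nb, names))))
  }
  sub <- igraph::induced_subgraph(g, keep)
  nodes <- filter(pg$nodes, .data$pathway_id %in% keep)
  edges <- filter(pg$edges, .data$from %in% keep & .data$to %in% keep)
  structure(list(nodes = nodes, edges = edges, graph = sub),
            class = "pathway_graph")
}

#' Export a pathway network for Cytoscape
#'
#' Writes the network as GraphML, as SIF, and as node/edge attribute TSVs.
#'
#' @param pg A `pathway_graph`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files (default `"network"`).
#' @return Invisibly, the written file paths.
#' @export
export_network <- function(pg, dir, name = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    graphml = file.path(dir, paste0(name, ".graphml")),
    sif = file.path(dir, paste0(name, ".sif")),
    nodes = file.path(dir, paste0(name, "_nodes.tsv")),
    edges = file.path(dir, paste0(name, "_edges.tsv"))
  )
  igraph::write_graph(pg$graph, paths[["graphml"]], format = "graphml")
  sif <- if (nrow(pg$edges) > 0) {
    sprintf("%s\tshares_de\t%s", pg$edges$from, pg$edges$to)
  } else {
    character(0)
  }
  isolated <- setdiff(pg$nodes$pathway_id, c(pg$edges$from, pg$edges$to))
  writeLines(c(sif, isolated), paths[["sif"]])
  readr::write_tsv(pg$nodes, paths[["nodes"]])
  readr::write_tsv(pg$edges, paths[["edges"]])
  invisible(paths)
}
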