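#' Flag unknown-function genes from descriptions
#'
#' Case-insensitive whole-word match of functional descriptions against the
#' unknown-function keyword set (`hypothetical`, `expressed`, `predicted`,
#' `uncharacterized`). Whole-word matching keeps e.g. "overexpressed" from
#' counting as "expressed".
#'
#' @param descriptions Tibble with `gene_id` and `description` columns
#'   (empty descriptions allowed).
#' @param keywords Keyword set (default [UNKNOWN_KEYWORDS]).
#' @return Tibble: `gene_id`, `is_unknown`, `matched` (comma-separated
#'   matched keywords, `""` when none).
#' @export
call_unknown <- function(descriptions, keywords = UNKNOWN_KEYWORDS) {
  descriptions <- as_tibble(descriptions)
  assert_cols(descriptions, c("gene_id", "description"), "descriptions")
  desc <- tolower(dplyr::coalesce(descriptions$description, ""))
  hit <- vapply(keywords, function(kw) {
    grepl(paste0("\\b", kw, "\\b"), desc)
  }, logical(length(desc)))
  hit <- matrix(hit, nrow = length(desc), dimnames = list(NULL, keywords))
  tibble(
    gene_id = descriptions$gene_id,
    is_unknown = rowSums(hit) > 0,
    matched = apply(hit, 1L, function(r) paste(keywords[r], collapse = ","))
  )
}

#' Cross-species unknown-function ortholog decision tree
#'
#' For each focal DE gene of unknown function, and separately for each
#' non-focal species, the gene is retained when (a) it has at least one
#' ortholog in that species, (b) *all* of its orthologs in that species are
#' of unknown function, and (c) at least one of those orthologs appears in
#' that species' drought-responsive gene list. Expression direction is
#' deliberately ignored. The tree is traversed once per species; with
#' `require_all_species = TRUE` a focal gene is only reported where branch
#' (b) also holds in every species in which it has orthologs.
#'
#' @param de_genes Character vector of focal DE gene ids (the pipeline's DE
#'   union across contrasts, or an external list).
#' @param unknown_calls [call_unknown()] output for the focal genes.
#' @param ortholog_table Tibble: `focal_gene`, `species`, `ortholog_gene`,
#'   `ortholog_description`.
#' @param drought_lists Named list (by species) of character vectors of
#'   drought-responsive ortholog gene ids. Species present in the table but
#'   absent here are skipped with a warning.
#' @param keywords Unknown-function keywords for the ortholog descriptions.
#' @param require_all_species Stricter cross-species mode (default FALSE).
#' @return Tibble: `focal_gene`, `species`, `ortholog_gene`.
#' @export
ortholog_decision_tree <- function(de_genes, unknown_calls, ortholog_table,
                                   drought_lists,
                                   keywords = UNKNOWN_KEYWORDS,
                                   require_all_species = FALSE) {
  ortholog_table <- as_tibble(ortholog_table)
  assert_cols(ortholog_table,
              c("focal_gene", "species", "ortholog_gene", "ortholog_description"),
              "ortholog table")
  focal_unknown <- unknown_calls$gene_id[unknown_calls$is_unknown]
  candidates <- intersect(de_genes, focal_unknown)
  species_in_table <- unique(ortholog_table$species)
  missing_sp <- setdiff(species_in_table, names(drought_lists))
  if (length(missing_sp) > 0L) {
    warn(sprintf("no drought list for species: %s; skipped",
                 paste(missing_sp, collapse = ", ")))
  }
  species_use <- intersect(species_in_table, names(drought_lists))
  orth <- filter(ortholog_table, .data$focal_gene %in% candidates)
  orth$ortholog_unknown <- call_unknown(
    tibble(gene_id = orth$ortholog_gene, description = orth$ortholog_description),
    keywords
  )$is_unknown
  per_species <- orth |>
    filter(.data$species %in% species_use) |>
    group_by(.data$focal_gene, .data$species) |>
    summarise(all_unknown = all(.data$ortholog_unknown), .groups = "drop")
  if (require_all_species) {
    strict <- orth |>
      group_by(.data$focal_gene) |>
      summarise(everywhere = all(.data$ortholog_unknown), .groups = "drop")
    per_species <- per_species |>
      left_join(strict, by = "focal_gene") |>
      mutate(all_unknown = .data$all_unknown & .data$everywhere) |>
      select(-"everywhere")
  }
  pass_b <- filter(per_species, .data$all_unknown)
  pairs <- orth |>
    semi_join(pass_b, by = c("focal_gene", "species")) |>
    rowwise_drought(drought_lists)
  pass_c <- pairs |>
    group_by(.data$focal_gene, .data$species) |>
    summarise(any_drought = any(.data$drought), .groups = "drop") |>
    filter(.data$any_drought)
  pairs |>
    semi_join(pass_c, by = c("focal_gene", "species")) |>
    filter(.data$drought) |>
    select("focal_gene", "species", "ortholog_gene") |>
    arrange(.data$species, .data$focal_gene, .data$ortholog_gene)
}

rowwise_drought <- function(pairs, drought_lists) {
  pairs$drought <- purrr::map2_lgl(
    pairs$ortholog_gene, pairs$species,
    function(g, sp) g %in% drought_lists[[sp]]
  )
  pairs
}

#' Multi-species overlap of decision-tree hits
#'
#' Counts focal genes by the combination of species in which they passed
#' the decision tree, and reports the genes found in all species and in at
#' least two species.
#'
#' @param pairs Decision-tree output ([ortholog_decision_tree()]), or a
#'   named list of character vectors of focal genes per species.
#' @return List: `regions` (tibble: region, n, genes), `per_species`
#'   (tibble: species, n), `all_species` (character), `two_or_more`
#'   (character).
#' @export
species_overlap <- function(pairs) {
  if (is.data.frame(pairs)) {
    sets <- split(pairs$focal_gene, pairs$species)
    sets <- lapply(sets, unique)
  } else {
    sets <- lapply(pairs, unique)
  }
  if (length(sets) < 2L) abort_design("need hits from >= 2 species")
  species <- names(sets)
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, species))
  region_of <- apply(member, 1L, function(r) paste(species[r], collapse = "&"))
  regions <- tibble(gene_id = genes, region = region_of) |>
    group_by(.data$region) |>
    summarise(n = n(), genes = list(.data$gene_id), .groups = "drop")
  n_species <- rowSums(member)
  list(
    regions = regions,
    per_species = tibble(species = species,
                         n = vapply(sets, length, integer(1))),
    all_species = genes[n_species == length(species)],
    two_or_more = genes[n_species >= 2]
  )
}
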