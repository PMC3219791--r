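toy_pathway_db <- function() {
  pathway_db(tibble::tibble(
    pathway_id = c("P1", "P1", "P1", "P2", "P2", "P3"),
    reaction_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    gene_id = c("a", "b", "c", "b", "d", "e"),
    is_hormone = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  ))
}

test_that("reaction coverage ratio counts reactions with DE genes", {
  db <- toy_pathway_db()
  rc <- reaction_coverage(db, de_genes = c("a", "b"), min_reactions = 1)
  expect_equal(rc$ratio[rc$pathway_id == "P1"], 2 / 3)
  expect_equal(rc$ratio[rc$pathway_id == "P2"], 1 / 2)
  expect_equal(rc$ratio[rc$pathway_id == "P3"], 0)
  # DE genes in every reaction gives 1
  rc_all <- reaction_coverage(db, de_genes = letters[1:5], min_reactions = 1)
  expect_equal(rc_all$ratio[rc_all$pathway_id == "P1"], 1)
  # pathways below min_reactions are excluded from the report
  rc3 <- reaction_coverage(db, de_genes = c("a"), min_reactions = 3)
  expect_equal(rc3$pathway_id, "P1")
})

test_that("pathway collapse takes unions and rejects chained maps", {
  db <- pathway_db(tibble::tibble(
    pathway_id = c("A", "A", "B", "B"),
    reaction_id = c("r1", "r2", "r3", "r4"),
    gene_id = c("a", "b", "b", "c")
  ))
  map <- tibble::tibble(pathway_id = c("A", "B"), collapsed_id = "AB")
  out <- collapse_pathways(db, map)
  merged <- out$table[out$table$pathway_id == "AB", ]
  expect_setequal(unique(merged$gene_id), c("a", "b", "c"))
  # collapsing preserves the total unique gene universe
  expect_setequal(unique(out$table$gene_id), unique(db$table$gene_id))
  # identity map leaves the DB unchanged
  idmap <- tibble::tibble(pathway_id = c("A", "B"), collapsed_id = c("A", "B"))
  expect_equal(collapse_pathways(db, idmap)$table, db$table)
  bad <- tibble::tibble(pathway_id = c("A", "AB"), collapsed_id = c("AB", "C"))
  expect_error(collapse_pathways(db, bad), class = "droughtseq_config_error")
})

test_that("network edges match the brute-force intersection oracle", {
  set.seed(83)
  for (rep in 1:4) {
    n_pw <- sample(10:50, 1)
    genes <- paste0("g", 1:300)
    pw_genes <- lapply(seq_len(n_pw), function(i) sample(genes, sample(5:40, 1)))
    names(pw_genes) <- sprintf("P%02d", seq_len(n_pw))
    tbl <- purrr::imap_dfr(pw_genes, function(gs, pid) {
      tibble::tibble(pathway_id = pid,
                     reaction_id = paste0(pid, ".r", seq_along(gs)),
                     gene_id = gs)
    })
    de <- sample(genes, 80)
    det <- tibble::tibble(gene_id = de,
                          direction = sample(c("up", "down"), 80, replace = TRUE))
    pg <- build_network(pathway_db(tbl), det)
    oracle <- network_oracle_edges(pw_genes, de)
    got <- dplyr::arrange(pg$edges[, c("from", "to", "weight")], from, to)
    want <- dplyr::arrange(oracle, from, to)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
    # node scores equal up - down computed independently
    for (pid in names(pw_genes)) {
      up <- sum(det$direction == "up" & det$gene_id %in% pw_genes[[pid]])
      dn <- sum(det$direction == "down" & det$gene_id %in% pw_genes[[pid]])
      expect_equal(pg$nodes$score[pg$nodes$pathway_id == pid], up - dn)
    }
  }
})

test_that("edge weight classes follow the published thresholds", {
  expect_equal(droughtseq:::edge_weight_class(c(1, 5, 6, 9, 10, 12)),
               c("<=5", "<=5", "6-9", "6-9", ">=10", ">=10"))
  # pathways sharing 12 DE genes land in the >=10 class
  shared <- paste0("s", 1:12)
  tbl <- tibble::tibble(
    pathway_id = rep(c("P1", "P2"), each = 13),
    reaction_id = paste0("r", 1:26),
    gene_id = c(shared, "x1", shared, "x2")
  )
  det <- tibble::tibble(gene_id = shared, direction = "up")
  pg <- build_network(pathway_db(tbl), det)
  expect_equal(pg$edges$class, ">=10")
  # 3 up + 3 down in one pathway: score 0, neutral class
  det2 <- tibble::tibble(gene_id = shared[1:6],
                         direction = rep(c("up", "down"), 3))
  pg2 <- build_network(pathway_db(tbl), det2)
  expect_equal(pg2$nodes$score[pg2$nodes$pathway_id == "P1"], 0)
  expect_equal(pg2$nodes$score_class[pg2$nodes$pathway_id == "P1"], "neutral")
})

test_that("no shared DE genes yields an empty edge set", {
  tbl <- tibble::tibble(pathway_id = c("P1", "P2"),
                        reaction_id = c("r1", "r2"),
                        gene_id = c("a", "b"))
  pg <- build_network(pathway_db(tbl),
                      tibble::tibble(gene_id = c("a", "b"), direction = "up"))
  expect_equal(nrow(pg$edges), 0L)
})

test_that("hormone subnetwork includes all tied shortest paths", {
  # A - x - B and A - y - B, both length 2, plus a longer detour A-z1-z2-B
  edges <- tibble::tibble(
    from = c("A", "x", "A", "y", "A", "z1", "z2"),
    to = c("x", "B", "y", "B", "z1", "z2", "B")
  )
  rows <- purrr::map_dfr(seq_len(nrow(edges)), function(i) {
    tibble::tibble(pathway_id = c(edges$from[i], edges$to[i]),
                   reaction_id = paste0("r", i, c("a", "b")),
                   gene_id = paste0("e", i))
  })
  rows$is_hormone <- rows$pathway_id %in% c("A", "B")
  db <- pathway_db(rows)
  de <- unique(rows$gene_id)
  pg <- build_network(db, tibble::tibble(gene_id = de, direction = "up"))
  hs <- hormone_subnetwork(pg, hormones = c("A", "B"))
  expect_true(all(c("x", "y") %in% hs$nodes$pathway_id))
  expect_false(any(c("z1", "z2") %in% hs$nodes$pathway_id))
  # oracle: exhaustive path enumeration gives the same tied-shortest nodes
  paths <- all_simple_paths_nodes(pg$edges, "A", "B")
  lens <- vapply(paths, length, integer(1))
  sp_nodes <- unique(unlist(paths[lens == min(lens)]))
  expect_setequal(hs$nodes$pathway_id, sp_nodes)
})

test_that("directly connected hormones contribute only their edge; isolates stay", {
  tbl <- tibble::tibble(
    pathway_id = c("A", "I", "A", "I", "C", "other"),
    reaction_id = paste0("r", 1:6),
    gene_id = c("s1", "s1", "s2", "s2", "c1", "o1"),
    is_hormone = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  pg <- build_network(pathway_db(tbl),
                      tibble::tibble(gene_id = c("s1", "s2"), direction = "up"))
  hs <- hormone_subnetwork(pg, hormones = c("A", "I", "C"))
  # disconnected hormone C is retained as an isolate
  expect_true("C" %in% hs$nodes$pathway_id)
  expect_setequal(hs$nodes$pathway_id, c("A", "I", "C"))
  expect_equal(nrow(hs$edges), 1L)
})

test_that("network export round-trips through GraphML", {
  db <- toy_pathway_db()
  pg <- build_network(db, tibble::tibble(gene_id = c("a", "b", "d"),
                                         direction = c("up", "down", "up")))
  d <- withr::local_tempdir()
  paths <- export_network(pg, d, "toy")
  expect_true(all(file.exists(paths)))
  g2 <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(sort(igraph::V(g2)$name), sort(pg$nodes$pathway_id))
  expect_equal(igraph::ecount(g2), nrow(pg$edges))
  ed2 <- igraph::as_data_frame(g2, "edges")
  expect_equal(sort(ed2$weight), sort(pg$edges$weight))
  # SIF lists isolated nodes on their own lines
  sif <- readLines(paths[["sif"]])
  expect_true(any(grepl("shares_de", sif)))
})

test_that("planted pathway enrichment is recovered from the generator", {
  cfg <- simulation_config(n_genes = 1200, seed = 29, n_conserved_unknown = 8)
  sim <- simulate_experiment(cfg)
  true_de <- unique(sim$truth$lfc$gene_id)
  db <- pathway_db(sim$pathway_table, sim$collapse_map)
  res <- enrich(true_de, pathway_categories(db))
  expect_true(all(res$significant[res$category %in% sim$truth$enriched_pathways]))
})
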