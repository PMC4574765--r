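test_that("a minimal two-entry document parses to the expected graph", {
  g <- parse_kgml(minimal_kgml())
  expect_s3_class(g, "pathway_graph")
  expect_identical(g$pathway_id, "hsa00001")
  expect_identical(g$organism, "hsa")
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_identical(g$edges$kind, "relation")
  expect_identical(g$edges$subtype, "activation")
  # multiple space-separated KEGG ids are all kept; label is the first alias
  expect_identical(g$nodes$kegg_ids[[1]], c("hsa:1356", "hsa:1359"))
  expect_identical(g$nodes$label[1], "CPA3")
  # graphics coordinates pass through unchanged
  expect_equal(g$nodes$x, c(100, 200))
  expect_equal(g$nodes$y, c(50, 50))
})

test_that("generated fixtures parse to exactly the requested counts", {
  g <- parse_kgml(generate_kgml_fixture(n_gene_nodes = 10, n_compound_nodes = 3,
                                        n_edges = 7, seed = 1))
  expect_equal(nrow(g$nodes), 13)
  expect_equal(nrow(g$edges), 7)
  expect_equal(sum(g$nodes$node_type == "gene"), 10)
  expect_equal(sum(g$nodes$node_type == "compound"), 3)
  expect_true(all(g$edges$kind == "relation"))
})

test_that("the synthetic renin-angiotensin fragment contains a CPA3 gene node", {
  g <- parse_kgml(system.file("extdata", "hsa04614-synthetic.xml",
                              package = "pathwaylens"))
  expect_identical(g$pathway_id, "hsa04614")
  idx <- which(g$nodes$label == "CPA3")
  expect_length(idx, 1)
  expect_identical(g$nodes$node_type[idx], "gene")
  expect_true("hsa:1359" %in% g$nodes$kegg_ids[[idx]])
})

test_that("group entries keep their members and reactions expand to cross products", {
  xml <- generate_kgml_fixture(n_gene_nodes = 4, n_compound_nodes = 4,
                               n_edges = 0, seed = 3, include_map = TRUE,
                               include_group = TRUE, include_reaction = TRUE)
  g <- parse_kgml(xml)
  expect_equal(nrow(g$nodes), 10)  # 4 genes + 4 compounds + map + group
  grp <- g$nodes[g$nodes$node_type == "group", ]
  expect_equal(nrow(grp), 1)
  expect_identical(grp$member_ids[[1]], c("1", "2"))
  # 2 substrates x 2 products = 4 reaction edges
  rx <- g$edges[g$edges$kind == "reaction", ]
  expect_equal(nrow(rx), 4)
  expect_true(all(rx$subtype == "irreversible"))
  expect_true("map" %in% g$nodes$node_type)
})

test_that("malformed and structurally invalid documents raise named errors", {
  expect_error(parse_kgml("<pathway><entry></pathway>"), "parse error")
  expect_error(parse_kgml("<notpathway/>"), "expected <pathway>")
  no_graphics <- '<pathway name="path:x00001"><entry id="1" type="gene"/></pathway>'
  expect_error(parse_kgml(no_graphics), "graphics")
  no_xy <- paste0('<pathway name="path:x00001"><entry id="1" type="gene">',
                  '<graphics name="A" width="46" height="17"/></entry></pathway>')
  expect_error(parse_kgml(no_xy), "'x'")
  no_type <- paste0('<pathway name="path:x00001"><entry id="1">',
                    '<graphics name="A" x="1" y="1"/></entry></pathway>')
  expect_error(parse_kgml(no_type), "'type'")
})

test_that("unknown entry types become 'other' and dangling relations are dropped", {
  xml <- paste0(
    '<pathway name="path:x00001">',
    '<entry id="1" name="x" type="brite-hierarchy"><graphics name="X" x="1" y="2"/></entry>',
    '<relation entry1="1" entry2="99" type="PPrel"/>',
    "</pathway>")
  expect_warning(g <- parse_kgml(xml), "dropped")
  expect_identical(g$nodes$node_type, "other")
  expect_equal(nrow(g$edges), 0)
})

test_that("the exported view document preserves counts and coordinates", {
  empty <- pathway_graph("x00000")
  doc0 <- graph_to_view_document(empty)
  expect_length(doc0$nodes, 0)
  expect_length(doc0$edges, 0)
  g <- parse_kgml(minimal_kgml())
  doc <- graph_to_view_document(g)
  expect_length(doc$nodes, nrow(g$nodes))
  expect_length(doc$edges, nrow(g$edges))
  expect_identical(doc$nodes[[1]]$x, g$nodes$x[1])
  expect_identical(doc$nodes[[1]]$y, g$nodes$y[1])
  expect_true(jsonlite::validate(view_document_json(doc)))
})

test_that("parse -> export -> re-import round-trips generated fixtures exactly", {
  for (seed in 1:8) {
    xml <- generate_kgml_fixture(n_gene_nodes = 5 + seed, n_compound_nodes = 4,
                                 n_edges = 3 * seed, seed = seed,
                                 include_map = TRUE, include_group = TRUE,
                                 include_reaction = seed %% 2 == 0)
    g <- parse_kgml(xml)
    g2 <- read_view_document(view_document_json(graph_to_view_document(g)))
    expect_same_graph(g, g2)
  }
})

test_that("pathway_gene_ids deduplicates in first-occurrence order", {
  expect_identical(pathway_gene_ids(pathway_graph("x00000")), character())
  xml <- paste0(
    '<pathway name="path:x00001">',
    '<entry id="1" name="hsa:9 hsa:5" type="gene"><graphics name="A" x="1" y="1"/></entry>',
    '<entry id="2" name="hsa:5" type="gene"><graphics name="B" x="2" y="2"/></entry>',
    '<entry id="3" name="cpd:C00001" type="compound"><graphics name="C" x="3" y="3"/></entry>',
    "</pathway>")
  expect_identical(pathway_gene_ids(parse_kgml(xml)), c("hsa:9", "hsa:5"))
  # planted pool is recovered exactly
  pool <- c("g1", "g2", "g3")
  g <- parse_kgml(generate_kgml_fixture(12, 0, 0, seed = 7, gene_pool = pool))
  expect_true(all(pathway_gene_ids(g) %in% pool))
})

test_that("graph invariants are enforced by the validator", {
  nodes <- data.frame(entry_id = c("1", "1"), node_type = "gene", label = "x",
                      x = 1, y = 1, width = 10, height = 10,
                      kegg_ids = I(list(character(), character())),
                      member_ids = I(list(character(), character())),
                      stringsAsFactors = FALSE)
  expect_error(pathway_graph("p", nodes = nodes), "duplicate entry_id")
  nodes2 <- nodes[1, ]
  nodes2$width <- 0
  expect_error(pathway_graph("p", nodes = nodes2), "width/height")
  edges <- data.frame(source = "1", target = "2", kind = "relation",
                      subtype = "", stringsAsFactors = FALSE)
  expect_error(pathway_graph("p", nodes = nodes[1, ], edges = edges),
               "refers to no node")
})
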