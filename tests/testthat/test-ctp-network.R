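# The bundled identification table doubles as an in-package fixture: seven
# key compounds, their correlating key targets, and the reported degrees.
fixture_net <- function() {
  assemble_ctp(
    key_compound_edges(),
    data.frame(symbol = character(0), term_id = character(0)),
    key_targets = key_target_table()$symbol,
    roster = list(targets = key_target_table()$symbol)
  )
}

test_that("assembly builds a tripartite, layer-prefixed, duplicate-free graph", {
  net <- fixture_net()
  expect_s3_class(net, "ctp_network")
  counts <- ctp_counts(net)
  expect_equal(unname(counts[c("compounds", "targets")]), c(7, 9))
  # no within-layer or compound-pathway edges by construction
  src_layer <- net$nodes$layer[match(net$edges$source, net$nodes$id)]
  tgt_layer <- net$nodes$layer[match(net$edges$target, net$nodes$id)]
  expect_true(all(paste(src_layer, tgt_layer) %in%
                    c("compound target", "target pathway")))
  # every edge endpoint exists in the node table
  expect_true(all(c(net$edges$source, net$edges$target) %in% net$nodes$id))
  # duplicated input edge leaves the edge count unchanged
  edges <- key_compound_edges()
  net2 <- assemble_ctp(rbind(edges, edges[3, ]),
                       data.frame(symbol = character(0), term_id = character(0)),
                       key_target_table()$symbol)
  expect_equal(nrow(net2$edges), nrow(edges))
})

test_that("node arithmetic: full rosters give the layer-sum node count", {
  roster <- list(compounds = sprintf("c%03d", 1:143),
                 targets = sprintf("T%d", 1:9),
                 pathways = sprintf("P%d", 1:20))
  net <- assemble_ctp(
    data.frame(compound_id = "c001", symbol = "T1"),
    data.frame(symbol = "T1", term_id = "P1"),
    key_targets = sprintf("T%d", 1:9), roster = roster
  )
  expect_equal(unname(ctp_counts(net)[["nodes"]]), 143 + 9 + 20)
  # empty everything gives an empty network
  empty <- assemble_ctp(data.frame(compound_id = character(0), symbol = character(0)),
                        data.frame(symbol = character(0), term_id = character(0)),
                        character(0))
  expect_equal(unname(ctp_counts(empty)[["nodes"]]), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("edges to unknown key targets are dropped with a warning", {
  expect_warning(
    net <- assemble_ctp(data.frame(compound_id = "c1", symbol = c("GOOD", "ROGUE")),
                        data.frame(symbol = character(0), term_id = character(0)),
                        key_targets = "GOOD"),
    "dropping 1"
  )
  expect_equal(nrow(net$edges), 1)
})

test_that("compound ranking reproduces the reported degrees", {
  ranks <- rank_compounds(fixture_net())
  expect_equal(ranks$compound_id[1], "Scopoletin")
  expect_equal(ranks$degree[1], 4)
  expect_equal(ranks$degree[ranks$compound_id == "Ferulic acid"], 3)
  # every row matches its reported degree
  kc <- key_compound_table()
  expect_equal(ranks$degree[match(kc$name, ranks$compound_id)],
               kc$degree_reported)
  # degree equals the number of correlating targets, and degrees sum to the
  # compound-target edge count
  expect_equal(ranks$degree,
               lengths(strsplit(ranks$correlating_targets, ";")))
  expect_equal(sum(ranks$degree),
               unname(ctp_counts(fixture_net())[["compound_target_edges"]]))
  # a roster compound with no edges ranks last with degree 0
  net0 <- assemble_ctp(key_compound_edges(),
                       data.frame(symbol = character(0), term_id = character(0)),
                       key_target_table()$symbol,
                       roster = list(compounds = "Zz inert"))
  r0 <- rank_compounds(net0)
  expect_equal(r0$degree[r0$compound_id == "Zz inert"], 0)
  expect_equal(r0$compound_id[nrow(r0)], "Zz inert")
})

test_that("key-compound selection supports degree threshold and top-k rules", {
  ranks <- rank_compounds(fixture_net())
  sel3 <- select_key_compounds(ranks, degree_min = 3)
  expect_setequal(sel3$compound_id,
                  c("Scopoletin", "Neocnidilide", "Liquiritic acid",
                    "Isoglabrolide", "Glabric acid", "Ferulic acid",
                    "Erybacin B"))
  expect_equal(nrow(select_key_compounds(ranks, degree_min = 5)), 0)
  expect_equal(select_key_compounds(ranks, top_k = 1)$compound_id, "Scopoletin")
  expect_error(select_key_compounds(ranks, top_k = 0), "positive")
  expect_error(select_key_compounds(ranks), "exactly one")
  expect_error(select_key_compounds(ranks, top_k = 2, degree_min = 3),
               "exactly one")
})

test_that("assembly is order-independent and exports round-trip exactly", {
  edges <- key_compound_edges()
  tp <- data.frame(symbol = c("TNF", "IL6"), term_id = c("P1", "P1"))
  key <- key_target_table()$symbol
  net_a <- assemble_ctp(edges, tp, key)
  set.seed(8)
  net_b <- assemble_ctp(edges[sample(nrow(edges)), ], tp[2:1, ], key)
  expect_identical(net_a, net_b)
  node_f <- withr::local_tempfile(fileext = ".tsv")
  edge_f <- withr::local_tempfile(fileext = ".tsv")
  exported <- export_cytoscape(net_a, node_f, edge_f)
  # node table carries per-node degree; 7 compound rows here
  expect_equal(sum(exported$nodes$layer == "compound"), 7)
  back <- read_ctp_tables(node_f, edge_f)
  expect_equal(back$nodes, net_a$nodes)
  expect_equal(back$edges, net_a$edges)
  # empty network exports header-only files
  empty <- assemble_ctp(data.frame(compound_id = character(0), symbol = character(0)),
                        data.frame(symbol = character(0), term_id = character(0)),
                        character(0))
  export_cytoscape(empty, node_f, edge_f)
  expect_equal(length(readLines(node_f)), 1)
  expect_equal(length(readLines(edge_f)), 1)
})
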