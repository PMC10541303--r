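star4 <- data.frame(
  protein1 = c("HUB", "HUB", "HUB"),
  protein2 = c("A", "B", "C"),
  combined_score = c(900L, 800L, 700L),
  stringsAsFactors = FALSE
)

test_that("STRING-style edge loading filters, symmetrizes and deduplicates", {
  g <- load_ppi(star4, score_min = 700)
  expect_equal(igraph::ecount(g), 3)         # score 700 kept (inclusive)
  g2 <- load_ppi(star4, score_min = 701)
  expect_equal(igraph::ecount(g2), 2)
  # self-loop dropped with a warning
  withself <- rbind(star4, data.frame(protein1 = "A", protein2 = "A",
                                      combined_score = 950L))
  expect_warning(g3 <- load_ppi(withself, 700), "self-loop")
  expect_equal(igraph::ecount(g3), 3)
  # (A,B) and (B,A) collapse to one edge
  dup <- rbind(star4, data.frame(protein1 = "A", protein2 = "HUB",
                                 combined_score = 750L))
  g4 <- load_ppi(dup, 700)
  expect_equal(igraph::ecount(g4), 3)
  # malformed and out-of-range rows are rejected with line numbers
  bad <- star4; bad$combined_score[2] <- 1500L
  expect_error(load_ppi(bad, 700), "out of range.*3")
  bad2 <- star4; bad2$protein1[1] <- ""
  expect_error(load_ppi(bad2, 700), "malformed.*2")
})

test_that("star and complete graphs give their analytic centralities", {
  cent <- ppi_centralities(load_ppi(star4, 700))
  hub <- cent[cent$symbol == "HUB", ]
  expect_equal(hub$degree, 3L)
  expect_equal(hub$betweenness, 1.0)
  expect_equal(hub$closeness, 1.0)
  leaf <- cent[cent$symbol == "A", ]
  expect_equal(leaf$closeness, 3 / 5)
  expect_equal(leaf$betweenness, 0)
  # complete graph: betweenness 0, closeness 1 everywhere
  k5 <- t(combn(sprintf("P%d", 1:5), 2))
  cent5 <- ppi_centralities(load_ppi(
    data.frame(protein1 = k5[, 1], protein2 = k5[, 2], combined_score = 900L),
    700
  ))
  expect_true(all(cent5$betweenness == 0))
  expect_true(all(cent5$closeness == 1))
})

test_that("disconnected graphs use component-scaled closeness and 0 for isolates", {
  # two K2 components in a 4-node graph: closeness = (1/1) * (1/3)
  g <- load_ppi(data.frame(protein1 = c("A", "C"), protein2 = c("B", "D"),
                           combined_score = 900L), 700)
  cent <- ppi_centralities(g)
  expect_true(all(abs(cent$closeness - 1 / 3) < 1e-12))
  # an isolated node gets closeness and betweenness 0
  g2 <- igraph::add_vertices(g, 1, name = "LONER")
  cent2 <- ppi_centralities(g2)
  expect_equal(cent2$closeness[cent2$symbol == "LONER"], 0)
  expect_equal(cent2$betweenness[cent2$symbol == "LONER"], 0)
})

test_that("centralities equal the exhaustive shortest-path oracle on random graphs", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    rg <- random_graph(n, p = runif(1, 0.15, 0.7))
    if (nrow(rg$edges) == 0) next
    g <- load_ppi(rg$edges, 700)
    cent <- ppi_centralities(g)
    orc <- oracle_centralities(rg$adj)
    idx <- match(cent$symbol, rg$syms)
    expect_equal(cent$degree, orc$degree[idx])
    # the oracle normalizes over all n nodes; the graph drops edgeless ones,
    # so rescale the normalizations to the graph's node count
    n_g <- igraph::vcount(g)
    bc_scale <- if (n_g > 2) ((n - 1) * (n - 2)) / ((n_g - 1) * (n_g - 2)) else 1
    expect_equal(cent$betweenness, orc$betweenness[idx] * bc_scale,
                 tolerance = 1e-12)
    expect_equal(cent$closeness,
                 orc$closeness[idx] * (n - 1) / max(n_g - 1, 1),
                 tolerance = 1e-12)
    # handshake identity
    expect_equal(sum(cent$degree), 2 * igraph::ecount(g))
  }
})

test_that("the triple topological filter gates inclusively and monotonically", {
  rec <- data.frame(
    symbol = c("A", "B", "C", "D"),
    degree = c(12L, 12L, 9L, 15L),
    betweenness = c(0.002, 0.0005, 0.01, 0.001),
    closeness = c(0.65, 0.65, 0.7, 0.6)
  )
  expect_equal(filter_key_targets(rec, 10, 0.001, 0.6), c("D", "A"))
  # each threshold excludes on its own
  expect_false("B" %in% filter_key_targets(rec, 10, 0.001, 0.6)) # bc too low
  expect_false("C" %in% filter_key_targets(rec, 10, 0.001, 0.6)) # degree too low
  # monotone non-increasing in every threshold
  base <- length(filter_key_targets(rec, 10, 0.001, 0.6))
  expect_lte(length(filter_key_targets(rec, 13, 0.001, 0.6)), base)
  expect_lte(length(filter_key_targets(rec, 10, 0.0015, 0.6)), base)
  expect_lte(length(filter_key_targets(rec, 10, 0.001, 0.66)), base)
  expect_error(filter_key_targets(rec, -1, 0.001, 0.6), "non-negative")
})
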