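small_cfg <- function(...) {
  synth_config(seed = 123, n_herbs = 4L, compounds_per_herb = 25L,
               n_targets_universe = 300L, n_disease_genes = 40L, ...)
}

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_cfg()
  expect_identical(gen_library(cfg), gen_library(cfg))
  td1 <- gen_targets_and_disease(cfg, compound_ids = sprintf("c%d", 1:10))
  td2 <- gen_targets_and_disease(cfg, compound_ids = sprintf("c%d", 1:10))
  expect_identical(td1, td2)
  genes <- sprintf("G%05d", 1:20)
  expect_identical(gen_ppi(cfg, genes), gen_ppi(cfg, genes))
  pw1 <- gen_pathways(cfg, genes[1:5], genes)
  pw2 <- gen_pathways(cfg, genes[1:5], genes)
  expect_identical(pw1, pw2)
  # whole-file determinism: identical bytes for the GMT
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(pw1$collection, f1); write_gmt(pw2$collection, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("library shape follows the configuration arithmetic", {
  lib <- gen_library(synth_config(seed = 1, n_herbs = 10L,
                                  compounds_per_herb = 242L))
  expect_equal(nrow(lib), 2420)
  # no duplicates requested: dedup is the identity (up to row order)
  cfg0 <- small_cfg(duplicate_rate = 0)
  lib0 <- gen_library(cfg0)
  expect_equal(nrow(deduplicate(lib0)), nrow(lib0))
  # with duplicates, dedup removes exactly the injected fraction
  cfg15 <- small_cfg(duplicate_rate = 0.2)
  lib15 <- gen_library(cfg15)
  expect_equal(nrow(lib15) - nrow(deduplicate(lib15)),
               floor(nrow(lib15) * 0.2))
  # descriptor sanity: generated tables pass the library validator
  expect_true(all(lib0$mw > 0 & lib0$psa >= 0 & lib0$hba >= 0))
  expect_type(lib0$ob, "logical")
})

test_that("relevance scores are Pareto-tailed with the configured mass above 9", {
  cfg <- synth_config(seed = 9, n_targets_universe = 6000L,
                      n_disease_genes = 3000L, relevance_shape = 0.834)
  td <- gen_targets_and_disease(cfg, compound_ids = "c1")
  frac <- mean(td$disease$relevance_score >= 9)
  # Pareto CDF oracle: P(X >= 9) = (3/9)^0.834 = 0.400
  expect_equal(frac, (1 / 3)^0.834, tolerance = 0.05)
})

test_that("prediction edges honor the Poisson size knob and planting", {
  cfg0 <- small_cfg(predictions_per_compound = 0)
  td0 <- gen_targets_and_disease(cfg0, compound_ids = sprintf("c%d", 1:5))
  expect_equal(nrow(td0$predictions), 0)
  # planted common genes all appear among predictions; planted potential
  # genes all score >= 9 and the rest of the planted set scores < 9
  cfgp <- small_cfg(n_planted_common = 12L, n_planted_potential = 5L)
  tdp <- gen_targets_and_disease(cfgp, compound_ids = sprintf("c%d", 1:40))
  expect_true(all(tdp$planted_common %in% tdp$predictions$symbol))
  sc <- tdp$disease$relevance_score[match(tdp$planted_common, tdp$disease$symbol)]
  pot <- tdp$planted_common %in% tdp$planted_potential
  expect_true(all(sc[pot] >= 9))
  expect_true(all(sc[!pot] < 9))
  # non-planted disease genes never enter the predictions
  outside <- setdiff(tdp$disease$symbol, tdp$planted_common)
  expect_false(any(outside %in% tdp$predictions$symbol))
})

test_that("planted PPI hubs are exactly recoverable by the topological filter", {
  cfg <- small_cfg(n_planted_hubs = 9L, hub_degree_boost = 6L, ppi_density = 0.08)
  genes <- sprintf("G%05d", 1:22)
  ppi <- gen_ppi(cfg, genes)
  # hub degree is deterministic: clique + spokes
  cent <- ppi_centralities(load_ppi(ppi$edges, 700))
  hub_deg <- cent$degree[cent$symbol %in% ppi$hubs]
  expect_true(all(hub_deg == 9 - 1 + 6))
  key <- filter_key_targets(cent, deg_min = 11, bc_min = 0.001, cc_min = 0.5)
  expect_setequal(key, ppi$hubs)
  # degenerate: no density, no hubs -> empty graph
  cfg0 <- small_cfg(n_planted_hubs = 0L, ppi_density = 0)
  expect_equal(nrow(gen_ppi(cfg0, genes)$edges), 0)
})

test_that("planted pathway terms dominate the over-representation ranking", {
  cfg <- small_cfg(n_pathways = 30L, n_planted_enriched_terms = 3L,
                   planted_overlap = 1.0)
  universe <- sprintf("G%05d", 1:300)
  key <- sample(universe, 9)
  pw <- gen_pathways(cfg, key, universe)
  expect_length(pw$collection, 30)
  res <- enrich(key, pw$collection, universe = universe, p_max = 1)
  expect_setequal(res$term_id[1:3], pw$planted_terms)
  # zero pathways -> empty collection
  cfg0 <- small_cfg(n_pathways = 0L, n_planted_enriched_terms = 0L)
  expect_length(gen_pathways(cfg0, key, universe)$collection, 0)
})

test_that("generated input files pass the pipeline validators", {
  out <- withr::local_tempdir()
  cfg <- small_cfg(n_planted_common = 12L, n_planted_potential = 6L,
                   n_planted_hubs = 4L, hub_degree_boost = 4L)
  inp <- write_synthetic_inputs(cfg, out)
  rep <- validate_inputs(inp$paths)
  expect_false(any(rep$level == "error"))
  # byte-identical regeneration
  out2 <- withr::local_tempdir()
  write_synthetic_inputs(cfg, out2)
  for (f in basename(unlist(inp$paths))) {
    expect_identical(readLines(file.path(out, f)), readLines(file.path(out2, f)),
                     info = f)
  }
})
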