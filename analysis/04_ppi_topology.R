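#!/usr/bin/env Rscript

# Stage 4: PPI topology and key-target selection.
#
# Loads the PPI edge list at the configured score cut, restricts it to the
# potential targets, computes degree / betweenness / closeness, and keeps
# the nodes passing all three thresholds. Writes results/centrality.tsv and
# results/key_targets.txt.

suppressPackageStartupMessages(library(npscreen))

cfg <- read_pipeline_config(file.path("results", "pipeline_config.json"))
potential <- utils::read.delim(file.path("results", "potential_targets.tsv"))

g <- load_ppi(cfg$ppi, score_min = cfg$score_min)
g <- igraph::induced_subgraph(
  g, igraph::V(g)[igraph::V(g)$name %in% potential$symbol]
)
cent <- ppi_centralities(g)
key_targets <- filter_key_targets(cent, deg_min = cfg$deg_min,
                                  bc_min = cfg$bc_min, cc_min = cfg$cc_min)
cent$passed_filter <- cent$symbol %in% key_targets

utils::write.table(cent, file.path("results", "centrality.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(key_targets, file.path("results", "key_targets.txt"))
cat(sprintf("PPI on %d potential targets: %d key targets (degree >= %g, bc >= %g, cc >= %g)\n",
            nrow(cent), length(key_targets), cfg$deg_min, cfg$bc_min,
            cfg$cc_min))
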