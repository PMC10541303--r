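#!/usr/bin/env Rscript

# Stage 6: compound-target-pathway network assembly and compound ranking.
#
# Builds the tripartite network over all screened compounds, the key
# targets and the top enriched pathways; ranks compounds by target degree
# and selects the key compounds. Writes results/ctp_nodes.tsv,
# results/ctp_edges.tsv, results/compound_ranking.tsv and
# results/key_compounds.tsv.

suppressPackageStartupMessages(library(npscreen))

cfg <- read_pipeline_config(file.path("results", "pipeline_config.json"))
passed <- utils::read.delim(file.path("results", "screened_compounds.tsv"))
key_targets <- readLines(file.path("results", "key_targets.txt"))
enr <- utils::read.delim(file.path("results", "enrichment.tsv"))
top <- top_pathways(enr, cfg$top_pathways)

preds <- read_prediction_table(cfg$predictions)
preds <- preds[preds$compound_id %in% passed$compound_id, , drop = FALSE]
ct_edges <- unique(preds[preds$symbol %in% key_targets,
                         c("compound_id", "symbol"), drop = FALSE])
tp_edges <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
  mem <- intersect(strsplit(top$genes[i], ";", fixed = TRUE)[[1]], key_targets)
  if (!length(mem)) return(NULL)
  data.frame(symbol = mem, term_id = top$term_id[i], stringsAsFactors = FALSE)
}))
if (is.null(tp_edges)) {
  tp_edges <- data.frame(symbol = character(0), term_id = character(0))
}

net <- assemble_ctp(ct_edges, tp_edges, key_targets,
                    roster = list(compounds = passed$compound_id,
                                  targets = key_targets,
                                  pathways = top$term_id))
export_cytoscape(net, file.path("results", "ctp_nodes.tsv"),
                 file.path("results", "ctp_edges.tsv"))

ranks <- rank_compounds(net)
utils::write.table(ranks, file.path("results", "compound_ranking.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
key_compounds <- if (cfg$compound_rule == "top_k") {
  select_key_compounds(ranks, top_k = cfg$compound_rule_value)
} else {
  select_key_compounds(ranks, degree_min = cfg$compound_rule_value)
}
utils::write.table(key_compounds, file.path("results", "key_compounds.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

counts <- ctp_counts(net)
cat(sprintf("C-T-P network: %d nodes (%d compounds, %d targets, %d pathways), %d edges; %d key compounds\n",
            counts[["nodes"]], counts[["compounds"]], counts[["targets"]],
            counts[["pathways"]], counts[["edges"]], nrow(key_compounds)))
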