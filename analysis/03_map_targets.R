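#!/usr/bin/env Rscript

# Stage 3: compound-target mapping and disease intersection.
#
# Restricts the predicted targets to compounds that survived the screen,
# intersects them with the disease gene set, and keeps the common genes at
# or above the relevance cut. Writes results/potential_targets.tsv and
# results/venn_summary.json.

suppressPackageStartupMessages(library(npscreen))

cfg <- read_pipeline_config(file.path("results", "pipeline_config.json"))
passed <- utils::read.delim(file.path("results", "screened_compounds.tsv"))

preds <- read_prediction_table(cfg$predictions)
preds <- preds[preds$compound_id %in% passed$compound_id, , drop = FALSE]
disease <- read_disease_table(cfg$disease)

venn <- intersect_targets(preds$symbol, disease)
jsonlite::write_json(
  list(predicted = unname(venn$counts[["predicted"]]),
       disease = unname(venn$counts[["disease"]]),
       common = unname(venn$counts[["common"]])),
  file.path("results", "venn_summary.json"), auto_unbox = TRUE
)

potential <- filter_by_relevance(venn, cfg$relevance_min)
utils::write.table(potential, file.path("results", "potential_targets.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d predicted vs %d disease genes: %d common, %d potential (relevance >= %g)\n",
            venn$counts[["predicted"]], venn$counts[["disease"]],
            venn$counts[["common"]], nrow(potential), cfg$relevance_min))
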