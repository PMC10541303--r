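#!/usr/bin/env Rscript

# Stage 5: pathway over-representation of the key targets.
#
# Hypergeometric enrichment of the key-target set against the GMT
# collection, at the configured p cut and adjustment. Writes
# results/enrichment.tsv.

suppressPackageStartupMessages(library(npscreen))

cfg <- read_pipeline_config(file.path("results", "pipeline_config.json"))
key_targets <- readLines(file.path("results", "key_targets.txt"))

collection <- read_gmt(cfg$gmt)
enr <- enrich(key_targets, collection, p_max = cfg$p_max, adjust = cfg$adjust)

utils::write.table(enr, file.path("results", "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d terms enriched at p < %g (%s adjustment)\n",
            nrow(enr), length(collection), cfg$p_max, cfg$adjust))
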