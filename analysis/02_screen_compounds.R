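#!/usr/bin/env Rscript

# Stage 2: QED drug-likeness screen of the compound library.
#
# Reads results/pipeline_config.json (written by 01_simulate.R), scores every
# compound, applies the QED/oral-bioavailability gate and deduplicates
# multi-herb entries. Writes results/screened_compounds.tsv and the screen
# portion of the funnel.

suppressPackageStartupMessages(library(npscreen))

cfg <- read_pipeline_config(file.path("results", "pipeline_config.json"))

lib <- read_compound_table(cfg$compounds)
lib <- qed_score_library(lib, weights = cfg$qed_weights)
scr <- screen_compounds(lib, qed_cutoff = cfg$qed_cutoff,
                        require_ob = cfg$require_ob)

utils::write.table(scr$passed, file.path("results", "screened_compounds.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(as.list(scr$funnel),
                     file.path("results", "screen_funnel.json"),
                     auto_unbox = TRUE)
cat(sprintf("screened %d compounds: %d pass QED >= %.2f%s, %d after dedup\n",
            scr$funnel[["n_input"]], scr$funnel[["n_pass"]], cfg$qed_cutoff,
            if (cfg$require_ob) " with OB" else "", scr$funnel[["n_dedup"]]))
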