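#!/usr/bin/env Rscript

# Stage 1: generate the study-shaped synthetic inputs.
#
# Writes the five pipeline input files (compound library, compound-target
# predictions, disease genes, PPI edges, pathway GMT) plus the planted
# ground truth, under results/synthetic_inputs/.

suppressPackageStartupMessages(library(npscreen))

seed <- 1L
indir <- file.path("results", "synthetic_inputs")

cfg <- synth_preset_study_scale(seed = seed)
inp <- write_synthetic_inputs(cfg, indir)

jsonlite::write_json(inp$truth, file.path(indir, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
write_pipeline_config(
  pipeline_config(
    compounds = inp$paths$compounds, predictions = inp$paths$predictions,
    disease = inp$paths$disease, ppi = inp$paths$ppi, gmt = inp$paths$gmt,
    outdir = "results", seed = seed
  ),
  file.path("results", "pipeline_config.json")
)

val <- validate_inputs(inp$paths)
print(val, row.names = FALSE)
if (any(val$level == "error")) stop("generated inputs failed validation")
cat("inputs written to", indir, "\n")
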