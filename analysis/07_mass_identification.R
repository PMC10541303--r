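#!/usr/bin/env Rscript

# Stage 7: exact-mass verification of the bundled key-compound table.
#
# Recomputes monoisotopic masses, protonated adduct m/z values and
# signed ppm errors for the seven bundled key compounds. Writes
# results/mass_identification.tsv.

suppressPackageStartupMessages(library(npscreen))

mt <- mass_table(key_compound_table())
utils::write.table(mt, file.path("results", "mass_identification.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

show <- mt[, c("name", "formula", "adduct", "calculated_M_display",
               "theoretical_mz_display", "measured_mz", "error_ppm_display")]
print(show, row.names = FALSE)
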