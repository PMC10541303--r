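#' Bundled key-compound identification table
#'
#' The seven key compounds of the ten-herb immune-boosting decoction
#' (Insampaedok-san) as identified by HPLC-QTOF-MS in positive ESI mode:
#' molecular formula, observed adduct, measured m/z, the reported network
#' degree and the key targets each compound correlates with. Ships with the
#' package so the mass arithmetic and the C-T-P degree bookkeeping can be
#' exercised end to end without any database access.
#'
#' @return data.frame with columns `peak, name, formula, degree_reported,
#'   correlating_targets, rt_min, adduct, calculated_mz_reported,
#'   measured_mz, error_ppm_reported, origin`.
#' @export
key_compound_table <- function() {
  utils::read.delim(
    system.file("extdata", "key_compounds.tsv", package = "npscreen"),
    stringsAsFactors = FALSE
  )
}

#' Bundled key-target table
#'
#' The nine key target genes selected by the triple topological criterion
#' on the potential-target PPI network, with UniProt accessions, reported
#' subnetwork degrees and disease relevance scores.
#'
#' @return data.frame with columns `uniprot, symbol, degree,
#'   relevance_score`.
#' @export
key_target_table <- function() {
  utils::read.delim(
    system.file("extdata", "key_targets.tsv", package = "npscreen"),
    stringsAsFactors = FALSE
  )
}

#' Compound-target edges implied by the key-compound table
#'
#' Expands the semicolon-joined `correlating_targets` column into an edge
#' list suitable for [assemble_ctp()].
#'
#' @param compounds Table in the [key_compound_table()] layout.
#' @return data.frame `compound_id, symbol`.
#' @export
key_compound_edges <- function(compounds = key_compound_table()) {
  do.call(rbind, lapply(seq_len(nrow(compounds)), function(i) {
    data.frame(
      compound_id = compounds$name[i],
      symbol = strsplit(compounds$correlating_targets[i], ";", fixed = TRUE)[[1]],
      stringsAsFactors = FALSE
    )
  }))
}
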