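#' Read a compound library table
#'
#' CSV or TSV (sniffed from the extension) with header
#' `compound_id, name, herbs, mw, alogp, hba, hbd, psa, rotb, arom, alerts,
#' ob`; `formula`, `smiles` and `inchikey` are optional. `ob` is coerced to
#' logical.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_compound_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "\"")
  req <- c("compound_id", "name", "herbs", "mw", "alogp", "hba", "hbd",
           "psa", "rotb", "arom", "alerts", "ob")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("compound table ", sQuote(path), " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x$ob <- as.logical(x$ob)
  x
}

#' Read a compound-target prediction edge table
#' @param path TSV with columns `compound_id, symbol` and optional
#'   `prediction_probability`.
#' @return data.frame with canonical symbols.
#' @export
read_prediction_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "symbol")
  if (!all(req %in% names(x))) {
    stop("prediction table ", sQuote(path), " needs columns: ",
         paste(req, collapse = ", "))
  }
  x$symbol <- canonicalize_symbol(x$symbol)
  x
}

#' Read a disease gene table
#' @param path TSV with columns `symbol, relevance_score` and optional
#'   `uniprot`.
#' @return data.frame with canonical symbols.
#' @export
read_disease_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("symbol", "relevance_score")
  if (!all(req %in% names(x))) {
    stop("disease gene table ", sQuote(path), " needs columns: ",
         paste(req, collapse = ", "))
  }
  x$symbol <- canonicalize_symbol(x$symbol)
  x
}

#' Pipeline configuration
#'
#' All thresholds default to the conventional screen settings: QED >= 0.4
#' with the OB gate, disease relevance >= 9, STRING combined score >= 700,
#' topology (degree, betweenness, closeness) >= (10, 0.001, 0.6),
#' enrichment p < 0.05 with the top 20 pathways, key compounds by
#' degree >= 3.
#'
#' @param compounds,predictions,disease,ppi,gmt Input file paths.
#' @param outdir Output directory.
#' @param qed_cutoff,require_ob,qed_weights Compound-screen settings.
#' @param relevance_min Disease relevance cut.
#' @param score_min PPI combined-score cut (0-1000 scale).
#' @param deg_min,bc_min,cc_min Topological thresholds.
#' @param p_max,adjust,top_pathways Enrichment settings (`adjust` is
#'   `"none"` or `"BH"`).
#' @param compound_rule,compound_rule_value Key-compound selector:
#'   `"degree_min"` (default, value 3) or `"top_k"`.
#' @param seed Seed for any sampling (none is used by the deterministic
#'   stages; kept for forward compatibility).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(compounds, predictions, disease, ppi, gmt,
                            outdir = ".",
                            qed_cutoff = 0.4, require_ob = TRUE,
                            qed_weights = "unweighted",
                            relevance_min = 9,
                            score_min = 700,
                            deg_min = 10, bc_min = 0.001, cc_min = 0.6,
                            p_max = 0.05, adjust = "none", top_pathways = 20,
                            compound_rule = "degree_min",
                            compound_rule_value = 3,
                            seed = 1L) {
  cfg <- list(
    compounds = compounds, predictions = predictions, disease = disease,
    ppi = ppi, gmt = gmt, outdir = outdir,
    qed_cutoff = qed_cutoff, require_ob = require_ob,
    qed_weights = qed_weights, relevance_min = relevance_min,
    score_min = score_min, deg_min = deg_min, bc_min = bc_min,
    cc_min = cc_min, p_max = p_max, adjust = adjust,
    top_pathways = top_pathways, compound_rule = compound_rule,
    compound_rule_value = compound_rule_value, seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' The JSON round-trip is lossless, so a run is fully described by its
#' config file.
#'
#' @param cfg A `pipeline_config`.
#' @param path JSON path.
#' @return `write_pipeline_config` the path (invisibly);
#'   `read_pipeline_config` the config.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Validate pipeline input files
#'
#' Per-file schema checks (columns, types, ranges), duplicate detection and
#' a symbol-case normalization preview. Never mutates inputs; unreadable
#' files yield an error entry while the other files are still checked.
#'
#' @param paths Named list/vector with entries `compounds`, `predictions`,
#'   `disease`, `ppi`, `gmt` (any subset).
#' @return data.frame `file, level, message` (`level` is "error", "warning"
#'   or "ok").
#' @export
validate_inputs <- function(paths) {
  out <- list()
  note <- function(file, level, message) {
    out[[length(out) + 1L]] <<- data.frame(file = file, level = level,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  check <- function(name, fn) {
    p <- paths[[name]]
    if (is.null(p)) return(invisible())
    res <- tryCatch(fn(p), error = function(e) conditionMessage(e))
    if (is.character(res) && length(res) == 1L && !identical(res, "ok")) {
      note(name, "error", res)
    }
  }
  check("compounds", function(p) {
    x <- read_compound_table(p)
    bad <- which(x$mw <= 0 | x$psa < 0 | x$hba < 0 | x$hbd < 0 |
                   x$rotb < 0 | x$arom < 0 | x$alerts < 0)
    if (length(bad)) {
      note("compounds", "error",
           paste("descriptor out of range at row(s):",
                 paste(utils::head(bad, 5L), collapse = ", ")))
    }
    if (anyNA(x$ob)) note("compounds", "error", "unparseable ob flag")
    note("compounds", "ok", sprintf("%d rows, %d unique compound ids",
                                    nrow(x), length(unique(x$compound_id))))
    "ok"
  })
  check("predictions", function(p) {
    x <- read_prediction_table(p)
    if (anyDuplicated(x[, c("compound_id", "symbol")])) {
      note("predictions", "warning", "duplicate compound-target pairs")
    }
    note("predictions", "ok", sprintf("%d edges, %d distinct targets",
                                      nrow(x), length(unique(x$symbol))))
    "ok"
  })
  check("disease", function(p) {
    x <- read_disease_table(p)
    bad <- which(is.na(x$relevance_score) | x$relevance_score < 0)
    if (length(bad)) {
      note("disease", "error",
           paste("negative or missing relevance score at row(s):",
                 paste(utils::head(bad, 5L), collapse = ", ")))
    }
    raw <- utils::read.delim(p, stringsAsFactors = FALSE)$symbol
    n_fix <- sum(raw != canonicalize_symbol(raw))
    if (n_fix) {
      note("disease", "warning",
           sprintf("%d symbol(s) will be case-normalized", n_fix))
    }
    note("disease", "ok", sprintf("%d genes", nrow(x)))
    "ok"
  })
  check("ppi", function(p) {
    g <- load_ppi(p, score_min = 0)
    note("ppi", "ok", sprintf("%d nodes, %d edges",
                              igraph::vcount(g), igraph::ecount(g)))
    "ok"
  })
  check("gmt", function(p) {
    sets <- read_gmt(p)
    note("gmt", "ok", sprintf("%d terms, %d genes in union", length(sets),
                              length(unique(unlist(lapply(sets, `[[`, "members"))))))
    "ok"
  })
  if (!length(out)) {
    return(data.frame(file = character(0), level = character(0),
                      message = character(0)))
  }
  do.call(rbind, out)
}

#' Run the full screening funnel
#'
#' Executes screen -> intersect -> topology -> enrich -> assemble in order,
#' writing every stage output (TSV/JSON) under `cfg$outdir` and returning a
#' funnel report. Empty intermediate sets produce warnings and empty
#' downstream outputs rather than failure.
#'
#' @param cfg A `pipeline_config`.
#' @return A `funnel_report` list of per-stage counts plus the paths of the
#'   written outputs.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  warn <- function(msg) {
    warnings_log <<- c(warnings_log, msg)
    warning(msg, call. = FALSE)
  }

  ## stage 1: drug-likeness screen
  lib <- read_compound_table(cfg$compounds)
  lib <- qed_score_library(lib, weights = cfg$qed_weights)
  scr <- screen_compounds(lib, qed_cutoff = cfg$qed_cutoff,
                          require_ob = cfg$require_ob)
  passed <- scr$passed
  utils::write.table(passed, file.path(cfg$outdir, "screened_compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(passed) == 0L) warn("no compound passed the drug-likeness screen")

  ## stage 2: target intersection + relevance filter
  preds <- read_prediction_table(cfg$predictions)
  preds <- preds[preds$compound_id %in% passed$compound_id, , drop = FALSE]
  disease <- read_disease_table(cfg$disease)
  venn <- intersect_targets(preds$symbol, disease)
  jsonlite::write_json(
    list(predicted = unname(venn$counts[["predicted"]]),
         disease = unname(venn$counts[["disease"]]),
         common = unname(venn$counts[["common"]])),
    file.path(cfg$outdir, "venn_summary.json"), auto_unbox = TRUE
  )
  potential <- filter_by_relevance(venn, cfg$relevance_min)
  utils::write.table(potential, file.path(cfg$outdir, "potential_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(potential) == 0L) warn("no potential target after relevance filter")

  ## stage 3: PPI topology
  g <- load_ppi(cfg$ppi, score_min = cfg$score_min)
  g <- igraph::induced_subgraph(
    g, igraph::V(g)[igraph::V(g)$name %in% potential$symbol]
  )
  cent <- ppi_centralities(g)
  key_targets <- filter_key_targets(cent, deg_min = cfg$deg_min,
                                    bc_min = cfg$bc_min, cc_min = cfg$cc_min)
  cent$passed_filter <- cent$symbol %in% key_targets
  utils::write.table(cent, file.path(cfg$outdir, "centrality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(key_targets, file.path(cfg$outdir, "key_targets.txt"))
  if (length(key_targets) == 0L) warn("no key target passed the topological filter")

  ## stage 4: enrichment
  collection <- read_gmt(cfg$gmt)
  enr <- if (length(key_targets)) {
    enrich(key_targets, collection, p_max = cfg$p_max, adjust = cfg$adjust)
  } else {
    enrich(character(0), collection, p_max = cfg$p_max, adjust = cfg$adjust)
  }
  top <- top_pathways(enr, cfg$top_pathways)
  utils::write.table(enr, file.path(cfg$outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(enr) == 0L) warn("no enriched pathway at the configured threshold")

  ## stage 5: C-T-P assembly
  ct_edges <- unique(preds[preds$symbol %in% key_targets,
                           c("compound_id", "symbol"), drop = FALSE])
  tp_edges <- if (nrow(top)) {
    do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
      mem <- intersect(strsplit(top$genes[i], ";", fixed = TRUE)[[1]],
                       key_targets)
      if (!length(mem)) return(NULL)
      data.frame(symbol = mem, term_id = top$term_id[i],
                 stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  if (is.null(tp_edges)) {
    tp_edges <- data.frame(symbol = character(0), term_id = character(0))
  }
  net <- assemble_ctp(ct_edges, tp_edges, key_targets,
                      roster = list(compounds = passed$compound_id,
                                    targets = key_targets,
                                    pathways = top$term_id))
  export_cytoscape(net, file.path(cfg$outdir, "ctp_nodes.tsv"),
                   file.path(cfg$outdir, "ctp_edges.tsv"))
  ranks <- rank_compounds(net)
  utils::write.table(ranks, file.path(cfg$outdir, "compound_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  key_compounds <- if (cfg$compound_rule == "top_k") {
    select_key_compounds(ranks, top_k = cfg$compound_rule_value)
  } else {
    select_key_compounds(ranks, degree_min = cfg$compound_rule_value)
  }
  counts <- ctp_counts(net)

  report <- list(
    compounds_scored = unname(scr$funnel[["n_input"]]),
    compounds_passed = unname(scr$funnel[["n_pass"]]),
    compounds_deduped = unname(scr$funnel[["n_dedup"]]),
    predicted_targets = unname(venn$counts[["predicted"]]),
    disease_genes = unname(venn$counts[["disease"]]),
    common_targets = unname(venn$counts[["common"]]),
    potential_targets = nrow(potential),
    key_targets = length(key_targets),
    enriched_terms = nrow(enr),
    top_pathways = nrow(top),
    key_compounds = nrow(key_compounds),
    ctp_nodes = unname(counts[["nodes"]]),
    ctp_edges = unname(counts[["edges"]]),
    warnings = warnings_log
  )
  class(report) <- "funnel_report"
  jsonlite::write_json(unclass(report),
                       file.path(cfg$outdir, "funnel_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}
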