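# Pareto location parameter for disease relevance scores. GeneCards-style
# relevance is heavy-tailed and positive; with xm = 3 and tail index alpha,
# P(score >= 9) = (1/3)^alpha, so alpha = 0.834 puts ~40% of disease genes
# above the conventional cut of 9.
.RELEVANCE_XM <- 3

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob the generators use. The same seed always yields
#' byte-identical output files.
#'
#' @param seed Integer RNG seed.
#' @param n_herbs Number of herbs in the formula.
#' @param compounds_per_herb Library rows per herb (pre-dedup).
#' @param duplicate_rate Fraction of rows that are cross-herb duplicates of
#'   an earlier compound.
#' @param n_targets_universe Size of the gene universe.
#' @param predictions_per_compound Poisson mean of per-compound predicted
#'   target counts.
#' @param n_disease_genes Disease-gene table size.
#' @param relevance_shape Pareto tail index of the relevance scores
#'   (default 0.834: about 40% of scores reach 9).
#' @param ppi_density Erdos-Renyi edge probability among non-hub proteins.
#' @param n_planted_hubs Number of hub proteins planted in the PPI graph.
#' @param hub_degree_boost Spoke edges per planted hub (hubs additionally
#'   form a clique, so hub degree is exactly
#'   `n_planted_hubs - 1 + hub_degree_boost`).
#' @param n_pathways Number of annotation terms generated.
#' @param pathway_size_range Length-2 integer range of term sizes.
#' @param n_planted_enriched_terms Terms seeded with the key genes.
#' @param planted_overlap Fraction of the key genes inserted into each
#'   planted term.
#' @param n_planted_common Disease genes forced into the predictions (0
#'   disables planting and lets the intersection fall where it may).
#' @param n_planted_potential Of the planted common genes, how many get a
#'   relevance score >= 9.
#' @param total_rows Override for the total library row count (default
#'   `n_herbs * compounds_per_herb`).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_herbs = 10L,
                         compounds_per_herb = 50L,
                         duplicate_rate = 0.15,
                         n_targets_universe = 500L,
                         predictions_per_compound = 8,
                         n_disease_genes = 60L,
                         relevance_shape = 0.834,
                         ppi_density = 0.08,
                         n_planted_hubs = 9L,
                         hub_degree_boost = 6L,
                         n_pathways = 40L,
                         pathway_size_range = c(10L, 60L),
                         n_planted_enriched_terms = 3L,
                         planted_overlap = 1.0,
                         n_planted_common = 0L,
                         n_planted_potential = 0L,
                         total_rows = NULL) {
  cfg <- list(
    seed = as.integer(seed), n_herbs = as.integer(n_herbs),
    compounds_per_herb = as.integer(compounds_per_herb),
    duplicate_rate = duplicate_rate,
    n_targets_universe = as.integer(n_targets_universe),
    predictions_per_compound = predictions_per_compound,
    n_disease_genes = as.integer(n_disease_genes),
    relevance_shape = relevance_shape,
    ppi_density = ppi_density,
    n_planted_hubs = as.integer(n_planted_hubs),
    hub_degree_boost = as.integer(hub_degree_boost),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_planted_enriched_terms = as.integer(n_planted_enriched_terms),
    planted_overlap = planted_overlap,
    n_planted_common = as.integer(n_planted_common),
    n_planted_potential = as.integer(n_planted_potential),
    total_rows = if (is.null(total_rows)) {
      as.integer(n_herbs) * as.integer(compounds_per_herb)
    } else {
      as.integer(total_rows)
    }
  )
  with(cfg, {
    stopifnot(
      n_herbs >= 1, compounds_per_herb >= 0, total_rows >= 0,
      duplicate_rate >= 0, duplicate_rate <= 1,
      n_targets_universe >= 1, predictions_per_compound >= 0,
      n_disease_genes >= 0, n_disease_genes <= n_targets_universe,
      relevance_shape > 0, ppi_density >= 0, ppi_density <= 1,
      n_planted_hubs >= 0, hub_degree_boost >= 0,
      n_pathways >= 0, length(pathway_size_range) == 2,
      pathway_size_range[1] >= 1, pathway_size_range[2] >= pathway_size_range[1],
      n_planted_enriched_terms >= 0, n_planted_enriched_terms <= n_pathways,
      planted_overlap >= 0, planted_overlap <= 1,
      n_planted_common >= 0, n_planted_common <= n_disease_genes,
      n_planted_potential >= 0, n_planted_potential <= max(n_planted_common, 0)
    )
  })
  class(cfg) <- "synth_config"
  cfg
}

#' Preset emulating the study-scale funnel
#'
#' A configuration whose cardinalities mirror a ten-herb screen: 2,419
#' library rows, 196 disease genes, 52 planted common targets of which 22
#' reach relevance 9, a 22-node PPI layer with 9 planted hubs, and 40
#' annotation terms of which 20 are planted enriched so the C-T-P pathway
#' layer carries its full 20 nodes. Identities
#' are synthetic; only the shape is meaningful.
#'
#' @param seed Integer RNG seed.
#' @return A `synth_config`.
#' @export
synth_preset_study_scale <- function(seed = 1L) {
  synth_config(
    seed = seed, n_herbs = 10L, compounds_per_herb = 242L, total_rows = 2419L,
    duplicate_rate = 0.15, n_targets_universe = 1500L,
    predictions_per_compound = 10, n_disease_genes = 196L,
    relevance_shape = 0.834, ppi_density = 0.08,
    n_planted_hubs = 9L, hub_degree_boost = 6L,
    n_pathways = 40L, pathway_size_range = c(10L, 60L),
    n_planted_enriched_terms = 20L, planted_overlap = 1.0,
    n_planted_common = 52L, n_planted_potential = 22L
  )
}

#' Generate a multi-herb compound library
#'
#' Descriptors follow drug-like marginals: MW lognormal around 350 g/mol,
#' ALOGP normal(2.5, 1.5), hydrogen-bond counts and ring/rotor counts
#' Poisson, PSA gamma. The OB flag is Bernoulli conditioned on a
#' Lipinski+Veber pass (P = 0.9 after a pass, 0.15 otherwise). A
#' `duplicate_rate` fraction of rows re-lists an earlier compound under a
#' different herb, so deduplication is exercised.
#'
#' @param cfg A `synth_config`.
#' @return Compound table with one row per (compound, herb) listing.
#' @export
gen_library <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  total <- cfg$total_rows
  herbs <- sprintf("herb%02d", seq_len(cfg$n_herbs))
  if (total == 0L) {
    return(data.frame(compound_id = character(0), name = character(0),
                      herbs = character(0), mw = numeric(0), alogp = numeric(0),
                      hba = integer(0), hbd = integer(0), psa = numeric(0),
                      rotb = integer(0), arom = integer(0), alerts = integer(0),
                      ob = logical(0)))
  }
  n_dup <- floor(total * cfg$duplicate_rate)
  n_unique <- total - n_dup
  ids <- sprintf("cpd%05d", seq_len(n_unique))
  desc <- data.frame(
    compound_id = ids,
    name = sprintf("synthetic compound %05d", seq_len(n_unique)),
    mw = stats::rlnorm(n_unique, log(350), 0.4),
    alogp = stats::rnorm(n_unique, 2.5, 1.5),
    hba = stats::rpois(n_unique, 4),
    hbd = stats::rpois(n_unique, 2),
    psa = stats::rgamma(n_unique, shape = 3, scale = 25),
    rotb = stats::rpois(n_unique, 4),
    arom = stats::rpois(n_unique, 1.5),
    alerts = stats::rpois(n_unique, 0.5),
    stringsAsFactors = FALSE
  )
  lipinski <- desc$mw <= 500 & desc$alogp <= 5 & desc$hbd <= 5 & desc$hba <= 10
  veber <- desc$rotb <= 10 & desc$psa <= 140
  desc$ob <- stats::runif(n_unique) < ifelse(lipinski & veber, 0.9, 0.15)
  desc$herb <- sample(herbs, n_unique, replace = TRUE)
  dup_rows <- NULL
  if (n_dup > 0L && cfg$n_herbs > 1L) {
    src <- sample.int(n_unique, n_dup, replace = TRUE)
    dup_rows <- desc[src, , drop = FALSE]
    dup_rows$herb <- vapply(desc$herb[src], function(h) {
      sample(setdiff(herbs, h), 1L)
    }, character(1))
  }
  lib <- rbind(desc, dup_rows)
  names(lib)[names(lib) == "herb"] <- "herbs"
  lib <- lib[order(lib$herbs, lib$compound_id), , drop = FALSE]
  rownames(lib) <- NULL
  lib[, c("compound_id", "name", "herbs", "mw", "alogp", "hba", "hbd",
          "psa", "rotb", "arom", "alerts", "ob")]
}

# Pareto(xm, alpha) sampler via inverse CDF.
.rpareto <- function(n, xm, alpha) xm * stats::runif(n)^(-1 / alpha)

#' Generate compound-target predictions and a disease-gene table
#'
#' Per-compound predicted-target lists are Poisson-sized draws from the gene
#' universe; disease relevance scores are Pareto-tailed so a relevance cut
#' at 9 retains a tunable fraction. When `n_planted_common > 0`, exactly
#' those disease genes appear among the predictions (other disease genes are
#' excluded from the prediction pool), and exactly `n_planted_potential` of
#' them score >= 9 — giving the downstream intersection and relevance filter
#' a known ground truth.
#'
#' @param cfg A `synth_config`.
#' @param compound_ids Compound ids to predict for (default: the deduplicated
#'   ids of [gen_library()] under the same config).
#' @return List: `predictions` (compound_id, symbol,
#'   prediction_probability), `disease` (symbol, uniprot, relevance_score),
#'   `universe`, `planted_common`, `planted_potential`.
#' @export
gen_targets_and_disease <- function(cfg, compound_ids = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(compound_ids)) {
    compound_ids <- unique(gen_library(cfg)$compound_id)
  }
  set.seed(cfg$seed + 1000L)
  universe <- sprintf("G%05d", seq_len(cfg$n_targets_universe))
  dis_sym <- sort(sample(universe, cfg$n_disease_genes))
  alpha <- cfg$relevance_shape
  relevance <- .rpareto(cfg$n_disease_genes, .RELEVANCE_XM, alpha)
  planted_common <- character(0)
  planted_potential <- character(0)
  if (cfg$n_planted_common > 0L) {
    planted_common <- sort(sample(dis_sym, cfg$n_planted_common))
    planted_potential <- sort(sample(planted_common, cfg$n_planted_potential))
    hi <- dis_sym %in% planted_potential
    lo <- dis_sym %in% setdiff(planted_common, planted_potential)
    # potential genes: Pareto re-based at 9 (always above the cut);
    # other planted common genes: uniform strictly below the cut
    relevance[hi] <- .rpareto(sum(hi), 9, alpha + 1)
    relevance[lo] <- stats::runif(sum(lo), .RELEVANCE_XM, 8.9)
  }
  disease <- data.frame(
    symbol = dis_sym,
    uniprot = sprintf("P%05d", match(dis_sym, universe)),
    relevance_score = round(relevance, 2),
    stringsAsFactors = FALSE
  )
  pool <- if (cfg$n_planted_common > 0L) {
    setdiff(universe, setdiff(dis_sym, planted_common))
  } else {
    universe
  }
  preds <- lapply(compound_ids, function(id) {
    k <- min(stats::rpois(1L, cfg$predictions_per_compound), length(pool))
    if (k == 0L) return(NULL)
    data.frame(compound_id = id, symbol = sample(pool, k),
               stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds[!vapply(preds, is.null, logical(1))])
  if (is.null(preds)) {
    preds <- data.frame(compound_id = character(0), symbol = character(0))
  }
  # guarantee every planted common gene is predicted at least once
  if (length(planted_common) && length(compound_ids)) {
    missing_genes <- setdiff(planted_common, preds$symbol)
    if (length(missing_genes)) {
      preds <- rbind(preds, data.frame(
        compound_id = sample(compound_ids, length(missing_genes), replace = TRUE),
        symbol = missing_genes, stringsAsFactors = FALSE
      ))
    }
  }
  preds <- unique(preds)
  preds <- preds[order(preds$compound_id, preds$symbol), , drop = FALSE]
  preds$prediction_probability <- round(stats::runif(nrow(preds), 0.3, 1), 3)
  rownames(preds) <- NULL
  list(predictions = preds, disease = disease, universe = universe,
       planted_common = planted_common, planted_potential = planted_potential)
}

#' Generate a PPI edge table with planted hubs
#'
#' Background interactions are Erdos-Renyi among non-hub proteins at
#' `ppi_density`; the `n_planted_hubs` hubs form a clique and each gains
#' `hub_degree_boost` spoke edges to distinct non-hubs, so every hub has
#' degree exactly `n_planted_hubs - 1 + hub_degree_boost` while background
#' degrees stay low. Combined scores are uniform integers in [700, 999].
#'
#' @param cfg A `synth_config`.
#' @param genes Node symbols (e.g. the potential-target set).
#' @return List: `edges` (protein1, protein2, combined_score), `hubs`
#'   (planted hub symbols).
#' @export
gen_ppi <- function(cfg, genes) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- unique(canonicalize_symbol(genes))
  set.seed(cfg$seed + 2000L)
  n <- length(genes)
  n_hubs <- min(cfg$n_planted_hubs, n)
  hubs <- if (n_hubs > 0L) sort(sample(genes, n_hubs)) else character(0)
  others <- setdiff(genes, hubs)
  e_from <- character(0); e_to <- character(0)
  if (n_hubs >= 2L) {
    cl <- utils::combn(hubs, 2L)
    e_from <- c(e_from, cl[1, ]); e_to <- c(e_to, cl[2, ])
  }
  if (n_hubs >= 1L && length(others) && cfg$hub_degree_boost > 0L) {
    for (h in hubs) {
      spokes <- sample(others, min(cfg$hub_degree_boost, length(others)))
      e_from <- c(e_from, rep(h, length(spokes))); e_to <- c(e_to, spokes)
    }
  }
  if (length(others) >= 2L && cfg$ppi_density > 0) {
    bg <- utils::combn(others, 2L)
    on <- stats::runif(ncol(bg)) < cfg$ppi_density
    e_from <- c(e_from, bg[1, on]); e_to <- c(e_to, bg[2, on])
  }
  if (length(e_from)) {
    lo <- pmin(e_from, e_to); hi <- pmax(e_from, e_to)
    keep <- !duplicated(paste(lo, hi))
    edges <- data.frame(
      protein1 = lo[keep], protein2 = hi[keep],
      combined_score = sample(700:999, sum(keep), replace = TRUE),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(protein1 = character(0), protein2 = character(0),
                        combined_score = integer(0))
  }
  list(edges = edges, hubs = hubs)
}

#' Generate an annotation collection with planted enriched terms
#'
#' Random terms of sizes drawn from `pathway_size_range`, members sampled
#' from the universe. The first `n_planted_enriched_terms` terms have a
#' `planted_overlap` fraction of the key genes inserted (term size is
#' preserved), so an over-representation test on the key genes must rank
#' them first.
#'
#' @param cfg A `synth_config`.
#' @param key_genes Genes to plant.
#' @param universe Gene universe the members are sampled from.
#' @return List: `collection` (a `gene_set_collection`), `planted_terms`
#'   (term ids).
#' @export
gen_pathways <- function(cfg, key_genes, universe) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 3000L)
  key_genes <- unique(canonicalize_symbol(key_genes))
  universe <- unique(canonicalize_symbol(universe))
  if (cfg$n_pathways == 0L) {
    sets <- list()
    class(sets) <- "gene_set_collection"
    return(list(collection = sets, planted_terms = character(0)))
  }
  cats <- c("GO-BP", "GO-MF", "GO-CC", "KEGG")
  ids <- sprintf("PWY%04d", seq_len(cfg$n_pathways))
  planted <- ids[seq_len(cfg$n_planted_enriched_terms)]
  sets <- lapply(seq_len(cfg$n_pathways), function(i) {
    size <- sample(cfg$pathway_size_range[1]:cfg$pathway_size_range[2], 1L)
    size <- min(size, length(universe))
    members <- sample(universe, size)
    if (ids[i] %in% planted && length(key_genes)) {
      n_in <- max(1L, round(cfg$planted_overlap * length(key_genes)))
      ins <- key_genes[seq_len(min(n_in, length(key_genes)))]
      members <- unique(c(ins, setdiff(members, key_genes)))
      members <- members[seq_len(min(length(members), max(size, length(ins))))]
    }
    list(term_id = ids[i], term_name = sprintf("synthetic pathway %04d", i),
         category = cats[(i - 1L) %% length(cats) + 1L],
         members = sort(members))
  })
  names(sets) <- ids
  class(sets) <- "gene_set_collection"
  list(collection = sets, planted_terms = planted)
}

#' Generate and write every pipeline input file
#'
#' Runs the four generators coherently (the PPI layer is built over the
#' genes that survive the intersection and relevance filter of the generated
#' tables; pathway terms are planted with the planted hubs) and writes the
#' exact file formats the pipeline readers consume.
#'
#' @param cfg A `synth_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the ground `truth`
#'   (planted common/potential genes, hubs, planted terms).
#' @export
write_synthetic_inputs <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lib <- gen_library(cfg)
  td <- gen_targets_and_disease(cfg, compound_ids = unique(lib$compound_id))
  venn <- intersect_targets(td$predictions$symbol, td$disease)
  potential <- filter_by_relevance(venn, 9)$symbol
  ppi <- gen_ppi(cfg, potential)
  pw <- gen_pathways(cfg, key_genes = ppi$hubs, universe = td$universe)
  paths <- list(
    compounds = file.path(outdir, "compounds.csv"),
    predictions = file.path(outdir, "predictions.tsv"),
    disease = file.path(outdir, "disease_genes.tsv"),
    ppi = file.path(outdir, "ppi_edges.tsv"),
    gmt = file.path(outdir, "pathways.gmt")
  )
  utils::write.csv(lib, paths$compounds, row.names = FALSE, quote = FALSE)
  utils::write.table(td$predictions, paths$predictions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(td$disease, paths$disease, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ppi$edges, paths$ppi, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(pw$collection, paths$gmt)
  invisible(list(
    paths = paths,
    truth = list(planted_common = td$planted_common,
                 planted_potential = td$planted_potential,
                 hubs = ppi$hubs, planted_terms = pw$planted_terms,
                 universe = td$universe)
  ))
}
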