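#' Load a STRING-dialect protein interaction edge table
#'
#' Reads (or accepts) a table with columns `protein1`, `protein2`,
#' `combined_score` (integer 0-1000), keeps edges with
#' `combined_score >= score_min`, drops self-loops with a warning, and
#' collapses duplicate unordered pairs to a single edge carrying the maximum
#' score.
#'
#' @param x Path to a TSV file or a data.frame.
#' @param score_min Inclusive confidence threshold on the 0-1000 scale
#'   (default 700, the conventional "high confidence" setting).
#' @return An undirected `igraph` graph with edge attribute
#'   `combined_score`; nodes are canonicalized gene symbols.
#' @export
load_ppi <- function(x, score_min = 700) {
  edges <- if (is.character(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    x
  }
  req <- c("protein1", "protein2", "combined_score")
  if (!all(req %in% names(edges))) {
    stop("PPI table needs columns: ", paste(req, collapse = ", "))
  }
  bad <- which(is.na(edges$protein1) | is.na(edges$protein2) |
                 !nzchar(edges$protein1) | !nzchar(edges$protein2) |
                 is.na(suppressWarnings(as.numeric(edges$combined_score))))
  if (length(bad)) {
    stop("malformed PPI row(s) at line(s): ", paste(bad + 1L, collapse = ", "))
  }
  score <- as.numeric(edges$combined_score)
  if (any(score < 0 | score > 1000)) {
    stop("combined_score out of range [0, 1000] at line(s): ",
         paste(which(score < 0 | score > 1000) + 1L, collapse = ", "))
  }
  a <- canonicalize_symbol(edges$protein1)
  b <- canonicalize_symbol(edges$protein2)
  self <- a == b
  if (any(self)) {
    warning("dropping ", sum(self), " self-loop edge(s)")
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }
  keep <- score >= score_min
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  # unordered pair key; keep max score among duplicates
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key)) {
    agg <- tapply(score, key, max)
    pairs <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs[, 1], to = pairs[, 2],
                 combined_score = as.numeric(agg), stringsAsFactors = FALSE),
      directed = FALSE
    )
  } else {
    g <- igraph::make_empty_graph(directed = FALSE)
  }
  g
}

#' Topological centralities of a PPI graph
#'
#' Degree, shortest-path betweenness and closeness on unit-length edges
#' (edge confidences are ignored for path lengths, the usual convention for
#' STRING-style topological screens).
#'
#' Betweenness is pair-count normalized: the raw Brandes value divided by
#' `(n-1)(n-2)/2` (endpoints excluded), so thresholds like 0.001 are
#' comparable across graph sizes. Closeness is computed per connected
#' component as `(n_c - 1) / sum(d)` and scaled by the Wasserman-Faust factor
#' `(n_c - 1) / (n - 1)` so disconnected graphs are handled gracefully;
#' isolated nodes get closeness and betweenness 0.
#'
#' @param g An `igraph` graph (or a data.frame/path accepted by
#'   [load_ppi()], loaded with `score_min = 0`).
#' @return data.frame `symbol, degree, betweenness, closeness`, ordered by
#'   degree descending then symbol.
#' @export
ppi_centralities <- function(g) {
  if (!igraph::is_igraph(g)) g <- load_ppi(g, score_min = 0)
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(data.frame(symbol = character(0), degree = integer(0),
                      betweenness = numeric(0), closeness = numeric(0)))
  }
  sym <- igraph::V(g)$name
  if (is.null(sym)) sym <- as.character(seq_len(n))
  deg <- igraph::degree(g, loops = FALSE)
  btw <- if (n > 2L) {
    igraph::betweenness(g, directed = FALSE, weights = NA) / ((n - 1) * (n - 2) / 2)
  } else {
    rep(0, n)
  }
  # closeness with Wasserman-Faust component scaling
  comp <- igraph::components(g)
  d <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(n), function(i) {
    nc <- comp$csize[comp$membership[i]]
    if (nc <= 1L || n == 1L) return(0)
    di <- d[i, comp$membership == comp$membership[i]]
    sumd <- sum(di[is.finite(di)])  # excludes self (0) harmlessly
    ((nc - 1) / sumd) * ((nc - 1) / (n - 1))
  }, numeric(1))
  out <- data.frame(symbol = sym, degree = as.integer(deg),
                    betweenness = as.numeric(btw), closeness = clo,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select key targets by the triple topological criterion
#'
#' Retains nodes satisfying all three inclusive thresholds simultaneously:
#' `degree >= deg_min`, `betweenness >= bc_min`, `closeness >= cc_min`.
#' Defaults are the conventional screen settings (10, 0.001, 0.6); note that
#' the meaningful degree scale depends on the graph in hand, so the
#' thresholds are parameters, not constants.
#'
#' @param records Centrality table from [ppi_centralities()].
#' @param deg_min,bc_min,cc_min Inclusive thresholds (non-negative).
#' @return Character vector of symbols, ordered by degree descending then
#'   symbol.
#' @export
filter_key_targets <- function(records, deg_min = 10, bc_min = 0.001, cc_min = 0.6) {
  if (any(c(deg_min, bc_min, cc_min) < 0)) stop("thresholds must be non-negative")
  stopifnot(all(c("symbol", "degree", "betweenness", "closeness") %in% names(records)))
  keep <- records$degree >= deg_min &
    records$betweenness >= bc_min &
    records$closeness >= cc_min
  sel <- records[keep, , drop = FALSE]
  sel <- sel[order(-sel$degree, sel$symbol), , drop = FALSE]
  sel$symbol
}
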