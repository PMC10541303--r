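#' Read a GMT gene-set collection
#'
#' GMT is the tab-delimited convention: one set per line,
#' `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. A category label
#' (GO-BP / GO-MF / GO-CC / KEGG-like) may be embedded in the description as
#' a `category|description` prefix; it is split out when present.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list of records with `term_id`,
#'   `term_name`, `category`, `members` (canonical symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has a term but no genes: ", sQuote(lines[i]))
    }
    desc <- f[2]
    category <- NA_character_
    if (grepl("|", desc, fixed = TRUE)) {
      parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
      category <- parts[1]
      desc <- paste(parts[-1], collapse = "|")
    }
    list(term_id = f[1], term_name = desc, category = category,
         members = unique(canonicalize_symbol(f[-(1:2)])))
  })
  ids <- vapply(sets, `[[`, "", "term_id")
  if (anyDuplicated(ids)) {
    stop("duplicate term_id in GMT: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(sets) <- ids
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection to GMT
#' @param sets A `gene_set_collection` (or compatible list).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    desc <- if (!is.na(s$category) && nzchar(s$category)) {
      paste0(s$category, "|", s$term_name)
    } else {
      s$term_name
    }
    paste(c(s$term_id, desc, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated genes in a size-`n` query drawn from a
#' universe of `N` genes of which `K` carry the annotation. Delegates to
#' `stats::phyper`, which works on log scale internally.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_p(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (K > N || n > N || k > min(K, n) || k < 0 || K < 0 || n < 0 || N < 1) {
    stop("impossible hypergeometric configuration (need 0 <= k <= min(K, n) <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, stable under
#' permutation of the input order (delegates to `stats::p.adjust`).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for enrichment of the query genes against a
#' gene universe. Terms are intersected with the universe before testing;
#' query genes outside the universe are dropped (their count is attached as
#' attribute `n_dropped` and reported via a warning). Terms with zero
#' overlap never appear in the result.
#'
#' @param query Character vector of gene symbols.
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param universe Character vector of background genes; default is the
#'   union of all collection members.
#' @param p_max Retain terms with p <= p_max (default 0.05); applied to the
#'   q-value instead when `adjust = "BH"`.
#' @param adjust `"none"` (raw p filter, the default) or `"BH"`.
#' @return data.frame sorted by ascending p then term_id with columns
#'   `term_id, term_name, category, k, K, n, N, p_value, q_value, genes`.
#' @export
enrich <- function(query, collection, universe = NULL,
                   p_max = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(collection, `[[`, "members")))
  }
  universe <- unique(canonicalize_symbol(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  query <- unique(canonicalize_symbol(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warning(length(dropped), " query gene(s) outside the universe dropped")
  }
  q <- intersect(query, universe)
  N <- length(universe)
  n <- length(q)
  rows <- lapply(collection, function(s) {
    mem <- intersect(s$members, universe)
    k <- length(intersect(q, mem))
    if (k == 0L) return(NULL)
    data.frame(
      term_id = s$term_id, term_name = s$term_name,
      category = s$category, k = k, K = length(mem), n = n, N = N,
      p_value = hypergeom_p(k, length(mem), n, N),
      genes = paste(sort(intersect(q, mem)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), genes = character(0))
    attr(out, "n_dropped") <- length(dropped)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  crit <- if (adjust == "BH") out$q_value else out$p_value
  out <- out[crit <= p_max, , drop = FALSE]
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  out <- out[, c("term_id", "term_name", "category", "k", "K", "n", "N",
                 "p_value", "q_value", "genes")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(dropped)
  out
}

#' Top pathways by significance
#'
#' Ascending p with term_id tie-break (the order [enrich()] already
#' returns); used to pick the pathway layer of the compound-target-pathway
#' network.
#'
#' @param results Enrichment table from [enrich()].
#' @param top Number of terms to keep (default 20).
#' @return The first `top` rows.
#' @export
top_pathways <- function(results, top = 20) {
  if (top <= 0) stop("top must be positive")
  utils::head(results[order(results$p_value, results$term_id), , drop = FALSE], top)
}
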