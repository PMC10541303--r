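#' Canonicalize gene symbols
#'
#' Upper-cases and trims HGNC-style symbols; idempotent by construction.
#'
#' @param x Character vector of symbols.
#' @return Canonical symbols.
#' @export
canonicalize_symbol <- function(x) {
  toupper(gsub("[[:space:]]+", "", trimws(as.character(x))))
}

#' Intersect predicted compound targets with disease-associated genes
#'
#' Computes the three-way partition (predicted only / disease only / common)
#' by exact symbol intersection. Relevance scores travel with the disease
#' side; duplicate disease symbols carrying different relevance scores are an
#' input error.
#'
#' @param predicted Character vector of predicted target symbols (duplicates
#'   allowed; collapsed).
#' @param disease data.frame with columns `symbol` and `relevance_score`
#'   (optional `uniprot`).
#' @return List of class `venn_result`: `only_predicted`, `only_disease`,
#'   `common` (data.frame with relevance scores), and `counts`.
#' @export
intersect_targets <- function(predicted, disease) {
  stopifnot(is.data.frame(disease), all(c("symbol", "relevance_score") %in% names(disease)))
  pred <- unique(canonicalize_symbol(predicted))
  dis <- disease
  dis$symbol <- canonicalize_symbol(dis$symbol)
  if (any(!is.na(dis$relevance_score) & dis$relevance_score < 0)) {
    stop("negative relevance scores in disease gene table")
  }
  dup <- unique(dis$symbol[duplicated(dis$symbol)])
  for (s in dup) {
    sc <- unique(dis$relevance_score[dis$symbol == s])
    if (length(sc) > 1L) {
      stop("conflicting relevance scores for disease gene ", sQuote(s))
    }
  }
  dis <- dis[!duplicated(dis$symbol), , drop = FALSE]
  common_sym <- sort(intersect(pred, dis$symbol))
  common <- dis[match(common_sym, dis$symbol), , drop = FALSE]
  rownames(common) <- NULL
  res <- list(
    only_predicted = sort(setdiff(pred, dis$symbol)),
    only_disease = sort(setdiff(dis$symbol, pred)),
    common = common,
    counts = c(
      predicted = length(pred), disease = nrow(dis),
      only_predicted = length(setdiff(pred, dis$symbol)),
      only_disease = length(setdiff(dis$symbol, pred)),
      common = length(common_sym)
    )
  )
  class(res) <- "venn_result"
  res
}

#' Filter common targets by disease relevance score
#'
#' Keeps common genes with `relevance_score >= min_score` (inclusive), the
#' potential-target selection step. Output is sorted by score descending,
#' ties broken by symbol.
#'
#' @param venn A `venn_result` from [intersect_targets()], or a data.frame
#'   with `symbol` and `relevance_score`.
#' @param min_score Inclusive threshold (default 9).
#' @return data.frame of retained target genes.
#' @export
filter_by_relevance <- function(venn, min_score = 9) {
  common <- if (inherits(venn, "venn_result")) venn$common else venn
  stopifnot(all(c("symbol", "relevance_score") %in% names(common)))
  if (nrow(common) == 0L) return(common)
  if (anyNA(common$relevance_score)) {
    bad <- common$symbol[is.na(common$relevance_score)]
    stop("missing relevance score for gene(s): ", paste(bad, collapse = ", "))
  }
  keep <- common[common$relevance_score >= min_score, , drop = FALSE]
  keep <- keep[order(-keep$relevance_score, keep$symbol), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
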