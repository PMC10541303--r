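#' QED constants
#'
#' `QED_ADS_PARAMS`: coefficients of the asymmetric double sigmoidal (ADS)
#' desirability function, one set per descriptor, from the QED method
#' publication (Bickerton et al., Nat. Chem. 4:90-98, 2012); `dmax` is the
#' global maximum of the unnormalized ADS, so `d(x) = ADS(x)/dmax` lies in
#' (0, 1]. `QED_DESCRIPTORS`: the descriptor order used throughout.
#' `QED_WEIGHTS`: the selectable weight schemes (`unweighted` and the
#' published optimal-information set `mo`).
#'
#' @name qed-constants
#' @aliases QED_ADS_PARAMS QED_DESCRIPTORS QED_WEIGHTS
NULL

#' @rdname qed-constants
#' @export
QED_ADS_PARAMS <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 1e-09,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  ROTB   = c(a = 0.01, b = 272.4121427, c = 2.55837997, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  AROM   = c(a = 3.21778897, b = 957.7374108, c = 2.274627939, d = 1e-09,
             e = 1.317690384, f = 0.375760881, dmax = 312.337261),
  ALERTS = c(a = 0.01, b = 1199.094025, c = -0.09002883, d = 1e-09,
             e = 0.185904477, f = 0.875193782, dmax = 417.725314)
)

#' @rdname qed-constants
#' @export
QED_DESCRIPTORS <- names(QED_ADS_PARAMS)

#' @rdname qed-constants
#' @export
QED_WEIGHTS <- list(
  unweighted = stats::setNames(rep(1, 8), QED_DESCRIPTORS),
  mo = c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
         PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)
)

#' ADS desirability of one descriptor value
#'
#' Evaluates the asymmetric double sigmoidal desirability
#' `ADS(x) = a + b / (1 + exp(-(x - c + d/2)/e)) * (1 - 1/(1 + exp(-(x - c - d/2)/f)))`
#' normalized by its global maximum `dmax`, then clipped into `(0, 1]` so the
#' downstream log-geometric mean is always defined.
#'
#' @param x Numeric vector of descriptor values.
#' @param params Either a descriptor name (one of
#'   `"MW","ALOGP","HBA","HBD","PSA","ROTB","AROM","ALERTS"`) or a named
#'   numeric vector `c(a, b, c, d, e, f, dmax)`.
#' @return Desirabilities in `(0, 1]`, same length as `x`.
#' @examples
#' ads_desirability(300, "MW")
#' ads_desirability(0, "ALERTS")
#' @export
ads_desirability <- function(x, params) {
  if (is.character(params)) {
    params <- match.arg(params, QED_DESCRIPTORS)
    params <- QED_ADS_PARAMS[[params]]
  }
  stopifnot(all(c("a", "b", "c", "d", "e", "f", "dmax") %in% names(params)))
  if (params[["e"]] == 0 || params[["f"]] == 0 || params[["dmax"]] <= 0) {
    stop("degenerate ADS parameter set (e, f nonzero; dmax > 0 required)")
  }
  p <- as.list(params)
  ads <- p$a + p$b / (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
    (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))
  pmin(pmax(ads / p$dmax, 1e-12), 1)
}

#' Weighted geometric mean of desirabilities
#'
#' The QED aggregation core: `exp(sum(w * log(d)) / sum(w))` over
#' desirabilities in `(0, 1]`. Invariant to positive rescaling of the
#' weights and monotone in each desirability.
#'
#' @param d Numeric vector of desirabilities in (0, 1].
#' @param w Non-negative weights, same length, at least one positive.
#' @return The weighted geometric mean in (0, 1].
#' @export
qed_from_desirabilities <- function(d, w = rep(1, length(d))) {
  if (any(d <= 0) || any(d > 1)) stop("desirabilities must lie in (0, 1]")
  if (length(w) != length(d) || any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with at least one positive entry")
  }
  exp(sum(w * log(d)) / sum(w))
}

#' QED drug-likeness score
#'
#' Weighted geometric mean of the eight descriptor desirabilities:
#' `QED = exp(sum(w_i * log(d_i)) / sum(w_i))`. The default is the unweighted
#' variant; `weights = "mo"` selects the published optimal-information
#' weights. QED is invariant to rescaling all weights by a positive constant.
#'
#' @param descriptors Named numeric vector (or one-row data.frame /list) with
#'   entries `MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS` (case-insensitive
#'   names accepted).
#' @param weights `"unweighted"`, `"mo"`, or a named non-negative numeric
#'   vector over the eight descriptors with at least one positive entry.
#' @return QED score in `(0, 1]`.
#' @examples
#' qed_score(c(MW = 194.18, ALOGP = 1.5, HBA = 4, HBD = 2,
#'             PSA = 66.8, ROTB = 3, AROM = 1, ALERTS = 0))
#' @export
qed_score <- function(descriptors, weights = "unweighted") {
  v <- unlist(descriptors)
  names(v) <- toupper(names(v))
  missing_d <- setdiff(QED_DESCRIPTORS, names(v))
  if (length(missing_d)) {
    stop("missing descriptors: ", paste(missing_d, collapse = ", "))
  }
  if (is.character(weights)) weights <- QED_WEIGHTS[[match.arg(weights, names(QED_WEIGHTS))]]
  w <- weights[QED_DESCRIPTORS]
  if (anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop("weights must be named, non-negative, with at least one positive entry")
  }
  d <- vapply(QED_DESCRIPTORS, function(k) ads_desirability(v[[k]], k), numeric(1))
  qed_from_desirabilities(d, w)
}

#' Score every compound in a library table
#'
#' Adds a `qed` column computed from the descriptor columns
#' `mw, alogp, hba, hbd, psa, rotb, arom, alerts`.
#'
#' @param library Compound table (see [read_compound_table()]).
#' @inheritParams qed_score
#' @return `library` with a `qed` column.
#' @export
qed_score_library <- function(library, weights = "unweighted") {
  cols <- tolower(QED_DESCRIPTORS)
  missing_cols <- setdiff(cols, names(library))
  if (length(missing_cols)) {
    stop("library lacks descriptor columns: ", paste(missing_cols, collapse = ", "))
  }
  library$qed <- vapply(seq_len(nrow(library)), function(i) {
    qed_score(stats::setNames(as.numeric(library[i, cols]), QED_DESCRIPTORS),
              weights = weights)
  }, numeric(1))
  library
}

# Canonical identity used for deduplication: case-folded InChIKey when an
# `inchikey` column carries one, otherwise the compound_id, otherwise the
# normalized name.
canonical_compound_id <- function(library) {
  key <- rep(NA_character_, nrow(library))
  if ("inchikey" %in% names(library)) {
    ik <- as.character(library$inchikey)
    ok <- !is.na(ik) & nzchar(ik)
    key[ok] <- tolower(trimws(ik[ok]))
  }
  fallback <- if ("compound_id" %in% names(library)) {
    as.character(library$compound_id)
  } else {
    as.character(library$name)
  }
  fallback <- tolower(gsub("[[:space:]]+", " ", trimws(fallback)))
  key[is.na(key)] <- fallback[is.na(key)]
  key
}

#' Deduplicate a compound library across herbs
#'
#' The same chemical typically occurs in several herbs of a multi-herb
#' formula; this collapses to one record per canonical compound identity,
#' merging `herbs` as a sorted, semicolon-separated union. Conflicting
#' descriptor values under one identity are an input error.
#'
#' @param library Compound table.
#' @return Deduplicated table, ordered by canonical id.
#' @export
deduplicate <- function(library) {
  if (nrow(library) == 0L) return(library)
  key <- canonical_compound_id(library)
  desc_cols <- intersect(
    c(tolower(QED_DESCRIPTORS), "formula", "ob"), names(library)
  )
  pieces <- split(seq_len(nrow(library)), key)
  rows <- lapply(pieces, function(idx) {
    block <- library[idx, , drop = FALSE]
    for (cc in desc_cols) {
      vals <- unique(block[[cc]][!is.na(block[[cc]])])
      if (length(vals) > 1L) {
        stop("conflicting values of ", sQuote(cc), " for duplicated compound ",
             sQuote(key[idx[1]]))
      }
    }
    out <- block[1L, , drop = FALSE]
    if ("herbs" %in% names(block)) {
      herbs <- sort(unique(unlist(strsplit(block$herbs, ";", fixed = TRUE))))
      out$herbs <- paste(herbs, collapse = ";")
    }
    out
  })
  out <- do.call(rbind, rows[sort(names(rows))])
  rownames(out) <- NULL
  out
}

#' Screen a compound library for drug-likeness and oral bioavailability
#'
#' Applies the inclusive gates `qed >= qed_cutoff` and (optionally)
#' `ob == TRUE`, then deduplicates survivors across herbs, recording the
#' funnel counts at each step.
#'
#' @param library Compound table with `qed` (see [qed_score_library()]) and
#'   logical `ob` columns.
#' @param qed_cutoff Inclusive QED threshold (default 0.4).
#' @param require_ob Require the oral-bioavailability flag (default TRUE).
#' @return List with `passed` (deduplicated survivor table) and `funnel`
#'   (named counts: `n_input`, `n_pass`, `n_dedup`).
#' @export
screen_compounds <- function(library, qed_cutoff = 0.4, require_ob = TRUE) {
  if (!"qed" %in% names(library) || anyNA(library$qed)) {
    stop("library must be fully QED-scored before screening; see qed_score_library()")
  }
  keep <- library$qed >= qed_cutoff
  if (require_ob) {
    if (!"ob" %in% names(library)) stop("require_ob = TRUE but no `ob` column")
    keep <- keep & as.logical(library$ob) %in% TRUE
  }
  pass <- library[keep, , drop = FALSE]
  dedup <- deduplicate(pass)
  list(
    passed = dedup,
    funnel = c(n_input = nrow(library), n_pass = nrow(pass), n_dedup = nrow(dedup))
  )
}
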