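# Monoisotopic masses (Da) of the most abundant isotope of each supported
# element, CODATA/IUPAC values. C is exactly 12 by definition.
.MONOISOTOPIC <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  Na = 22.9897692809,
  Mg = 23.9850417,
  Si = 27.9769265325,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Se = 73.9224764,
  Br = 78.9183371,
  I  = 126.904473
)

# Proton mass (Da). Distinct from the hydrogen-atom mass: protonation adds a
# bare proton, i.e. H minus one electron.
.PROTON_MASS <- 1.00727646

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula string (e.g. `"C10H10O4"`) into a
#' named integer vector of element counts. Markup characters that appear in
#' typeset tables (underscores, carets, asterisks, whitespace) are stripped
#' first, so strings copied verbatim from publications (`"C_10_H_10_O_4_"`)
#' are accepted.
#'
#' @param text A single formula string.
#' @return A named integer vector (class `molecular_formula`), one entry per
#'   element, counts summed across repeated element tokens.
#' @examples
#' parse_formula("C10H10O4")
#' parse_formula("C_30_H_44_O_4_")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  clean <- gsub("[_^*[:space:]]", "", text)
  if (!nzchar(clean)) {
    stop("empty molecular formula: ", sQuote(text))
  }
  counts <- integer(0)
  pos <- 1L
  n <- nchar(clean)
  while (pos <= n) {
    m <- regmatches(
      substr(clean, pos, n),
      regexpr("^([A-Z][a-z]?)([0-9]*)", substr(clean, pos, n))
    )
    if (length(m) == 0L || !nzchar(m)) {
      stop(
        "malformed formula token at position ", pos, " in ", sQuote(clean),
        ": ", sQuote(substr(clean, pos, pos))
      )
    }
    elem <- sub("[0-9]*$", "", m)
    # two-letter symbols are greedy; back off if unknown but one-letter known
    if (!elem %in% names(.MONOISOTOPIC) && nchar(elem) == 2L &&
        substr(elem, 1L, 1L) %in% names(.MONOISOTOPIC)) {
      elem <- substr(elem, 1L, 1L)
      m <- regmatches(
        substr(clean, pos, n),
        regexpr(paste0("^", elem, "[0-9]*"), substr(clean, pos, n))
      )
    }
    if (!elem %in% names(.MONOISOTOPIC)) {
      stop(
        "unknown element ", sQuote(elem), " at position ", pos,
        " in ", sQuote(clean)
      )
    }
    cnt_str <- sub("^[A-Za-z]+", "", m)
    cnt <- if (nzchar(cnt_str)) as.integer(cnt_str) else 1L
    if (is.na(cnt) || cnt < 1L) {
      stop("invalid count for element ", sQuote(elem), " in ", sQuote(clean))
    }
    counts[elem] <- if (elem %in% names(counts)) counts[[elem]] + cnt else cnt
    pos <- pos + nchar(m)
  }
  structure(counts, class = "molecular_formula")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the exact mass of the element's most
#' abundant isotope, using the bundled CODATA/IUPAC table.
#'
#' @param f A formula string or the result of [parse_formula()].
#' @return Mass in Da (full precision; round for table display).
#' @examples
#' monoisotopic_mass("C30H44O4") # 468.3240
#' monoisotopic_mass("H2O")      # 18.01056
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molecular_formula") || (is.numeric(f) && !is.null(names(f))))
  sum(unclass(f) * .MONOISOTOPIC[names(f)])
}

#' Parse an ESI adduct label
#'
#' Understands the `(M+nH)n+` grammar with optional neutral losses in square
#' brackets, e.g. `"(M+H)+"`, `"(M+2H)2+"`, `"(M+H)+[-H2O]"`. Typeset markup
#' (carets, underscores, spaces) is tolerated, so `"(M+H)^+^ [-H_2_O]"`
#' parses identically to `"(M+H)+[-H2O]"`.
#'
#' @param label Adduct label string.
#' @return A list of class `adduct_spec` with `protons_added`,
#'   `neutral_losses` (list of parsed formulas), `charge`, and a canonical
#'   `label` rendering.
#' @export
parse_adduct <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  clean <- gsub("[_^[:space:]]", "", label)
  m <- regmatches(
    clean,
    regexec("^\\(M(\\+([0-9]*)H)?\\)([0-9]*)\\+((\\[-[A-Za-z0-9]+\\])*)$", clean)
  )[[1]]
  if (length(m) == 0L) {
    stop("unrecognized adduct label: ", sQuote(label),
         " (expected (M+nH)n+ with optional [-X] losses)")
  }
  protons <- if (!nzchar(m[2])) 0L else if (nzchar(m[3])) as.integer(m[3]) else 1L
  charge <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  if (charge < 1L) stop("adduct charge must be >= 1")
  losses <- list()
  if (nzchar(m[5])) {
    toks <- regmatches(m[5], gregexpr("\\[-([A-Za-z0-9]+)\\]", m[5]))[[1]]
    losses <- lapply(gsub("^\\[-|\\]$", "", toks), parse_formula)
  }
  canon <- paste0(
    "(M", if (protons > 0L) paste0("+", if (protons > 1L) protons, "H"), ")",
    if (charge > 1L) charge, "+",
    paste0(vapply(losses, function(l) paste0("[-", format_formula(l), "]"), ""),
           collapse = "")
  )
  structure(
    list(protons_added = protons, neutral_losses = losses,
         charge = charge, label = canon),
    class = "adduct_spec"
  )
}

#' Render a parsed formula back to Hill-style text
#' @param f A `molecular_formula`.
#' @return A single string, C then H then other elements alphabetically.
#' @export
format_formula <- function(f) {
  els <- names(f)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(unclass(f)[ord] > 1L, unclass(f)[ord], ""), collapse = "")
}

#' Theoretical m/z of an adduct
#'
#' `m/z = (M - sum(neutral loss masses) + protons_added * 1.00727646) / charge`.
#' The proton mass (not the hydrogen-atom mass) is used so the electron
#' removed on protonation is accounted for.
#'
#' @param M Neutral monoisotopic mass in Da.
#' @param adduct An `adduct_spec` or a label string.
#' @return m/z in Da per unit charge.
#' @examples
#' adduct_mz(468.32396, "(M+H)+")        # 469.33124
#' adduct_mz(194.05791, "(M+H)+[-H2O]")  # 177.05462
#' @export
adduct_mz <- function(M, adduct) {
  stopifnot(is.numeric(M), length(M) == 1L, M > 0)
  if (is.character(adduct)) adduct <- parse_adduct(adduct)
  stopifnot(inherits(adduct, "adduct_spec"))
  loss <- sum(vapply(adduct$neutral_losses, monoisotopic_mass, numeric(1)))
  mz <- (M - loss + adduct$protons_added * .PROTON_MASS) / adduct$charge
  if (mz <= 0) {
    stop("adduct arithmetic yields non-positive m/z (losses exceed M)")
  }
  mz
}

#' Signed mass error in parts per million
#'
#' `ppm = (measured - theoretical) / theoretical * 1e6`.
#'
#' @param theoretical Theoretical m/z in Da (> 0).
#' @param measured Measured m/z in Da.
#' @return Signed ppm error.
#' @export
ppm_error <- function(theoretical, measured) {
  stopifnot(is.numeric(theoretical), is.numeric(measured))
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (measured - theoretical) / theoretical * 1e6
}

#' Mass-identity table for observed ions
#'
#' For a table of compounds with formula, adduct label and measured m/z,
#' computes the neutral monoisotopic mass, the theoretical adduct m/z and the
#' signed ppm error.
#'
#' @param x data.frame with columns `name`, `formula`, `adduct`,
#'   `measured_mz`.
#' @param digits Decimal places for the rounded display columns (round
#'   half-to-even, the base R convention). Full-precision columns are kept.
#' @return `x` with columns `calculated_M`, `theoretical_mz`, `error_ppm`
#'   appended (full precision) plus rounded display counterparts.
#' @export
mass_table <- function(x, digits = 4L) {
  req <- c("name", "formula", "adduct", "measured_mz")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("mass_table input lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  M <- vapply(x$formula, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
  mz <- mapply(adduct_mz, M, x$adduct)
  ppm <- ppm_error(mz, x$measured_mz)
  out <- x
  out$calculated_M <- M
  out$theoretical_mz <- mz
  out$error_ppm <- ppm
  out$calculated_M_display <- round(M, digits)
  out$theoretical_mz_display <- round(mz, digits)
  out$error_ppm_display <- round(ppm, 2L)
  out
}
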