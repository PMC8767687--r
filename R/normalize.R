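#' Normalize a term label
#'
#' Canonical label normalization used throughout the package: Unicode canonical
#' composition (NFC) followed by stripping of leading/trailing whitespace,
#' including the ideographic space (U+3000). Internal characters, width, case
#' and punctuation are preserved, so two labels merge only when their notation
#' is identical. Optional width and case folding can be switched on for
#' exploratory runs but are off by default: terminology integration "by term
#' notation" treats e.g. a trailing ideographic full stop as significant.
#'
#' @param raw character vector of raw labels.
#' @param width_fold logical; if `TRUE`, fold fullwidth/halfwidth variants
#'   (via the ICU Halfwidth-Fullwidth transform) before comparison.
#' @param case_fold logical; if `TRUE`, lower-case the label.
#' @return character vector of normalized labels.
#' @examples
#' normalize_label(" fuse blown ")
#' normalize_label("　不明")  # leading ideographic space stripped
#' @export
normalize_label <- function(raw, width_fold = FALSE, case_fold = FALSE) {
  if (!is.character(raw)) stop("normalize_label: `raw` must be a character vector")
  x <- normalize_text(raw, width_fold = width_fold, case_fold = case_fold)
  bad <- !is.na(x) & !nzchar(x)
  if (any(bad)) {
    stop("normalize_label: label is empty after normalization (input: ",
         paste(sprintf("'%s'", raw[bad]), collapse = ", "), ")")
  }
  x
}

# Shared trim+NFC used for labels and definition text; empty results allowed.
normalize_text <- function(raw, width_fold = FALSE, case_fold = FALSE) {
  x <- stringi::stri_trans_nfc(raw)
  x <- stringi::stri_trim_both(x)
  if (width_fold) x <- stringi::stri_trans_general(x, "Halfwidth-Fullwidth")
  if (case_fold) x <- stringi::stri_trans_tolower(x)
  x
}

# Byte-order (code point) sort: locale-independent, deterministic.
sort_cp <- function(x) sort(x, method = "radix", na.last = TRUE)

order_cp <- function(...) order(..., method = "radix")
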