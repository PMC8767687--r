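#' Table dialect for terminology files
#'
#' Describes how a terminology table is laid out: the field separator, the
#' delimiter used inside the synonym and CDRH-NCIt cells, accepted header
#' names (Japanese or English), accepted problem-domain labels, and the
#' normalization flags passed to [normalize_label()]. The defaults match the
#' seven-column CSV layout of the JFMDA 1st-edition terminology after
#' spreadsheet conversion, with comma-delimited, double-quote-escaped lists
#' inside cells.
#'
#' @param field_sep single character separating table fields ("," or "\t").
#' @param cell_sep single character separating items inside the synonym and
#'   CDRH-NCIt cells; items containing the separator are protected by
#'   double quotes (doubled quotes escape a literal quote).
#' @param header_map named list mapping each canonical field name
#'   (`terminology_id`, `problem_domain`, `category_term`, `preferred_term`,
#'   `synonyms`, `definition`, `cdrh_ncit`) to a character vector of accepted
#'   header spellings. Matching is case-insensitive after trimming.
#' @param domain_map named list with elements `device` and `patient`, each a
#'   character vector of accepted cell values for the problem-domain column.
#' @param width_fold,case_fold normalization flags, see [normalize_label()].
#' @return an object of class `table_dialect`.
#' @seealso [read_dialect()] to load a dialect from a YAML file.
#' @export
table_dialect <- function(field_sep = ",",
                          cell_sep = ",",
                          header_map = default_header_map(),
                          domain_map = default_domain_map(),
                          width_fold = FALSE,
                          case_fold = FALSE) {
  stopifnot(nchar(field_sep) == 1L, nchar(cell_sep) == 1L)
  need <- c("terminology_id", "problem_domain", "category_term",
            "preferred_term", "synonyms", "definition", "cdrh_ncit")
  missing_fields <- setdiff(need, names(header_map))
  if (length(missing_fields)) {
    stop("table_dialect: header_map lacks fields: ",
         paste(missing_fields, collapse = ", "))
  }
  structure(
    list(field_sep = field_sep, cell_sep = cell_sep,
         header_map = header_map, domain_map = domain_map,
         width_fold = isTRUE(width_fold), case_fold = isTRUE(case_fold)),
    class = "table_dialect"
  )
}

#' @rdname table_dialect
#' @export
default_header_map <- function() {
  list(
    terminology_id = c("terminology_id", "terminology ID", "用語集ID", "ID"),
    problem_domain = c("problem_domain", "medical device problems/patient problems",
                       "不具合/健康被害", "区分"),
    category_term  = c("category_term", "category terms", "category term",
                       "カテゴリー用語", "分類語"),
    preferred_term = c("preferred_term", "preferred terms", "preferred term",
                       "基本用語", "推奨用語"),
    synonyms       = c("synonyms", "同義語", "類義語"),
    definition     = c("definition", "definitions", "定義"),
    cdrh_ncit      = c("cdrh_ncit", "CDRH-NCIt", "CDRH-NCIt用語")
  )
}

#' @rdname table_dialect
#' @export
default_domain_map <- function() {
  list(
    device  = c("device", "medical device problem", "medical device problems",
                "医療機器不具合", "不具合"),
    patient = c("patient", "patient problem", "patient problems",
                "健康被害",
                "患者への健康被害")
  )
}

#' Read a table dialect from a YAML file
#'
#' Keys mirror the arguments of [table_dialect()]; absent keys fall back to
#' the defaults, so a dialect file only needs to state what differs.
#'
#' @param path path to a YAML file.
#' @return a `table_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- table_dialect()
  hm <- base$header_map
  if (!is.null(cfg$header_map)) {
    for (nm in names(cfg$header_map)) hm[[nm]] <- as.character(cfg$header_map[[nm]])
  }
  dm <- base$domain_map
  if (!is.null(cfg$domain_map)) {
    for (nm in names(cfg$domain_map)) dm[[nm]] <- as.character(cfg$domain_map[[nm]])
  }
  table_dialect(
    field_sep = cfg$field_sep %||% base$field_sep,
    cell_sep = cfg$cell_sep %||% base$cell_sep,
    header_map = hm, domain_map = dm,
    width_fold = cfg$width_fold %||% FALSE,
    case_fold = cfg$case_fold %||% FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve actual header names to canonical field names; errors name the
# missing canonical column.
match_headers <- function(headers, dialect) {
  canon <- names(dialect$header_map)
  norm <- tolower(stringi::stri_trim_both(headers))
  out <- stats::setNames(rep(NA_integer_, length(canon)), canon)
  for (field in canon) {
    aliases <- tolower(stringi::stri_trim_both(dialect$header_map[[field]]))
    hit <- which(norm %in% aliases)
    if (length(hit)) out[[field]] <- hit[1L]
  }
  missing_cols <- canon[is.na(out)]
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out
}

parse_domain <- function(values, dialect, rows) {
  v <- tolower(stringi::stri_trim_both(values))
  dev <- tolower(stringi::stri_trim_both(dialect$domain_map$device))
  pat <- tolower(stringi::stri_trim_both(dialect$domain_map$patient))
  out <- ifelse(v %in% dev, "device", ifelse(v %in% pat, "patient", NA_character_))
  if (anyNA(out)) {
    bad <- rows[which(is.na(out))[1L]]
    stop(sprintf("unparseable problem-domain value '%s' at row %d",
                 values[is.na(out)][1L], bad), call. = FALSE)
  }
  out
}

# Split one synonym / CDRH-NCIt cell into items, honoring double-quoted items
# that contain the delimiter (quotes doubled to escape).
split_cell <- function(cell, sep) {
  if (is.na(cell) || !nzchar(stringi::stri_trim_both(cell))) return(character())
  chars <- strsplit(cell, "", fixed = TRUE)[[1]]
  items <- character()
  buf <- character()
  in_q <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == '"') {
      if (in_q && i < n && chars[i + 1L] == '"') { # escaped quote
        buf <- c(buf, '"'); i <- i + 1L
      } else {
        in_q <- !in_q
      }
    } else if (ch == sep && !in_q) {
      items <- c(items, paste(buf, collapse = "")); buf <- character()
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  items <- c(items, paste(buf, collapse = ""))
  items <- stringi::stri_trim_both(items)
  items[nzchar(items)]
}

# Inverse of split_cell: quote items containing the separator or a quote.
join_cell <- function(items, sep) {
  if (!length(items)) return("")
  needs_quote <- grepl(sep, items, fixed = TRUE) | grepl('"', items, fixed = TRUE)
  items[needs_quote] <- paste0('"', gsub('"', '""', items[needs_quote]), '"')
  paste(items, collapse = paste0(sep, " "))
}
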