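#' Construct a terminology record
#'
#' One row of a terminology table: a (category term, preferred term) pair with
#' its synonyms, definition and CDRH-NCIt mappings, tagged with the
#' terminology it came from and its problem domain. All labels pass through
#' [normalize_label()]; exact duplicate synonyms and mappings are collapsed.
#' A preferred term that also appears among its own synonyms is kept so that
#' [validate_records()] can report it.
#'
#' @param terminology_id non-empty identifier of the source terminology set
#'   (e.g. `"A01-1"`).
#' @param problem_domain `"device"` or `"patient"`.
#' @param category_label,preferred_label term labels; must be non-empty after
#'   normalization.
#' @param synonym_labels character vector of synonyms (may be empty).
#' @param definition_text optional definition sentence (`NA` if absent);
#'   trimmed and canonically composed, punctuation preserved.
#' @param cdrh_ncit_labels character vector of mapped CDRH-NCIt terms.
#' @param width_fold,case_fold normalization flags, see [normalize_label()].
#' @return a list of class `term_record`.
#' @export
term_record <- function(terminology_id, problem_domain, category_label,
                        preferred_label, synonym_labels = character(),
                        definition_text = NA_character_,
                        cdrh_ncit_labels = character(),
                        width_fold = FALSE, case_fold = FALSE) {
  terminology_id <- stringi::stri_trim_both(as.character(terminology_id))
  if (!length(terminology_id) || !nzchar(terminology_id)) {
    stop("term_record: terminology_id must be non-empty")
  }
  problem_domain <- match.arg(problem_domain, c("device", "patient"))
  category_label <- normalize_label(category_label, width_fold, case_fold)
  preferred_label <- normalize_label(preferred_label, width_fold, case_fold)
  synonym_labels <- as.character(synonym_labels)
  if (length(synonym_labels)) {
    synonym_labels <- unique(normalize_label(synonym_labels, width_fold, case_fold))
  }
  definition_text <- if (is.null(definition_text) || is.na(definition_text)) {
    NA_character_
  } else {
    d <- normalize_text(definition_text)
    if (!nzchar(d)) NA_character_ else d
  }
  cdrh_ncit_labels <- as.character(cdrh_ncit_labels)
  if (length(cdrh_ncit_labels)) {
    cdrh_ncit_labels <- unique(normalize_label(cdrh_ncit_labels, width_fold, case_fold))
  }
  structure(
    list(terminology_id = terminology_id, problem_domain = problem_domain,
         category_label = category_label, preferred_label = preferred_label,
         synonym_labels = synonym_labels, definition_text = definition_text,
         cdrh_ncit_labels = cdrh_ncit_labels),
    class = "term_record"
  )
}

#' Construct a terminology set
#'
#' One of the per-device-group terminology sets: an identifier, the device
#' group name, and its records. Records may cover both problem domains (each
#' set has a medical-device-problem and a patient-problem section).
#'
#' @param terminology_id set identifier; every record must carry the same id.
#' @param records list of [term_record()] objects.
#' @param device_group_name free-text device group name (optional).
#' @return a list of class `terminology_set`.
#' @export
terminology_set <- function(terminology_id, records = list(),
                            device_group_name = "") {
  terminology_id <- stringi::stri_trim_both(as.character(terminology_id))
  if (!nzchar(terminology_id)) stop("terminology_set: terminology_id must be non-empty")
  if (!all(vapply(records, inherits, logical(1), "term_record"))) {
    stop("terminology_set: records must be term_record objects")
  }
  ids <- vapply(records, `[[`, character(1), "terminology_id")
  if (length(ids) && any(ids != terminology_id)) {
    stop("terminology_set: all records must share the set's terminology_id")
  }
  structure(
    list(terminology_id = terminology_id,
         device_group_name = as.character(device_group_name),
         records = records),
    class = "terminology_set"
  )
}

#' @export
print.terminology_set <- function(x, ...) {
  cat(sprintf("<terminology_set %s> %s: %d record(s)\n", x$terminology_id,
              if (nzchar(x$device_group_name)) x$device_group_name else "(unnamed)",
              length(x$records)))
  invisible(x)
}

record_key <- function(r, with_def = TRUE) {
  paste(r$terminology_id, r$problem_domain, r$category_label, r$preferred_label,
        if (with_def) r$definition_text else "", sep = "\x1f")
}

#' Read a terminology table
#'
#' Reads a UTF-8 CSV/TSV terminology table in the seven-field JFMDA layout
#' (terminology ID, problem domain, category term, preferred term, synonyms,
#' definition, CDRH-NCIt) into one [terminology_set()] per distinct
#' terminology ID. Synonym and CDRH-NCIt cells are split on the dialect's
#' intra-cell delimiter honoring double-quoted items (so
#' `"Vessels, perforation of"` stays one label). Rows repeated for the same
#' (terminology, domain, category, preferred, definition) are collapsed into
#' one record with the union of synonyms and mappings.
#'
#' @param path path to the table file.
#' @param dialect a [table_dialect()].
#' @return list of `terminology_set`, in order of first appearance.
#' @export
read_terminology_table <- function(path, dialect = table_dialect()) {
  if (!file.exists(path)) stop("read_terminology_table: no such file: ", path)
  df <- utils::read.table(path, sep = dialect$field_sep, quote = '"',
                          header = TRUE, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE, na.strings = NULL,
                          comment.char = "", fill = FALSE)
  idx <- match_headers(names(df), dialect)
  if (!nrow(df)) return(list())
  rows <- seq_len(nrow(df)) + 1L  # 1-based data rows; +1 for the header line
  tid <- stringi::stri_trim_both(df[[idx[["terminology_id"]]]])
  if (any(!nzchar(tid))) {
    stop(sprintf("empty terminology ID at row %d", rows[!nzchar(tid)][1L]))
  }
  dom <- parse_domain(df[[idx[["problem_domain"]]]], dialect, rows)
  pref_raw <- stringi::stri_trim_both(df[[idx[["preferred_term"]]]])
  if (any(!nzchar(pref_raw))) {
    stop(sprintf("empty preferred term cell at row %d", rows[!nzchar(pref_raw)][1L]))
  }
  cat_raw <- stringi::stri_trim_both(df[[idx[["category_term"]]]])
  if (any(!nzchar(cat_raw))) {
    stop(sprintf("empty category term cell at row %d", rows[!nzchar(cat_raw)][1L]))
  }
  recs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    recs[[i]] <- term_record(
      terminology_id = tid[i], problem_domain = dom[i],
      category_label = cat_raw[i], preferred_label = pref_raw[i],
      synonym_labels = split_cell(df[[idx[["synonyms"]]]][i], dialect$cell_sep),
      definition_text = df[[idx[["definition"]]]][i],
      cdrh_ncit_labels = split_cell(df[[idx[["cdrh_ncit"]]]][i], dialect$cell_sep),
      width_fold = dialect$width_fold, case_fold = dialect$case_fold
    )
  }
  # collapse repeated-row dialect: same (set, domain, category, preferred,
  # definition) rows merge, unioning synonyms and mappings
  keys <- vapply(recs, record_key, character(1))
  merged <- list()
  for (i in seq_along(recs)) {
    k <- keys[i]
    if (is.null(merged[[k]])) {
      merged[[k]] <- recs[[i]]
    } else {
      merged[[k]]$synonym_labels <-
        unique(c(merged[[k]]$synonym_labels, recs[[i]]$synonym_labels))
      merged[[k]]$cdrh_ncit_labels <-
        unique(c(merged[[k]]$cdrh_ncit_labels, recs[[i]]$cdrh_ncit_labels))
    }
  }
  recs <- unname(merged)
  set_ids <- unique(vapply(recs, `[[`, character(1), "terminology_id"))
  grp_col <- df[["device_group_name"]]
  lapply(set_ids, function(id) {
    in_set <- vapply(recs, function(r) r$terminology_id == id, logical(1))
    grp <- ""
    if (!is.null(grp_col)) {
      g <- grp_col[tid == id]
      g <- g[nzchar(g)]
      if (length(g)) grp <- g[1L]
    }
    terminology_set(id, recs[in_set], device_group_name = grp)
  })
}

#' Write terminology sets back to the tabular dialect
#'
#' Inverse of [read_terminology_table()]: one row per record, list cells
#' joined with the dialect's intra-cell delimiter (items containing the
#' delimiter are double-quoted). Reading the written file back yields equal
#' records.
#'
#' @param sets list of [terminology_set()].
#' @param path output file path.
#' @param dialect a [table_dialect()].
#' @return `path`, invisibly.
#' @export
write_terminology_table <- function(sets, path, dialect = table_dialect()) {
  rows <- list()
  for (s in sets) {
    for (r in s$records) {
      rows[[length(rows) + 1L]] <- data.frame(
        terminology_id = r$terminology_id,
        problem_domain = r$problem_domain,
        category_term = r$category_label,
        preferred_term = r$preferred_label,
        synonyms = join_cell(r$synonym_labels, dialect$cell_sep),
        definition = if (is.na(r$definition_text)) "" else r$definition_text,
        cdrh_ncit = join_cell(r$cdrh_ncit_labels, dialect$cell_sep),
        device_group_name = s$device_group_name,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(terminology_id = character(), problem_domain = character(),
               category_term = character(), preferred_term = character(),
               synonyms = character(), definition = character(),
               cdrh_ncit = character(), device_group_name = character())
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = dialect$field_sep, qmethod = "double",
                     quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Validate terminology records
#'
#' Collects machine-readable data-quality issues without mutating or raising:
#' exact duplicate rows within a set, a preferred term listed among its own
#' synonyms, and blank definitions. Severities are `"warn"` or `"error"`.
#'
#' @param sets list of [terminology_set()].
#' @return data.frame with columns `terminology_id`, `record`, `severity`,
#'   `code`, `message`; zero rows when clean.
#' @export
validate_records <- function(sets) {
  issues <- list()
  add <- function(tid, rec, severity, code, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      terminology_id = tid, record = rec, severity = severity,
      code = code, message = message, stringsAsFactors = FALSE)
  }
  for (s in sets) {
    full_keys <- vapply(s$records, function(r) {
      paste(record_key(r), paste(sort_cp(r$synonym_labels), collapse = "|"),
            paste(sort_cp(r$cdrh_ncit_labels), collapse = "|"), sep = "\x1f")
    }, character(1))
    dup <- duplicated(full_keys)
    for (i in which(dup)) {
      r <- s$records[[i]]
      add(s$terminology_id, i, "warn", "duplicate-row",
          sprintf("duplicate identical row for '%s' / '%s'",
                  r$category_label, r$preferred_label))
    }
    for (i in seq_along(s$records)) {
      r <- s$records[[i]]
      if (r$preferred_label %in% r$synonym_labels) {
        add(s$terminology_id, i, "error", "self-synonym",
            sprintf("preferred term '%s' listed among its own synonyms",
                    r$preferred_label))
      }
      if (is.na(r$definition_text)) {
        add(s$terminology_id, i, "warn", "blank-definition",
            sprintf("no definition for preferred term '%s'", r$preferred_label))
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(terminology_id = character(), record = integer(),
                      severity = character(), code = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
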