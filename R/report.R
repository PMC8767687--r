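#' Summarize an audit run
#'
#' Aggregates graph statistics and check results into one report: per domain
#' the pre-/post-integration term and relation tallies with the duplicate
#' reduction percentage, per check the pattern and unique-term counts with the
#' percentage of the domain's combined (category + preferred) term count, the
#' maximum multiplicity and a top-k listing, plus the cross-domain term list
#' and the hierarchy cycles. Percentages use the post-integration combined
#' term count of the domain as denominator (stated in the report itself).
#' Pre-integration term tallies are sums over terminology sets of per-set
#' distinct category / preferred labels.
#'
#' @param device_graph,patient_graph `integrated_graph`s.
#' @param check_results an `audit_results` from [run_all_checks()] over the
#'   same graphs.
#' @param top_k how many highest-multiplicity terms to list per check.
#' @return a list of class `audit_report` (schema-stable, JSON-serializable).
#' @export
summarize_audit <- function(device_graph, patient_graph, check_results,
                            top_k = 5L) {
  stopifnot(inherits(check_results, "audit_results"))
  dom_summary <- function(g, res) {
    terms <- count_terms(g)
    pre_combined <- g$pre$category_mentions + g$pre$preferred_mentions
    degenerate <- pre_combined == 0L
    reduction <- if (degenerate) 0 else
      100 * (1 - terms$combined / pre_combined)
    rel <- lapply(PREDICATES, function(p) {
      list(pre = count_relations(g, p, dedup = FALSE),
           post = count_relations(g, p, dedup = TRUE))
    })
    names(rel) <- PREDICATES
    checks <- lapply(c("dual_role", "swap", "multi_parent",
                       "multi_definition", "multi_mapping"), function(nm) {
      cr <- res[[nm]]
      top <- list()
      if (!is.na(cr$max_multiplicity) && nrow(cr$findings)) {
        f <- cr$findings
        # multiplicity descending, then label code point
        ord <- order(-f$multiplicity, match(f$term, sort_cp(f$term)))
        sel <- utils::head(ord, top_k)
        top <- lapply(sel, function(i) {
          list(term = f$term[i], multiplicity = f$multiplicity[i])
        })
      }
      out <- list(pattern_count = cr$pattern_count,
                  unique_term_count = cr$unique_term_count,
                  pct_of_combined_terms = if (terms$combined > 0)
                    100 * cr$unique_term_count / terms$combined else 0,
                  max_multiplicity = if (is.na(cr$max_multiplicity)) NULL
                    else cr$max_multiplicity,
                  top = top)
      if (nm == "swap") {
        out$unique_term_count_with_partners <-
          cr$extra$unique_term_count_with_partners
      }
      out
    })
    names(checks) <- c("dual_role", "swap", "multi_parent",
                       "multi_definition", "multi_mapping")
    list(
      terms = list(
        pre = list(category = g$pre$category_mentions,
                   preferred = g$pre$preferred_mentions,
                   combined = pre_combined),
        post = list(category = terms$category, preferred = terms$preferred,
                    synonym = terms$synonym, combined = terms$combined),
        reduction_pct = reduction,
        degenerate = degenerate
      ),
      relations = rel,
      checks = checks,
      cycles = lapply(res$cycles, as.list)
    )
  }
  structure(list(
    schema_version = "1.0",
    denominator = "post-integration combined (category+preferred) term count per domain",
    device = dom_summary(device_graph, check_results$device),
    patient = dom_summary(patient_graph, check_results$patient),
    cross_domain = list(
      count = check_results$cross_domain$unique_term_count,
      terms = as.list(check_results$cross_domain$unique_terms)
    )
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  for (dom in c("device", "patient")) {
    d <- x[[dom]]
    cat(sprintf("%s: %d -> %d combined terms (%.1f%% reduction)\n", dom,
                d$terms$pre$combined, d$terms$post$combined,
                d$terms$reduction_pct))
    for (nm in names(d$checks)) {
      ck <- d$checks[[nm]]
      cat(sprintf("  %-16s %4d pattern(s), %3d unique term(s) (%.1f%%)%s\n", nm,
                  ck$pattern_count, ck$unique_term_count,
                  ck$pct_of_combined_terms,
                  if (!is.null(ck$max_multiplicity))
                    sprintf(", max multiplicity %d", ck$max_multiplicity) else ""))
    }
    cat(sprintf("  cycles: %d\n", length(d$cycles)))
  }
  cat(sprintf("cross-domain terms: %d\n", x$cross_domain$count))
  invisible(x)
}

#' Write an audit report
#'
#' JSON output is schema-stable and machine-diffable (byte-identical across
#' runs on the same inputs); markdown renders per-section tables; CSV writes
#' one file per section next to `path` (suffixing the section name).
#'
#' @param report an `audit_report`.
#' @param path output path (for CSV, the stem used for the per-section files).
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE)
    con <- file(path, open = "w", encoding = "UTF-8")
    writeLines(json, con)
    close(con)
    return(invisible(path))
  }
  if (format == "csv") {
    stem <- sub("\\.csv$", "", path)
    write_utf8_csv <- function(df, p) {
      con <- file(p, open = "w", encoding = "UTF-8")
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    terms <- do.call(rbind, lapply(c("device", "patient"), function(dom) {
      t <- report[[dom]]$terms
      data.frame(domain = dom, pre_combined = t$pre$combined,
                 post_combined = t$post$combined,
                 reduction_pct = t$reduction_pct, stringsAsFactors = FALSE)
    }))
    write_utf8_csv(terms, paste0(stem, "_terms.csv"))
    rel <- do.call(rbind, lapply(c("device", "patient"), function(dom) {
      do.call(rbind, lapply(names(report[[dom]]$relations), function(p) {
        r <- report[[dom]]$relations[[p]]
        data.frame(domain = dom, predicate = p, pre = r$pre, post = r$post,
                   stringsAsFactors = FALSE)
      }))
    }))
    write_utf8_csv(rel, paste0(stem, "_relations.csv"))
    checks <- do.call(rbind, lapply(c("device", "patient"), function(dom) {
      do.call(rbind, lapply(names(report[[dom]]$checks), function(nm) {
        ck <- report[[dom]]$checks[[nm]]
        data.frame(domain = dom, check = nm,
                   pattern_count = ck$pattern_count,
                   unique_term_count = ck$unique_term_count,
                   pct_of_combined_terms = ck$pct_of_combined_terms,
                   max_multiplicity = ck$max_multiplicity %||% NA_integer_,
                   stringsAsFactors = FALSE)
      }))
    }))
    write_utf8_csv(checks, paste0(stem, "_checks.csv"))
    xd <- data.frame(term = unlist(report$cross_domain$terms) %||% character(),
                     stringsAsFactors = FALSE)
    write_utf8_csv(xd, paste0(stem, "_cross_domain.csv"))
    return(invisible(path))
  }
  # markdown
  lines <- c("# Terminology audit report", "")
  for (dom in c("device", "patient")) {
    d <- report[[dom]]
    lines <- c(lines, sprintf("## %s problems", dom), "",
               "| tally | before integration | after integration |",
               "|---|---|---|",
               sprintf("| combined terms | %d | %d |",
                       d$terms$pre$combined, d$terms$post$combined),
               sprintf("| reduction | | %.1f%% |", d$terms$reduction_pct), "")
    lines <- c(lines, "| relation | before | after |", "|---|---|---|")
    for (p in names(d$relations)) {
      lines <- c(lines, sprintf("| %s | %d | %d |", p,
                                d$relations[[p]]$pre, d$relations[[p]]$post))
    }
    lines <- c(lines, "",
               "| check | patterns | unique terms | % of terms | max multiplicity |",
               "|---|---|---|---|---|")
    for (nm in names(d$checks)) {
      ck <- d$checks[[nm]]
      lines <- c(lines, sprintf("| %s | %d | %d | %.1f | %s |", nm,
                                ck$pattern_count, ck$unique_term_count,
                                ck$pct_of_combined_terms,
                                if (is.null(ck$max_multiplicity)) ""
                                else ck$max_multiplicity))
    }
    lines <- c(lines, "", sprintf("Hierarchy cycles: %d", length(d$cycles)))
    for (cy in d$cycles) {
      lines <- c(lines, sprintf("- %s", paste(unlist(cy), collapse = " -> ")))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Terms shared by both domains", "",
             sprintf("%d term(s):", report$cross_domain$count),
             sprintf("- %s", unlist(report$cross_domain$terms)))
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Read back a JSON audit report
#'
#' @param path path to a JSON report written by [write_report()].
#' @return an `audit_report`.
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(rep, class = "audit_report")
}
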