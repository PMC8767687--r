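# The six structural consistency checks plus hierarchy-cycle detection.
# Every check is a pure function of the graph(s); findings are returned in a
# deterministic order (lexicographic by pattern, code-point collation).

new_check_result <- function(check_id, domain, findings, unique_terms,
                             max_multiplicity = NA_integer_, extra = list()) {
  rownames(findings) <- NULL
  structure(
    list(check_id = check_id, domain = domain, findings = findings,
         pattern_count = nrow(findings),
         unique_term_count = length(unique_terms),
         unique_terms = sort_cp(unique_terms),
         max_multiplicity = max_multiplicity, extra = extra),
    class = "check_result"
  )
}

#' @export
print.check_result <- function(x, ...) {
  cat(sprintf("<check_result %s [%s]> %d pattern(s), %d unique term(s)",
              x$check_id, x$domain, x$pattern_count, x$unique_term_count))
  if (!is.na(x$max_multiplicity)) cat(sprintf(", max multiplicity %d", x$max_multiplicity))
  cat("\n")
  invisible(x)
}

prov_union <- function(...) sort_cp(unique(unlist(list(...))))

edge_prov <- function(ed, s, o) {
  i <- which(ed$subject == s & ed$object == o)
  if (!length(i)) character() else ed$provenance[[i]]
}

#' Check 1: terms used as both category and preferred term
#'
#' A consistent two-layer hierarchy cannot contain a label that is a category
#' term in one terminology and a preferred term in another: integrating such
#' sets by notation creates three or more layers. A term T is flagged iff its
#' node roles include both `category` and `preferred`. One pattern is emitted
#' per distinct (parent, T, child) context, where (T subClassOf parent) and
#' (child subClassOf T); self edges are allowed, so parent or child may equal
#' T. A finding additionally carries the `identical_label` sub-flag when a
#' single record used the same label at both levels (a self subClassOf edge
#' exists).
#'
#' @param graph an `integrated_graph`.
#' @return a `check_result` with findings columns `parent`, `term`, `child`,
#'   `identical_label`, `provenance`.
#' @export
check_dual_role <- function(graph) {
  stopifnot(inherits(graph, "integrated_graph"))
  n <- graph$nodes
  dual <- n$label[n$category & n$preferred]
  sub <- graph$edges$subClassOf
  rows <- list()
  for (t in dual) {
    parents <- sub$object[sub$subject == t]
    children <- sub$subject[sub$object == t]
    self_edge <- t %in% parents && t %in% children &&
      any(sub$subject == t & sub$object == t)
    if (!length(parents)) parents <- NA_character_
    if (!length(children)) children <- NA_character_
    for (p in sort_cp(parents)) {
      for (ch in sort_cp(children)) {
        prov <- prov_union(
          if (!is.na(p)) edge_prov(sub, t, p),
          if (!is.na(ch)) edge_prov(sub, ch, t)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          parent = p, term = t, child = ch, identical_label = self_edge,
          stringsAsFactors = FALSE, row.names = NULL)
        rows[[length(rows)]]$provenance <- I(list(prov))
      }
    }
  }
  findings <- bind_findings(rows, c("parent", "term", "child"),
                            extra_cols = list(identical_label = logical()))
  new_check_result("dual_role", graph$domain, findings, dual)
}

bind_findings <- function(rows, key_cols, extra_cols = list()) {
  if (!length(rows)) {
    df <- data.frame(stringsAsFactors = FALSE)
    for (k in key_cols) df[[k]] <- character()
    for (k in names(extra_cols)) df[[k]] <- extra_cols[[k]]
    df$provenance <- I(list())
    return(df)
  }
  df <- do.call(rbind, rows)
  ord <- do.call(order_cp, lapply(key_cols, function(k) df[[k]]))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Check 2: preferred term and synonym exchanged
#'
#' Flags a term X that one terminology attaches as a synonym of some preferred
#' term P while another terminology uses X itself as a preferred term. One
#' pattern per distinct (P, X, S) with (P hasSynonym X) and (X hasSynonym S);
#' when X has the preferred role but no synonyms of its own, the pattern is
#' (P, X, NA). `unique_term_count` counts flagged X terms;
#' `extra$unique_term_count_with_partners` additionally includes the partner
#' terms P and S.
#'
#' @param graph an `integrated_graph`.
#' @return a `check_result` with findings columns `preferred`, `term`,
#'   `synonym`, `provenance`.
#' @export
check_preferred_synonym_swap <- function(graph) {
  stopifnot(inherits(graph, "integrated_graph"))
  syn <- graph$edges$hasSynonym
  n <- graph$nodes
  preferred_labels <- n$label[n$preferred]
  xs <- sort_cp(unique(syn$object[syn$object %in% preferred_labels]))
  rows <- list()
  partners <- character()
  for (x in xs) {
    ps <- sort_cp(syn$subject[syn$object == x])
    ss <- sort_cp(syn$object[syn$subject == x])
    if (!length(ss)) ss <- NA_character_
    for (p in ps) {
      for (s in ss) {
        prov <- prov_union(edge_prov(syn, p, x),
                           if (!is.na(s)) edge_prov(syn, x, s))
        rows[[length(rows) + 1L]] <- data.frame(
          preferred = p, term = x, synonym = s,
          stringsAsFactors = FALSE, row.names = NULL)
        rows[[length(rows)]]$provenance <- I(list(prov))
        partners <- c(partners, p, if (!is.na(s)) s)
      }
    }
  }
  findings <- bind_findings(rows, c("preferred", "term", "synonym"))
  new_check_result(
    "swap", graph$domain, findings, xs,
    extra = list(unique_term_count_with_partners =
                   length(unique(c(xs, partners))))
  )
}

# Shared machinery for checks 3-5: flag subjects with >= 2 distinct objects
# under the given predicate.
check_multiplicity <- function(graph, predicate, check_id, key,
                               distinct = identity) {
  ed <- graph$edges[[predicate]]
  rows <- list()
  flagged <- character()
  max_mult <- 0L
  for (s in sort_cp(unique(ed$subject))) {
    i <- which(ed$subject == s)
    objs <- ed$object[i]
    m <- length(unique(distinct(objs)))
    if (m < 2L) next
    flagged <- c(flagged, s)
    max_mult <- max(max_mult, m)
    row <- data.frame(term = s, multiplicity = m,
                      stringsAsFactors = FALSE, row.names = NULL)
    row[[key]] <- I(list(sort_cp(unique(objs))))
    row$provenance <- I(list(prov_union(unlist(ed$provenance[i]))))
    rows[[length(rows) + 1L]] <- row
  }
  findings <- if (length(rows)) {
    df <- do.call(rbind, rows)
    df <- df[order_cp(df$term), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    df <- data.frame(term = character(), multiplicity = integer(),
                     stringsAsFactors = FALSE)
    df[[key]] <- I(list())
    df$provenance <- I(list())
    df
  }
  new_check_result(check_id, graph$domain, findings, flagged,
                   max_multiplicity = if (length(flagged)) max_mult else NA_integer_)
}

#' Check 3: preferred terms subordinate to several category terms
#'
#' In a monohierarchy every preferred term has exactly one category parent;
#' this check flags preferred terms whose set of distinct category parents
#' (after integration) has size two or more. A self parent counts.
#'
#' @param graph an `integrated_graph`.
#' @return a `check_result` with findings columns `term`, `multiplicity`,
#'   `parents`, `provenance`; `max_multiplicity` is the largest parent-set
#'   size.
#' @export
check_multi_parent <- function(graph) {
  stopifnot(inherits(graph, "integrated_graph"))
  check_multiplicity(graph, "subClassOf", "multi_parent", "parents")
}

#' Check 4: preferred terms with several definitions
#'
#' Flags preferred terms carrying two or more distinct definition sentences.
#' Distinctness is exact-string after trim and canonical composition, so two
#' definitions differing only in a trailing ideographic full stop count
#' separately.
#'
#' @param graph an `integrated_graph`.
#' @return a `check_result` with findings columns `term`, `multiplicity`,
#'   `definitions`, `provenance`.
#' @export
check_multi_definition <- function(graph) {
  stopifnot(inherits(graph, "integrated_graph"))
  check_multiplicity(graph, "isDefinedBy", "multi_definition", "definitions")
}

#' Check 5: preferred terms mapped to several CDRH-NCIt terms
#'
#' Flags preferred terms with two or more distinct correspondence targets.
#' Comparison is case-sensitive exact match after trim by default; set
#' `ignore_case = TRUE` to count case variants (e.g. "Material deformation"
#' vs "material deformation") as one target.
#'
#' @param graph an `integrated_graph`.
#' @param ignore_case count targets case-insensitively.
#' @return a `check_result` with findings columns `term`, `multiplicity`,
#'   `targets`, `provenance`.
#' @export
check_multi_mapping <- function(graph, ignore_case = FALSE) {
  stopifnot(inherits(graph, "integrated_graph"))
  distinct <- if (ignore_case) stringi::stri_trans_tolower else identity
  check_multiplicity(graph, "correspondenceOf", "multi_mapping", "targets",
                     distinct = distinct)
}

#' Check 6: terms shared between the device and patient domains
#'
#' Flags labels that carry the category or preferred role in both the
#' medical-device-problem graph and the patient-problem graph. Such labels
#' denote different subjects (the device vs the patient) under one notation
#' and would get their hierarchies exchanged if the domains were merged.
#' Synonym-only occurrences do not count.
#'
#' @param device_graph,patient_graph `integrated_graph`s built over the same
#'   label normalization.
#' @return a `check_result` with findings columns `term`, `roles_device`,
#'   `roles_patient`, `provenance`.
#' @export
check_cross_domain <- function(device_graph, patient_graph) {
  stopifnot(inherits(device_graph, "integrated_graph"),
            inherits(patient_graph, "integrated_graph"))
  dev <- labels_with_roles(device_graph, c("category", "preferred"))
  pat <- labels_with_roles(patient_graph, c("category", "preferred"))
  shared <- sort_cp(intersect(dev, pat))
  rows <- lapply(shared, function(t) {
    row <- data.frame(
      term = t,
      roles_device = paste(intersect(node_roles(device_graph, t),
                                     c("category", "preferred")), collapse = "+"),
      roles_patient = paste(intersect(node_roles(patient_graph, t),
                                      c("category", "preferred")), collapse = "+"),
      stringsAsFactors = FALSE, row.names = NULL)
    row$provenance <- I(list(prov_union(label_prov(device_graph, t),
                                        label_prov(patient_graph, t))))
    row
  })
  findings <- bind_findings(rows, "term",
                            extra_cols = list(roles_device = character(),
                                              roles_patient = character()))
  new_check_result("cross_domain", "both", findings, shared)
}

# provenance of every subclass edge touching the label in a cat/pref position
label_prov <- function(graph, label) {
  sub <- graph$edges$subClassOf
  i <- which(sub$subject == label | sub$object == label)
  prov_union(unlist(sub$provenance[i]))
}

#' Enumerate elementary cycles of the subclass hierarchy
#'
#' A consistently integrated two-layer terminology should form a directed
#' acyclic graph under `subClassOf`; cycles arise from identical labels at
#' both levels (1-cycles), hypernym/hyponym inversion across terminologies
#' (2-cycles), and longer chains. All elementary cycles of the directed
#' child-to-parent relation are returned, each in canonical rotation (starting
#' at its code-point-smallest label), ordered by length then labels. The
#' enumeration is Johnson's algorithm restricted to nontrivial strongly
#' connected components.
#'
#' @param graph an `integrated_graph`.
#' @return list of character vectors; each vector lists the labels of one
#'   cycle (length 1 for self edges).
#' @export
detect_hierarchy_cycles <- function(graph) {
  stopifnot(inherits(graph, "integrated_graph"))
  sub <- graph$edges$subClassOf
  find_cycles(sub$subject, sub$object)
}

# Elementary cycle enumeration on a digraph given as parallel from/to vectors.
find_cycles <- function(from, to) {
  cycles <- list()
  if (!length(from)) return(cycles)
  keep <- !duplicated(paste(from, to, sep = "\x1f"))  # parallel edges count once
  from <- from[keep]; to <- to[keep]
  self <- from == to
  for (lab in sort_cp(unique(from[self]))) cycles[[length(cycles) + 1L]] <- lab
  from2 <- from[!self]; to2 <- to[!self]
  if (length(from2)) {
    labels <- sort_cp(unique(c(from2, to2)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = from2, to = to2, stringsAsFactors = FALSE),
      directed = TRUE, vertices = labels)
    comp <- igraph::components(g, mode = "strong")
    for (ci in which(comp$csize >= 2L)) {
      members <- labels[comp$membership == ci]
      keep <- from2 %in% members & to2 %in% members
      cycles <- c(cycles, johnson_cycles(from2[keep], to2[keep]))
    }
  }
  if (!length(cycles)) return(list())
  key <- vapply(cycles, function(cy) {
    sprintf("%09d\x1f%s", length(cy), paste(cy, collapse = "\x1f"))
  }, character(1))
  cycles[order_cp(key)]
}

# Johnson (1975) elementary-circuit enumeration within one strongly connected
# subgraph; vertices explored in code-point order so each cycle is found
# exactly once, rooted at its smallest label (= canonical rotation).
johnson_cycles <- function(from, to) {
  verts <- sort_cp(unique(c(from, to)))
  n <- length(verts)
  adj <- lapply(verts, function(v) sort(match(to[from == v], verts)))
  cycles <- list()
  for (s in seq_len(n)) {
    blocked <- rep(FALSE, n)
    B <- vector("list", n)
    stack <- integer()
    unblock <- function(u) {
      blocked[u] <<- FALSE
      for (w in B[[u]]) if (blocked[w]) unblock(w)
      B[[u]] <<- integer()
    }
    circuit <- function(v) {
      found <- FALSE
      stack <<- c(stack, v)
      blocked[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w < s) next
        if (w == s) {
          cycles[[length(cycles) + 1L]] <<- verts[stack]
          found <- TRUE
        } else if (!blocked[w]) {
          if (circuit(w)) found <- TRUE
        }
      }
      if (found) {
        unblock(v)
      } else {
        for (w in adj[[v]]) {
          if (w < s) next
          if (!v %in% B[[w]]) B[[w]] <<- c(B[[w]], v)
        }
      }
      stack <<- stack[-length(stack)]
      found
    }
    circuit(s)
  }
  cycles
}

#' Run every audit check
#'
#' Runs checks 1-5 and cycle detection on each domain graph and the
#' cross-domain check across the pair. Findings come back in a deterministic
#' order, and the input graphs are never mutated.
#'
#' @param device_graph,patient_graph `integrated_graph`s for the two problem
#'   domains.
#' @param mapping_ignore_case passed to [check_multi_mapping()].
#' @return a list of class `audit_results`: per domain the five
#'   `check_result`s and the cycle list, plus `cross_domain`.
#' @export
run_all_checks <- function(device_graph, patient_graph,
                           mapping_ignore_case = FALSE) {
  per_domain <- function(g) {
    list(dual_role = check_dual_role(g),
         swap = check_preferred_synonym_swap(g),
         multi_parent = check_multi_parent(g),
         multi_definition = check_multi_definition(g),
         multi_mapping = check_multi_mapping(g, ignore_case = mapping_ignore_case),
         cycles = detect_hierarchy_cycles(g))
  }
  structure(list(device = per_domain(device_graph),
                 patient = per_domain(patient_graph),
                 cross_domain = check_cross_domain(device_graph, patient_graph)),
            class = "audit_results")
}

#' Export findings as CSV or JSON lines
#'
#' One row/line per pattern with the check id, the pattern fields and the
#' supporting terminology IDs, so the industry associations that disagree can
#' be contacted.
#'
#' @param results an `audit_results` from [run_all_checks()].
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_findings <- function(results, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  rows <- list()
  flat <- function(v) {
    if (is.list(v)) vapply(v, function(x) paste(x, collapse = "; "), character(1))
    else as.character(v)
  }
  for (dom in c("device", "patient")) {
    for (nm in c("dual_role", "swap", "multi_parent", "multi_definition",
                 "multi_mapping")) {
      cr <- results[[dom]][[nm]]
      f <- cr$findings
      if (!nrow(f)) next
      pattern_cols <- setdiff(names(f), "provenance")
      rows[[length(rows) + 1L]] <- data.frame(
        check_id = cr$check_id, domain = dom,
        pattern = do.call(paste, c(lapply(pattern_cols, function(cn) flat(f[[cn]])),
                                   sep = " | ")),
        provenance = flat(f$provenance), stringsAsFactors = FALSE)
    }
    for (cy in results[[dom]]$cycles) {
      rows[[length(rows) + 1L]] <- data.frame(
        check_id = "cycle", domain = dom,
        pattern = paste(cy, collapse = " -> "), provenance = "",
        stringsAsFactors = FALSE)
    }
  }
  xf <- results$cross_domain$findings
  if (nrow(xf)) {
    rows[[length(rows) + 1L]] <- data.frame(
      check_id = "cross_domain", domain = "both",
      pattern = paste(xf$term, xf$roles_device, xf$roles_patient, sep = " | "),
      provenance = flat(xf$provenance), stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(check_id = character(), domain = character(),
               pattern = character(), provenance = character())
  if (format == "csv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con <- file(path, open = "w", encoding = "UTF-8"))
    close(con)
  }
  invisible(path)
}
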