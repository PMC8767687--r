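PREDICATES <- c("subClassOf", "hasSynonym", "correspondenceOf", "isDefinedBy")

empty_edge_df <- function() {
  data.frame(subject = character(), object = character(),
             provenance = I(list()), n_raw = integer(),
             stringsAsFactors = FALSE)
}

# Aggregate raw (subject, object, terminology_id) triples into a deduplicated
# edge table: one row per distinct pair, provenance = sorted set of ids,
# n_raw = number of contributing records.
aggregate_edges <- function(subject, object, tid) {
  if (!length(subject)) return(empty_edge_df())
  key <- paste(subject, object, sep = "\x1f")
  first <- !duplicated(key)
  prov <- split(tid, factor(key, levels = key[first]))
  df <- data.frame(subject = subject[first], object = object[first],
                   stringsAsFactors = FALSE)
  df$provenance <- I(unname(lapply(prov, function(p) sort_cp(unique(p)))))
  df$n_raw <- as.integer(lengths(prov))
  df <- df[order_cp(df$subject, df$object), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the integrated per-domain graph
#'
#' Merges all records of the requested problem domain across terminology sets
#' into one labeled graph, keyed purely by term notation: labels that are
#' spelled identically (after [normalize_label()]) become one node. Four edge
#' relations are kept, deduplicated by (subject, object) with the contributing
#' terminology IDs unioned as provenance:
#'
#' * `subClassOf` — preferred term (child) to category term (parent);
#' * `hasSynonym` — preferred term to synonym;
#' * `correspondenceOf` — preferred term to CDRH-NCIt term;
#' * `isDefinedBy` — preferred term to its definition sentence (a literal).
#'
#' Node roles record every position a label occupies anywhere in the input, so
#' a label used as both a category term and a preferred term yields one node
#' with both roles (the signature the dual-role check detects). Self edges
#' (category = preferred in one record) are retained. Records of the other
#' problem domain are skipped and counted, never merged: device and patient
#' graphs are always built separately.
#'
#' @param sets list of [terminology_set()].
#' @param domain `"device"` or `"patient"`.
#' @return an object of class `integrated_graph` with fields `domain`,
#'   `nodes` (label + logical role columns), `edges` (one data.frame per
#'   predicate), `pre` (pre-integration tallies) and `skipped`.
#' @export
build_graph <- function(sets, domain = c("device", "patient")) {
  domain <- match.arg(domain)
  sub_s <- sub_o <- syn_s <- syn_o <- cor_s <- cor_o <- def_s <- def_o <-
    character()
  sub_t <- syn_t <- cor_t <- def_t <- character()
  pre_cat <- pre_pref <- n_records <- 0L
  skipped <- 0L
  for (s in sets) {
    cats <- character(); prefs <- character()
    for (r in s$records) {
      if (r$problem_domain != domain) { skipped <- skipped + 1L; next }
      n_records <- n_records + 1L
      cats <- c(cats, r$category_label); prefs <- c(prefs, r$preferred_label)
      sub_s <- c(sub_s, r$preferred_label); sub_o <- c(sub_o, r$category_label)
      sub_t <- c(sub_t, r$terminology_id)
      if (length(r$synonym_labels)) {
        syn_s <- c(syn_s, rep(r$preferred_label, length(r$synonym_labels)))
        syn_o <- c(syn_o, r$synonym_labels)
        syn_t <- c(syn_t, rep(r$terminology_id, length(r$synonym_labels)))
      }
      if (length(r$cdrh_ncit_labels)) {
        cor_s <- c(cor_s, rep(r$preferred_label, length(r$cdrh_ncit_labels)))
        cor_o <- c(cor_o, r$cdrh_ncit_labels)
        cor_t <- c(cor_t, rep(r$terminology_id, length(r$cdrh_ncit_labels)))
      }
      if (!is.na(r$definition_text)) {
        def_s <- c(def_s, r$preferred_label); def_o <- c(def_o, r$definition_text)
        def_t <- c(def_t, r$terminology_id)
      }
    }
    pre_cat <- pre_cat + length(unique(cats))
    pre_pref <- pre_pref + length(unique(prefs))
  }
  if (skipped > 0L) {
    message(sprintf("build_graph(%s): skipped %d record(s) of the other domain",
                    domain, skipped))
  }
  edges <- list(
    subClassOf = aggregate_edges(sub_s, sub_o, sub_t),
    hasSynonym = aggregate_edges(syn_s, syn_o, syn_t),
    correspondenceOf = aggregate_edges(cor_s, cor_o, cor_t),
    isDefinedBy = aggregate_edges(def_s, def_o, def_t)
  )
  nodes <- make_nodes(category = sub_o, preferred = sub_s, synonym = syn_o)
  pre_rel <- c(subClassOf = length(sub_s), hasSynonym = length(syn_s),
               correspondenceOf = length(cor_s), isDefinedBy = length(def_s))
  new_integrated_graph(domain, nodes, edges,
                       pre = list(category_mentions = pre_cat,
                                  preferred_mentions = pre_pref,
                                  records = n_records,
                                  relations_raw = pre_rel),
                       skipped = skipped)
}

make_nodes <- function(category, preferred, synonym) {
  labels <- sort_cp(unique(c(category, preferred, synonym)))
  data.frame(label = labels,
             category = labels %in% category,
             preferred = labels %in% preferred,
             synonym = labels %in% synonym,
             stringsAsFactors = FALSE)
}

new_integrated_graph <- function(domain, nodes, edges, pre, skipped = 0L) {
  rownames(nodes) <- NULL
  structure(list(domain = domain, nodes = nodes, edges = edges,
                 pre = pre, skipped = skipped),
            class = "integrated_graph")
}

#' @export
print.integrated_graph <- function(x, ...) {
  cat(sprintf("<integrated_graph: %s> %d node(s)\n", x$domain, nrow(x$nodes)))
  for (p in PREDICATES) {
    cat(sprintf("  %-16s %5d edge(s) (%d before integration)\n", p,
                nrow(x$edges[[p]]), x$pre$relations_raw[[p]]))
  }
  invisible(x)
}

#' Merge two integrated graphs of the same domain
#'
#' Unions nodes (role-wise) and edges; duplicate (subject, object) pairs merge
#' with provenance unioned and raw multiplicities summed. Building one graph
#' over the union of all sets equals merging per-set graphs.
#'
#' @param x,y `integrated_graph` objects with equal `domain`.
#' @return an `integrated_graph`.
#' @export
merge_graphs <- function(x, y) {
  stopifnot(inherits(x, "integrated_graph"), inherits(y, "integrated_graph"))
  if (x$domain != y$domain) stop("merge_graphs: graphs are for different domains")
  edges <- lapply(PREDICATES, function(p) {
    a <- x$edges[[p]]; b <- y$edges[[p]]
    subject <- c(a$subject, b$subject); object <- c(a$object, b$object)
    if (!length(subject)) return(empty_edge_df())
    key <- paste(subject, object, sep = "\x1f")
    first <- !duplicated(key)
    fac <- factor(key, levels = key[first])
    prov_all <- c(a$provenance, b$provenance)
    n_all <- c(a$n_raw, b$n_raw)
    df <- data.frame(subject = subject[first], object = object[first],
                     stringsAsFactors = FALSE)
    df$provenance <- I(unname(lapply(split(prov_all, fac), function(ps) {
      sort_cp(unique(unlist(ps)))
    })))
    df$n_raw <- as.integer(vapply(split(n_all, fac), sum, numeric(1)))
    df <- df[order_cp(df$subject, df$object), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(edges) <- PREDICATES
  labels <- sort_cp(unique(c(x$nodes$label, y$nodes$label)))
  role <- function(g, lab, r) {
    i <- match(lab, g$nodes$label)
    out <- !is.na(i) & g$nodes[[r]][ifelse(is.na(i), 1L, i)]
    out
  }
  nodes <- data.frame(
    label = labels,
    category = role(x, labels, "category") | role(y, labels, "category"),
    preferred = role(x, labels, "preferred") | role(y, labels, "preferred"),
    synonym = role(x, labels, "synonym") | role(y, labels, "synonym"),
    stringsAsFactors = FALSE
  )
  pre <- list(
    category_mentions = x$pre$category_mentions + y$pre$category_mentions,
    preferred_mentions = x$pre$preferred_mentions + y$pre$preferred_mentions,
    records = x$pre$records + y$pre$records,
    relations_raw = x$pre$relations_raw + y$pre$relations_raw
  )
  new_integrated_graph(x$domain, nodes, edges, pre,
                       skipped = x$skipped + y$skipped)
}

#' Count terms in an integrated graph
#'
#' Distinct labels per role, plus the combined tally used by the summary
#' report: the number of distinct labels having the category or the preferred
#' role (synonym-only labels are excluded from the combined tally).
#'
#' @param graph an `integrated_graph`.
#' @return named list with `category`, `preferred`, `synonym`, `combined`.
#' @export
count_terms <- function(graph) {
  stopifnot(inherits(graph, "integrated_graph"))
  n <- graph$nodes
  list(category = sum(n$category),
       preferred = sum(n$preferred),
       synonym = sum(n$synonym),
       combined = sum(n$category | n$preferred))
}

#' Count relations of one predicate
#'
#' @param graph an `integrated_graph`.
#' @param predicate one of `"subClassOf"`, `"hasSynonym"`,
#'   `"correspondenceOf"`, `"isDefinedBy"`.
#' @param dedup if `TRUE` (default) the number of distinct (subject, object)
#'   pairs after integration; if `FALSE` the pre-integration total, i.e. the
#'   sum of per-record multiplicities.
#' @return integer count.
#' @export
count_relations <- function(graph, predicate, dedup = TRUE) {
  stopifnot(inherits(graph, "integrated_graph"))
  if (!predicate %in% PREDICATES) {
    stop("count_relations: unknown predicate '", predicate, "'")
  }
  if (dedup) nrow(graph$edges[[predicate]])
  else sum(graph$edges[[predicate]]$n_raw)
}

# role lookup helpers used by checks
node_roles <- function(graph, label) {
  i <- match(label, graph$nodes$label)
  if (is.na(i)) return(character())
  r <- graph$nodes[i, , drop = FALSE]
  c("category", "preferred", "synonym")[c(r$category, r$preferred, r$synonym)]
}

labels_with_roles <- function(graph, roles) {
  n <- graph$nodes
  keep <- Reduce(`|`, lapply(roles, function(r) n[[r]]))
  n$label[keep]
}
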