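# IRI and serialization machinery. Labels are minted as IRIs by
# percent-encoding the normalized label under a per-domain namespace, so the
# IRI is a pure function of the label (label identity is the merge key).

NS_SCHEMA <- "http://termaudit.org/schema#"
NS_TERM <- "http://termaudit.org/term/"
NS_GRAPH <- "http://termaudit.org/graph/"
NS_STMT <- "http://termaudit.org/stmt/"
NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"

RDF_PREFIXES <- c(ta = NS_SCHEMA, term = NS_TERM, graph = NS_GRAPH,
                  stmt = NS_STMT, rdf = NS_RDF, rdfs = NS_RDFS)

enc_label <- function(label) {
  vapply(label, function(l) utils::URLencode(l, reserved = TRUE), character(1),
         USE.NAMES = FALSE)
}

term_iri <- function(label, domain) paste0(NS_TERM, domain, "/", enc_label(label))

decode_term_iri <- function(iri) {
  rest <- sub(paste0("^", NS_TERM, "(device|patient)/"), "", iri)
  out <- utils::URLdecode(rest)
  Encoding(out) <- "UTF-8"  # URLdecode leaves the encoding unmarked
  out
}

pred_iri <- function(predicate) {
  switch(predicate,
         subClassOf = paste0(NS_RDFS, "subClassOf"),
         isDefinedBy = paste0(NS_RDFS, "isDefinedBy"),
         hasSynonym = paste0(NS_SCHEMA, "hasSynonym"),
         correspondenceOf = paste0(NS_SCHEMA, "correspondenceOf"),
         stop("unknown predicate: ", predicate))
}

PRED_FROM_IRI <- c(stats::setNames("subClassOf", paste0(NS_RDFS, "subClassOf")),
                   stats::setNames("isDefinedBy", paste0(NS_RDFS, "isDefinedBy")),
                   stats::setNames("hasSynonym", paste0(NS_SCHEMA, "hasSynonym")),
                   stats::setNames("correspondenceOf",
                                   paste0(NS_SCHEMA, "correspondenceOf")))

# Predicates whose objects are term nodes (IRIs); others take literal objects.
OBJECT_IS_NODE <- c(subClassOf = TRUE, hasSynonym = TRUE,
                    correspondenceOf = FALSE, isDefinedBy = FALSE)

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[k], "", fixed = TRUE)[[1]]
    buf <- character(); i <- 1L; n <- length(chars)
    while (i <= n) {
      if (chars[i] == "\\" && i < n) {
        nxt <- chars[i + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", '"' = '"', nxt))
        i <- i + 2L
      } else {
        buf <- c(buf, chars[i]); i <- i + 1L
      }
    }
    out[k] <- paste(buf, collapse = "")
  }
  out
}

lit <- function(x) paste0('"', escape_literal(x), '"')
iri <- function(x) paste0("<", x, ">")

#' Serialize an integrated graph to RDF
#'
#' Emits the graph as Turtle or N-Triples. Hierarchy edges use the standard
#' `rdfs:subClassOf` predicate, definitions use `rdfs:isDefinedBy` with the
#' definition sentence as a literal object, and `hasSynonym` /
#' `correspondenceOf` live in the project namespace. Node roles are emitted as
#' `rdf:type` triples and each term node carries an `rdfs:label`. Edge
#' provenance (the contributing terminology IDs) and the pre-integration raw
#' multiplicity are carried by standard RDF reification of each statement, so
#' [import_rdf()] can reconstruct the graph exactly. Statement ordering is
#' deterministic (sorted by subject, predicate, object code points).
#'
#' @param graph an `integrated_graph`.
#' @param format `"turtle"` or `"ntriples"`.
#' @param path optional file path; if given the text is written there (UTF-8).
#' @return the serialized text as a single string (invisibly when `path` is
#'   given).
#' @export
export_rdf <- function(graph, format = c("turtle", "ntriples"), path = NULL) {
  stopifnot(inherits(graph, "integrated_graph"))
  format <- match.arg(format)
  dom <- graph$domain
  triples <- list()
  add <- function(s, p, o) triples[[length(triples) + 1L]] <<- c(s, p, o)

  add(iri(paste0(NS_GRAPH, dom)), iri(paste0(NS_SCHEMA, "problemDomain")), lit(dom))

  role_class <- c(category = "CategoryTerm", preferred = "PreferredTerm",
                  synonym = "SynonymTerm")
  for (i in seq_len(nrow(graph$nodes))) {
    node <- graph$nodes[i, ]
    s <- iri(term_iri(node$label, dom))
    add(s, iri(paste0(NS_RDFS, "label")), lit(node$label))
    for (r in names(role_class)) {
      if (node[[r]]) add(s, iri(paste0(NS_RDF, "type")),
                         iri(paste0(NS_SCHEMA, role_class[[r]])))
    }
  }
  for (p in PREDICATES) {
    ed <- graph$edges[[p]]
    if (!nrow(ed)) next
    p_iri <- iri(pred_iri(p))
    for (i in seq_len(nrow(ed))) {
      s <- iri(term_iri(ed$subject[i], dom))
      o <- if (OBJECT_IS_NODE[[p]]) iri(term_iri(ed$object[i], dom))
           else lit(ed$object[i])
      add(s, p_iri, o)
      st <- iri(paste0(NS_STMT, dom, "/", p, "/",
                       enc_label(ed$subject[i]), "/", enc_label(ed$object[i])))
      add(st, iri(paste0(NS_RDF, "type")), iri(paste0(NS_RDF, "Statement")))
      add(st, iri(paste0(NS_RDF, "subject")), s)
      add(st, iri(paste0(NS_RDF, "predicate")), p_iri)
      add(st, iri(paste0(NS_RDF, "object")), o)
      for (tid in ed$provenance[[i]]) {
        add(st, iri(paste0(NS_SCHEMA, "provenance")), lit(tid))
      }
      add(st, iri(paste0(NS_SCHEMA, "rawCount")), lit(as.character(ed$n_raw[i])))
    }
  }
  m <- do.call(rbind, triples)
  m <- m[order_cp(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  lines <- if (format == "ntriples") {
    paste(m[, 1], m[, 2], m[, 3], ".")
  } else {
    header <- sprintf("@prefix %s: <%s> .", names(RDF_PREFIXES), RDF_PREFIXES)
    body <- paste(prefixize(m[, 1]), prefixize(m[, 2]), prefixize(m[, 3]), ".")
    c(header, "", body)
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, con <- file(path, open = "w", encoding = "UTF-8"), sep = "")
    close(con)
    return(invisible(text))
  }
  text
}

# Replace full IRIs by prefixed names where the local part is a safe PN_LOCAL
# (we keep percent escapes, letters, digits, and a few safe chars).
prefixize <- function(x) {
  is_iri <- startsWith(x, "<")
  out <- x
  bare <- substr(x, 2, nchar(x) - 1L)
  for (px in names(RDF_PREFIXES)) {
    ns <- RDF_PREFIXES[[px]]
    hit <- is_iri & startsWith(bare, ns)
    if (!any(hit)) next
    local <- substring(bare[hit], nchar(ns) + 1L)
    # only clean local names become prefixed (valid Turtle PN_LOCAL);
    # percent-encoded term IRIs stay in <...> form
    ok <- grepl("^[A-Za-z][A-Za-z0-9_]*$", local)
    out[hit][ok] <- paste0(px, ":", local[ok])
  }
  out
}

deprefixize <- function(tok) {
  if (startsWith(tok, "<")) return(substr(tok, 2, nchar(tok) - 1L))
  i <- regexpr(":", tok, fixed = TRUE)
  px <- substr(tok, 1, i - 1L)
  if (!px %in% names(RDF_PREFIXES)) stop("unknown prefix: ", px)
  paste0(RDF_PREFIXES[[px]], substring(tok, i + 1L))
}

# Tokenize one triple line of our own Turtle/N-Triples dialect into
# (subject, predicate, object-token). Objects may be quoted literals
# containing escaped quotes.
tokenize_triple <- function(line, lineno) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  toks <- character(); buf <- character()
  in_q <- FALSE; esc <- FALSE
  for (ch in chars) {
    if (in_q) {
      buf <- c(buf, ch)
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == '"') in_q <- FALSE
    } else if (ch == '"') {
      buf <- c(buf, ch); in_q <- TRUE
    } else if (ch == " " || ch == "\t") {
      if (length(buf)) { toks <- c(toks, paste(buf, collapse = "")); buf <- character() }
    } else {
      buf <- c(buf, ch)
    }
  }
  if (length(buf)) toks <- c(toks, paste(buf, collapse = ""))
  if (length(toks) < 4L || toks[length(toks)] != ".") {
    stop(sprintf("RDF parse error at line %d: expected 'S P O .'", lineno))
  }
  toks[-length(toks)]
}

#' Parse RDF produced by [export_rdf()] back into an integrated graph
#'
#' Supports the Turtle and N-Triples dialect this package writes (one triple
#' per line, optional `@prefix` header). Provenance and raw multiplicities are
#' recovered from the reified statements.
#'
#' @param text serialized RDF as a single string, or `NULL` when `path` given.
#' @param format `"turtle"` or `"ntriples"` (auto-detected from `@prefix`
#'   lines when omitted).
#' @param path optional file to read instead of `text`.
#' @return an `integrated_graph` equal to the exported one.
#' @export
import_rdf <- function(text = NULL, format = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("import_rdf: give `text` or `path`")
    text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  subj <- pred <- obj <- character()
  for (k in seq_along(lines)) {
    ln <- stringi::stri_trim_both(lines[k])
    if (!nzchar(ln) || startsWith(ln, "@prefix")) next
    toks <- tokenize_triple(ln, k)
    subj <- c(subj, deprefixize(toks[1]))
    pred <- c(pred, deprefixize(toks[2]))
    o <- toks[3]
    obj <- c(obj, if (startsWith(o, '"')) {
      paste0("\x1eL", unescape_literal(substr(o, 2, nchar(o) - 1L)))
    } else {
      paste0("\x1eI", deprefixize(o))
    })
  }
  obj_kind <- substr(obj, 2, 2)
  obj_val <- substring(obj, 3)

  dom_i <- which(pred == paste0(NS_SCHEMA, "problemDomain"))
  if (length(dom_i) != 1L) stop("import_rdf: missing problemDomain triple")
  dom <- obj_val[dom_i]

  # nodes from rdf:type triples on term IRIs
  type_i <- which(pred == paste0(NS_RDF, "type") &
                    startsWith(subj, NS_TERM) & obj_kind == "I")
  node_lab <- vapply(subj[type_i], decode_term_iri, character(1), USE.NAMES = FALSE)
  node_role <- obj_val[type_i]
  nodes <- make_nodes(
    category = node_lab[node_role == paste0(NS_SCHEMA, "CategoryTerm")],
    preferred = node_lab[node_role == paste0(NS_SCHEMA, "PreferredTerm")],
    synonym = node_lab[node_role == paste0(NS_SCHEMA, "SynonymTerm")]
  )

  # provenance / raw counts from reified statements
  stmt_i <- startsWith(subj, NS_STMT)
  stmt_sub <- stats::setNames(obj_val[stmt_i & pred == paste0(NS_RDF, "subject")],
                              subj[stmt_i & pred == paste0(NS_RDF, "subject")])
  stmt_prd <- stats::setNames(obj_val[stmt_i & pred == paste0(NS_RDF, "predicate")],
                              subj[stmt_i & pred == paste0(NS_RDF, "predicate")])
  stmt_obj <- stats::setNames(obj[stmt_i & pred == paste0(NS_RDF, "object")],
                              subj[stmt_i & pred == paste0(NS_RDF, "object")])
  prov_i <- stmt_i & pred == paste0(NS_SCHEMA, "provenance")
  prov_by_stmt <- split(obj_val[prov_i], subj[prov_i])
  raw_i <- stmt_i & pred == paste0(NS_SCHEMA, "rawCount")
  raw_by_stmt <- stats::setNames(as.integer(obj_val[raw_i]), subj[raw_i])

  stmt_key <- stats::setNames(paste(stmt_sub, stmt_prd, stmt_obj[names(stmt_sub)],
                                    sep = "\x1f"), names(stmt_sub))
  prov_by_key <- stats::setNames(lapply(names(stmt_key), function(st) {
    sort_cp(unique(prov_by_stmt[[st]]))
  }), stmt_key)
  raw_by_key <- stats::setNames(raw_by_stmt[names(stmt_key)], stmt_key)

  edges <- lapply(PREDICATES, function(p) {
    pi <- pred_iri(p)
    sel <- which(pred == pi & startsWith(subj, NS_TERM))
    if (!length(sel)) return(empty_edge_df())
    s_lab <- vapply(subj[sel], decode_term_iri, character(1), USE.NAMES = FALSE)
    o_lab <- if (OBJECT_IS_NODE[[p]]) {
      vapply(obj_val[sel], decode_term_iri, character(1), USE.NAMES = FALSE)
    } else obj_val[sel]
    key <- paste(subj[sel], pi, obj[sel], sep = "\x1f")
    df <- data.frame(subject = s_lab, object = o_lab, stringsAsFactors = FALSE)
    df$provenance <- I(unname(prov_by_key[key]))
    df$n_raw <- as.integer(raw_by_key[key])
    df <- df[order_cp(df$subject, df$object), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(edges) <- PREDICATES
  pre_rel <- vapply(edges, function(e) sum(e$n_raw), numeric(1))
  new_integrated_graph(dom, nodes, edges,
                       pre = list(category_mentions = NA_integer_,
                                  preferred_mentions = NA_integer_,
                                  records = NA_integer_,
                                  relations_raw = pre_rel))
}

# Structural equality ignoring pre-integration bookkeeping (import cannot
# recover per-set tallies, only the raw relation totals).
graph_identical <- function(x, y) {
  isTRUE(all.equal(x$domain, y$domain)) &&
    isTRUE(all.equal(x$nodes, y$nodes, check.attributes = FALSE)) &&
    all(vapply(PREDICATES, function(p) {
      a <- x$edges[[p]]; b <- y$edges[[p]]
      nrow(a) == nrow(b) &&
        identical(a$subject, b$subject) && identical(a$object, b$object) &&
        identical(unclass(a$provenance), unclass(b$provenance)) &&
        identical(a$n_raw, b$n_raw)
    }, logical(1))) &&
    isTRUE(all.equal(as.numeric(x$pre$relations_raw),
                     as.numeric(y$pre$relations_raw)))
}
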