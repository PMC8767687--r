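# Brute-force oracles: independent, naive re-implementations of each check,
# written directly from the check definitions as exhaustive loops over roles,
# edges and label tuples. They share no code with the package internals.

rr <- function(tid, dom, cat, pref, syn = character(), def = NA_character_,
               ncit = character()) {
  term_record(tid, dom, cat, pref, synonym_labels = syn, definition_text = def,
              cdrh_ncit_labels = ncit)
}

one_set <- function(tid, ...) terminology_set(tid, list(...))

# two-set chain: 故障 -> バッテリ不良 -> 早期放電 with the middle label used
# as category in one set and preferred in the other
chain_sets <- function() list(
  one_set("S1", rr("S1", "device", "故障", "バッテリ不良")),
  one_set("S2", rr("S2", "device", "バッテリ不良", "早期放電"))
)

# flatten a graph's subclass edges to a plain two-column data.frame
sub_edges <- function(g) g$edges$subClassOf[, c("subject", "object")]

oracle_dual_role_patterns <- function(g) {
  n <- g$nodes
  dual <- n$label[n$category & n$preferred]
  sub <- g$edges$subClassOf
  out <- list()
  for (t in dual) {
    parents <- unique(sub$object[sub$subject == t])
    children <- unique(sub$subject[sub$object == t])
    if (!length(parents)) parents <- NA_character_
    if (!length(children)) children <- NA_character_
    for (p in parents) for (ch in children) {
      out[[length(out) + 1L]] <- c(p, t, ch)
    }
  }
  out
}

oracle_swap_patterns <- function(g) {
  syn <- g$edges$hasSynonym
  n <- g$nodes
  out <- list()
  for (x in unique(syn$object)) {
    if (!any(n$label == x & n$preferred)) next
    ps <- unique(syn$subject[syn$object == x])
    ss <- unique(syn$object[syn$subject == x])
    if (!length(ss)) ss <- NA_character_
    for (p in ps) for (s in ss) out[[length(out) + 1L]] <- c(p, x, s)
  }
  out
}

oracle_multiplicity <- function(g, predicate, transform = identity) {
  ed <- g$edges[[predicate]]
  res <- list()
  for (s in unique(ed$subject)) {
    m <- length(unique(transform(ed$object[ed$subject == s])))
    if (m >= 2L) res[[s]] <- m
  }
  res
}

oracle_cross_domain <- function(gd, gp) {
  pick <- function(g) g$nodes$label[g$nodes$category | g$nodes$preferred]
  sort(intersect(pick(gd), pick(gp)), method = "radix")
}

# exhaustive elementary-cycle enumeration for digraphs with <= 8 vertices:
# every subset, every rotation-fixed permutation, edge-checked
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

oracle_cycles <- function(from, to) {
  verts <- sort(unique(c(from, to)), method = "radix")
  stopifnot(length(verts) <= 8L)
  has_edge <- function(a, b) any(from == a & to == b)
  found <- list()
  for (k in seq_along(verts)) {
    for (subset in utils::combn(seq_along(verts), k, simplify = FALSE)) {
      labs <- verts[subset]
      # fix smallest as start so each cycle is generated once per rotation
      for (tail in perms(labs[-1L])) {
        cyc <- c(labs[1L], tail)
        ok <- TRUE
        for (i in seq_along(cyc)) {
          nxt <- if (i == length(cyc)) cyc[1L] else cyc[i + 1L]
          if (!has_edge(cyc[i], nxt)) { ok <- FALSE; break }
        }
        if (ok) found[[length(found) + 1L]] <- cyc
      }
    }
  }
  key <- vapply(found, function(cy) sprintf("%09d\x1f%s", length(cy),
                                            paste(cy, collapse = "\x1f")),
                character(1))
  found[order(key, method = "radix")]
}

# random terminology sets over a small shared label pool, so that dual roles,
# swaps, polyhierarchy, duplicate definitions/mappings and cycles all arise
# by collision
random_sets <- function(seed, n_sets = 4L, n_records = 10L, pool_size = 12L) {
  set.seed(seed)
  pool <- sprintf("w%02d", seq_len(pool_size))
  defs <- sprintf("def %d.", 1:4)
  maps <- sprintf("target %d", 1:4)
  lapply(seq_len(n_sets), function(si) {
    recs <- lapply(seq_len(n_records), function(i) {
      rr(sprintf("R%02d", si), sample(c("device", "patient"), 1L),
         sample(pool, 1L), sample(pool, 1L),
         syn = sample(pool, sample(0:2, 1L)),
         def = if (stats::runif(1) < 0.7) sample(defs, 1L) else NA_character_,
         ncit = sample(maps, sample(0:2, 1L)))
    })
    terminology_set(sprintf("R%02d", si), recs)
  })
}

pattern_strings <- function(lst) {
  sort(vapply(lst, function(p) paste(p, collapse = "\x1f"), character(1)),
       method = "radix")
}

finding_pattern_strings <- function(cr, cols) {
  f <- cr$findings
  if (!nrow(f)) return(character())
  sort(do.call(paste, c(lapply(cols, function(cn) f[[cn]]), sep = "\x1f")),
       method = "radix")
}
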