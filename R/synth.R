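#' Configuration for the synthetic terminology generator
#'
#' Describes a synthetic corpus of two-level terminology sets shaped like the
#' JFMDA 1st edition (both problem domains per set; each preferred term with
#' synonyms, one definition and one CDRH-NCIt mapping) plus planted, countable
#' inconsistencies. Every planted structure is built from a vocabulary pool
#' disjoint from the background vocabulary and from every other pool, so the
#' checks cannot interfere and the generator can predict each check's result
#' exactly. Generation is a pure function of the config (same seed, same
#' output).
#'
#' @param seed integer RNG seed.
#' @param n_terminologies number of terminology sets.
#' @param n_categories_per_set background category terms per set and domain.
#' @param n_preferred_per_category background preferred terms per category.
#' @param n_synonyms_per_preferred synonyms attached to each background
#'   preferred term.
#' @param dual_role number of planted category/preferred dual-role terms
#'   (check 1).
#' @param swaps number of planted preferred/synonym swap pairs (check 2); each
#'   pair flags 2 terms.
#' @param multi_parent,multi_parent_multiplicity number of planted preferred
#'   terms with several category parents, and how many parents each gets
#'   (check 3).
#' @param multi_definition,multi_definition_multiplicity analogous for
#'   definitions (check 4).
#' @param multi_mapping,multi_mapping_multiplicity analogous for CDRH-NCIt
#'   targets (check 5).
#' @param cross_domain number of planted terms used in both problem domains
#'   (check 6).
#' @param cycle_lengths integer vector of planted subclass-cycle lengths
#'   (1 = self edge, 2 = hypernym/hyponym inversion, ...). Cycle labels are
#'   necessarily dual-role terms; the bookkeeping accounts for that overlap.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_terminologies = 6L,
                         n_categories_per_set = 4L,
                         n_preferred_per_category = 3L,
                         n_synonyms_per_preferred = 1L,
                         dual_role = 0L,
                         swaps = 0L,
                         multi_parent = 0L, multi_parent_multiplicity = 3L,
                         multi_definition = 0L, multi_definition_multiplicity = 2L,
                         multi_mapping = 0L, multi_mapping_multiplicity = 2L,
                         cross_domain = 0L,
                         cycle_lengths = integer()) {
  cfg <- list(seed = as.integer(seed),
              n_terminologies = as.integer(n_terminologies),
              n_categories_per_set = as.integer(n_categories_per_set),
              n_preferred_per_category = as.integer(n_preferred_per_category),
              n_synonyms_per_preferred = as.integer(n_synonyms_per_preferred),
              dual_role = as.integer(dual_role),
              swaps = as.integer(swaps),
              multi_parent = as.integer(multi_parent),
              multi_parent_multiplicity = as.integer(multi_parent_multiplicity),
              multi_definition = as.integer(multi_definition),
              multi_definition_multiplicity = as.integer(multi_definition_multiplicity),
              multi_mapping = as.integer(multi_mapping),
              multi_mapping_multiplicity = as.integer(multi_mapping_multiplicity),
              cross_domain = as.integer(cross_domain),
              cycle_lengths = as.integer(cycle_lengths))
  counts <- unlist(cfg[c("n_terminologies", "n_categories_per_set",
                         "n_preferred_per_category", "n_synonyms_per_preferred",
                         "dual_role", "swaps", "multi_parent",
                         "multi_definition", "multi_mapping", "cross_domain")])
  if (any(counts < 0L)) stop("synth_config: counts must be >= 0")
  if (cfg$n_terminologies < 1L) stop("synth_config: need at least one terminology set")
  for (nm in c("multi_parent", "multi_definition", "multi_mapping")) {
    m <- cfg[[paste0(nm, "_multiplicity")]]
    if (cfg[[nm]] > 0L && m < 2L) {
      stop("synth_config: ", nm, "_multiplicity must be >= 2 (infeasible config)")
    }
  }
  if (length(cfg$cycle_lengths) && any(cfg$cycle_lengths < 1L)) {
    stop("synth_config: cycle lengths must be >= 1")
  }
  if (cfg$swaps > 0L && cfg$n_terminologies < 2L) {
    stop("synth_config: swaps need at least 2 terminology sets")
  }
  structure(cfg, class = "synth_config")
}

# opaque transliterated nonsense labels; `pool` keeps every planted structure
# in its own namespace so counts never interfere
tok <- function(pool, i, j = NULL) {
  if (is.null(j)) sprintf("%s%03d", pool, i) else sprintf("%s%03d x%02d", pool, i, j)
}

#' Generate synthetic terminology sets with planted inconsistencies
#'
#' Builds the background corpus described by the config, plants each requested
#' inconsistency as the minimal record pair (or tuple) that triggers exactly
#' one check, assigns planted records to terminology sets pseudo-randomly, and
#' returns the generator's bookkeeping: the counts every check must report on
#' this corpus. Planted structures live in the device domain (cross-domain
#' terms in both, by construction).
#'
#' @param config a [synth_config()].
#' @return list with elements `sets` (list of [terminology_set()]) and
#'   `expected` (bookkeeping: per domain the expected pattern/unique counts,
#'   maxima and canonical cycles).
#' @export
generate_terminologies <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  n_sets <- config$n_terminologies
  set_ids <- sprintf("S%02d", seq_len(n_sets))
  recs <- vector("list", n_sets)
  for (i in seq_len(n_sets)) recs[[i]] <- list()
  put <- function(set_i, r) recs[[set_i]][[length(recs[[set_i]]) + 1L]] <<- r
  rand_set <- function() sample.int(n_sets, 1L)
  two_sets <- function() sample.int(n_sets, 2L)

  # background: globally unique labels, one definition and mapping each
  for (si in seq_len(n_sets)) {
    for (dom in c("device", "patient")) {
      dcode <- if (dom == "device") "d" else "p"
      for (ci in seq_len(config$n_categories_per_set)) {
        cat_lab <- sprintf("bg %s s%02d cat%03d", dcode, si, ci)
        for (pi in seq_len(config$n_preferred_per_category)) {
          pref_lab <- sprintf("bg %s s%02d cat%03d pt%03d", dcode, si, ci, pi)
          syns <- if (config$n_synonyms_per_preferred > 0L) {
            sprintf("%s syn%02d", pref_lab, seq_len(config$n_synonyms_per_preferred))
          } else character()
          put(si, term_record(set_ids[si], dom, cat_lab, pref_lab,
                              synonym_labels = syns,
                              definition_text = sprintf("Definition of %s.", pref_lab),
                              cdrh_ncit_labels = sprintf("map %s", pref_lab)))
        }
      }
    }
  }

  # check 1: dual-role chains parent -> mid -> child (mid gets both roles)
  for (i in seq_len(config$dual_role)) {
    si <- rand_set(); sj <- rand_set()
    put(si, term_record(set_ids[si], "device", tok("dr par", i), tok("dr mid", i)))
    put(sj, term_record(set_ids[sj], "device", tok("dr mid", i), tok("dr chi", i)))
  }

  # check 2: swap pairs, planted in two different sets
  for (i in seq_len(config$swaps)) {
    ss <- two_sets()
    a <- tok("sw a", i); b <- tok("sw b", i)
    put(ss[1], term_record(set_ids[ss[1]], "device", tok("sw cat1", i), a,
                           synonym_labels = b))
    put(ss[2], term_record(set_ids[ss[2]], "device", tok("sw cat2", i), b,
                           synonym_labels = a))
  }

  # check 3: one preferred term under several category parents
  for (i in seq_len(config$multi_parent)) {
    pt <- tok("mp pt", i)
    for (j in seq_len(config$multi_parent_multiplicity)) {
      si <- rand_set()
      put(si, term_record(set_ids[si], "device", tok("mp cat", i, j), pt))
    }
  }

  # check 4: one preferred term with several distinct definitions
  for (i in seq_len(config$multi_definition)) {
    pt <- tok("md pt", i)
    for (j in seq_len(config$multi_definition_multiplicity)) {
      si <- rand_set()
      put(si, term_record(set_ids[si], "device", tok("md cat", i), pt,
                          definition_text = sprintf("Meaning %02d of %s.", j, pt)))
    }
  }

  # check 5: one preferred term mapped to several CDRH-NCIt targets
  for (i in seq_len(config$multi_mapping)) {
    si <- rand_set()
    put(si, term_record(set_ids[si], "device", tok("mm cat", i), tok("mm pt", i),
                        cdrh_ncit_labels = sprintf("mm target %03d %02d", i,
                                                   seq_len(config$multi_mapping_multiplicity))))
  }

  # check 6: same preferred label in both problem domains
  for (i in seq_len(config$cross_domain)) {
    si <- rand_set(); sj <- rand_set()
    xd <- tok("xd", i)
    put(si, term_record(set_ids[si], "device", tok("xd dcat", i), xd))
    put(sj, term_record(set_ids[sj], "patient", tok("xd pcat", i), xd))
  }

  # cycles: subclass loops of the requested lengths (labels become dual-role)
  cycles <- list()
  for (k in seq_along(config$cycle_lengths)) {
    L <- config$cycle_lengths[k]
    labs <- sprintf("cyc%02d n%02d", k, seq_len(L))
    for (j in seq_len(L)) {
      si <- rand_set()
      child <- labs[if (j == L) 1L else j + 1L]
      put(si, term_record(set_ids[si], "device", labs[j], child))
    }
    # detection walks child->parent, i.e. against the planting order; the
    # canonical rotation starts at the code-point-smallest label (labs[1])
    cycles[[k]] <- c(labs[1L], rev(labs[-1L]))
  }

  sets <- lapply(seq_len(n_sets), function(i) terminology_set(set_ids[i], recs[[i]]))

  n_cyc_terms <- sum(config$cycle_lengths)
  expected <- list(
    device = list(
      dual_role = list(pattern_count = config$dual_role + n_cyc_terms,
                       unique_term_count = config$dual_role + n_cyc_terms,
                       identical_label_terms = sum(config$cycle_lengths == 1L)),
      swap = list(pattern_count = 2L * config$swaps,
                  unique_term_count = 2L * config$swaps),
      multi_parent = list(
        unique_term_count = config$multi_parent,
        max_multiplicity = if (config$multi_parent > 0L)
          config$multi_parent_multiplicity else NA_integer_),
      multi_definition = list(
        unique_term_count = config$multi_definition,
        max_multiplicity = if (config$multi_definition > 0L)
          config$multi_definition_multiplicity else NA_integer_),
      multi_mapping = list(
        unique_term_count = config$multi_mapping,
        max_multiplicity = if (config$multi_mapping > 0L)
          config$multi_mapping_multiplicity else NA_integer_),
      cycles = {
        key <- vapply(cycles, function(cy)
          sprintf("%09d\x1f%s", length(cy), paste(cy, collapse = "\x1f")),
          character(1))
        if (length(cycles)) cycles[order_cp(key)] else list()
      }
    ),
    patient = list(
      dual_role = list(pattern_count = 0L, unique_term_count = 0L,
                       identical_label_terms = 0L),
      swap = list(pattern_count = 0L, unique_term_count = 0L),
      multi_parent = list(unique_term_count = 0L, max_multiplicity = NA_integer_),
      multi_definition = list(unique_term_count = 0L, max_multiplicity = NA_integer_),
      multi_mapping = list(unique_term_count = 0L, max_multiplicity = NA_integer_),
      cycles = list()
    ),
    cross_domain = list(unique_term_count = config$cross_domain)
  )
  list(sets = sets, expected = expected)
}
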