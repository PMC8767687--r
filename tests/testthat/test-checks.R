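fx <- table_fixtures()

test_that("dual-role terms are flagged with one pattern per hierarchy context", {
  g <- build_graph(chain_sets(), "device")
  res <- check_dual_role(g)
  expect_identical(res$pattern_count, 1L)
  expect_identical(res$unique_term_count, 1L)
  expect_identical(res$findings$parent, "故障")
  expect_identical(res$findings$term, "バッテリ不良")
  expect_identical(res$findings$child, "早期放電")

  # single record with distinct levels: nothing to flag
  g1 <- build_graph(list(one_set("S1", rr("S1", "device", "A", "B"))), "device")
  expect_identical(check_dual_role(g1)$pattern_count, 0L)
})

test_that("dual-role patterns are the cross product of parents and children", {
  sets <- list(one_set("S1",
    rr("S1", "device", "p1", "T"), rr("S1", "device", "p2", "T"),
    rr("S1", "device", "T", "c1"), rr("S1", "device", "T", "c2"),
    rr("S1", "device", "T", "c3")))
  res <- check_dual_role(build_graph(sets, "device"))
  expect_identical(res$pattern_count, 6L)
  expect_identical(res$unique_term_count, 1L)
})

test_that("identical category and preferred labels carry the identical-label sub-flag", {
  g <- suppressMessages(build_graph(fx$table2, "device"))
  res <- check_dual_role(g)
  f <- res$findings
  expect_true(all(f$identical_label[f$term == "誤穿刺"]))
  expect_true(all(f$identical_label[f$term == "不明"]))
  expect_false(any(f$identical_label[f$term == "バッテリ不良"]))
  expect_setequal(res$unique_terms,
                  c("ヒューズ切れ", "アラーム異常", "不明", "バッテリ不良", "誤穿刺"))
})

test_that("preferred/synonym swaps are flagged from both directions", {
  sets <- list(one_set("S1", rr("S1", "device", "c1", "剥離", syn = "はがれ")),
               one_set("S2", rr("S2", "device", "c2", "はがれ", syn = "剥離")))
  res <- check_preferred_synonym_swap(build_graph(sets, "device"))
  pats <- finding_pattern_strings(res, c("preferred", "term", "synonym"))
  expect_true(paste("剥離", "はがれ", "剥離", sep = "\x1f") %in% pats)
  expect_setequal(res$unique_terms, c("剥離", "はがれ"))

  # a synonym that is never a preferred term is not a swap
  g <- build_graph(list(one_set("S1", rr("S1", "device", "c", "A", syn = "B"))),
                   "device")
  expect_identical(check_preferred_synonym_swap(g)$pattern_count, 0L)
})

test_that("a flagged term with no synonyms of its own yields an open pattern", {
  # X is preferred (with a definition, no synonyms) and a synonym of P
  sets <- list(one_set("S1", rr("S1", "device", "c1", "P", syn = "X")),
               one_set("S2", rr("S2", "device", "c2", "X", def = "d.")))
  res <- check_preferred_synonym_swap(build_graph(sets, "device"))
  expect_identical(res$pattern_count, 1L)
  expect_identical(res$findings$preferred, "P")
  expect_true(is.na(res$findings$synonym))
})

test_that("planted swap pairs in disjoint vocabulary count 2k unique terms", {
  for (k in c(1L, 3L, 5L)) {
    gen <- generate_terminologies(synth_config(seed = k, swaps = k))
    g <- build_graph(gen$sets, "device")
    res <- check_preferred_synonym_swap(g)
    expect_identical(res$unique_term_count, 2L * k)
    expect_identical(res$pattern_count, 2L * k)
  }
})

test_that("polyhierarchy check reproduces the published parent multiplicities", {
  g <- suppressMessages(build_graph(fx$table4, "device"))
  res <- check_multi_parent(g)
  expect_identical(res$max_multiplicity, 11L)
  f <- res$findings
  expect_identical(f$multiplicity[f$term == "変形"], 11L)
  expect_identical(f$multiplicity[f$term == "アーチファクト"], 2L)  # self-parent counts
  expect_true("アーチファクト" %in% f$parents[f$term == "アーチファクト"][[1]])

  gp <- suppressMessages(build_graph(fx$table4, "patient"))
  expect_identical(check_multi_parent(gp)$max_multiplicity, 7L)

  mono <- build_graph(list(one_set("S1", rr("S1", "device", "c1", "p1"),
                                   rr("S1", "device", "c2", "p2"))), "device")
  expect_identical(check_multi_parent(mono)$pattern_count, 0L)
})

test_that("definition distinctness is exact-string, punctuation significant", {
  g <- suppressMessages(build_graph(fx$table5, "patient"))
  res <- check_multi_definition(g)
  f <- res$findings
  expect_identical(f$multiplicity[f$term == "感染"], 8L)
  expect_identical(res$max_multiplicity, 8L)

  gd <- suppressMessages(build_graph(fx$table5, "device"))
  fd <- check_multi_definition(gd)$findings
  expect_identical(fd$multiplicity[fd$term == "ヒューズ切れ"], 2L)

  single <- build_graph(list(one_set("S1", rr("S1", "device", "c", "p", def = "only one."),
                                     rr("S1", "device", "c", "p", def = "only one."))),
                        "device")
  expect_identical(check_multi_definition(single)$pattern_count, 0L)
})

test_that("mapping check counts distinct CDRH-NCIt targets, case-sensitively by default", {
  g <- suppressMessages(build_graph(fx$table6, "patient"))
  res <- check_multi_mapping(g)
  f <- res$findings
  expect_identical(f$multiplicity[f$term == "穿孔"], 4L)
  expect_identical(f$multiplicity[f$term == "アレルギー反応"], 2L)
  expect_true("Vessels, perforation of" %in% f$targets[f$term == "穿孔"][[1]])

  gd <- suppressMessages(build_graph(fx$table6, "device"))
  strict <- check_multi_mapping(gd)$findings
  folded <- check_multi_mapping(gd, ignore_case = TRUE)$findings
  m_strict <- strict$multiplicity[strict$term == "変形"]
  m_folded <- folded$multiplicity[folded$term == "変形"]
  # case-insensitive counting merges the Material/material deformation pair
  labs <- fx$table6[[1]]$records[[4]]$cdrh_ncit_labels
  expect_identical(m_strict, length(unique(labs)))
  expect_identical(m_folded, length(unique(tolower(labs))))
  expect_lt(m_folded, m_strict)

  uniq <- build_graph(list(one_set("S1", rr("S1", "device", "c", "p", ncit = "one"))),
                      "device")
  expect_identical(check_multi_mapping(uniq)$pattern_count, 0L)
})

test_that("cross-domain check flags exactly the shared category/preferred labels", {
  gd <- suppressMessages(build_graph(fx$table7, "device"))
  gp <- suppressMessages(build_graph(fx$table7, "patient"))
  res <- check_cross_domain(gd, gp)
  expect_identical(res$unique_term_count, 8L)
  expect_setequal(res$unique_terms,
                  c("損傷", "汚染", "発熱", "感染", "感電",
                    "その他の事象", "その他", "不明"))

  # disjoint vocabularies
  a <- build_graph(list(one_set("S1", rr("S1", "device", "da", "db"))), "device")
  b <- build_graph(list(one_set("S1", rr("S1", "patient", "pa", "pb"))), "patient")
  expect_identical(check_cross_domain(a, b)$pattern_count, 0L)

  # synonym-only occurrence in one domain does not count
  a2 <- build_graph(list(one_set("S1", rr("S1", "device", "da", "db", syn = "X"))),
                    "device")
  b2 <- build_graph(list(one_set("S1", rr("S1", "patient", "pa", "X"))), "patient")
  expect_identical(check_cross_domain(a2, b2)$pattern_count, 0L)
})

test_that("hierarchy cycles are detected in canonical rotation", {
  gp <- suppressMessages(build_graph(fx$table2, "patient"))
  cys <- detect_hierarchy_cycles(gp)
  expect_identical(cys, list(c("外傷", "損傷")))

  acyclic <- build_graph(chain_sets(), "device")
  expect_identical(detect_hierarchy_cycles(acyclic), list())

  gen <- generate_terminologies(synth_config(seed = 5, cycle_lengths = 3L))
  g <- build_graph(gen$sets, "device")
  expect_identical(detect_hierarchy_cycles(g), gen$expected$device$cycles)
})

test_that("cycle enumeration agrees with brute force on random small digraphs", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(2:7, 1)
    verts <- sprintf("v%d", seq_len(n))
    m <- sample(1:12, 1)
    from <- sample(verts, m, replace = TRUE)
    to <- sample(verts, m, replace = TRUE)
    got <- termaudit:::find_cycles(from, to)
    want <- oracle_cycles(from, to)
    expect_identical(got, want,
                     label = sprintf("cycles on random digraph %d", i))
  }
})

test_that("checks are pure functions of the graph", {
  g <- suppressMessages(build_graph(random_sets(11), "device"))
  snapshot <- serialize(g, NULL)
  r1 <- check_dual_role(g)
  r2 <- check_dual_role(g)
  expect_identical(r1, r2)
  expect_identical(serialize(g, NULL), snapshot)
})

test_that("every check matches its brute-force oracle on random collision graphs", {
  for (seed in 1:12) {
    sets <- random_sets(seed, n_sets = 4L, n_records = 12L, pool_size = 10L)
    gd <- suppressMessages(build_graph(sets, "device"))
    gp <- suppressMessages(build_graph(sets, "patient"))
    for (g in list(gd, gp)) {
      expect_identical(
        finding_pattern_strings(check_dual_role(g), c("parent", "term", "child")),
        pattern_strings(oracle_dual_role_patterns(g)))
      expect_identical(
        finding_pattern_strings(check_preferred_synonym_swap(g),
                                c("preferred", "term", "synonym")),
        pattern_strings(oracle_swap_patterns(g)))
      mp <- check_multi_parent(g)
      want <- oracle_multiplicity(g, "subClassOf")
      expect_setequal(mp$findings$term, names(want))
      expect_identical(
        stats::setNames(mp$findings$multiplicity, mp$findings$term)[names(want)],
        vapply(want, as.integer, integer(1)))
      md <- check_multi_definition(g)
      expect_setequal(md$findings$term, names(oracle_multiplicity(g, "isDefinedBy")))
      mm <- check_multi_mapping(g)
      expect_setequal(mm$findings$term,
                      names(oracle_multiplicity(g, "correspondenceOf")))
      sub <- sub_edges(g)
      if (length(unique(c(sub$subject, sub$object))) <= 8L) {
        expect_identical(detect_hierarchy_cycles(g),
                         oracle_cycles(sub$subject, sub$object))
      }
    }
    expect_identical(check_cross_domain(gd, gp)$unique_terms,
                     oracle_cross_domain(gd, gp))
  }
})

test_that("unique term count never exceeds pattern count", {
  for (seed in 13:20) {
    g <- suppressMessages(build_graph(random_sets(seed), "device"))
    for (res in list(check_dual_role(g), check_preferred_synonym_swap(g))) {
      if (res$pattern_count > 0L) {
        expect_lte(res$unique_term_count, res$pattern_count)
      }
    }
  }
})

test_that("run_all_checks is deterministic and covers every check", {
  gen <- generate_terminologies(synth_config(seed = 2, dual_role = 2, swaps = 1,
                                             cross_domain = 2))
  gd <- build_graph(gen$sets, "device")
  gp <- build_graph(gen$sets, "patient")
  r1 <- run_all_checks(gd, gp)
  r2 <- run_all_checks(gd, gp)
  expect_identical(r1, r2)
  expect_named(r1, c("device", "patient", "cross_domain"))
  expect_named(r1$device, c("dual_role", "swap", "multi_parent",
                            "multi_definition", "multi_mapping", "cycles"))
})
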