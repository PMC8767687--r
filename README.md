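# termaudit

Integration and consistency auditing of two-level adverse-event terminologies.

## The problem

Adverse events involving medical devices are reported with controlled
vocabularies. In Japan, 89 per-device-group terminology sets (the JFMDA
terminology, 1st edition) were developed independently by 13 industry
associations. Each set is two-layered: **category terms** group **preferred
terms**; each preferred term carries synonyms, a definition sentence, and a
mapping to the CDRH-NCIt thesaurus, and every set covers two problem domains
(*medical device problems* and *patient problems*). Because the sets were
written independently, merging them "by term notation" — identical spellings
become one term — surfaces structural inconsistencies: the same label used as
both category and preferred term, preferred terms and synonyms exchanged
between sets, preferred terms under several parents, conflicting definitions
or mappings, and labels reused across the two problem domains.

`termaudit` is for terminology maintainers and medical-informatics
researchers who need to find these inconsistencies mechanically and report
them back to the source associations with provenance.

## The model

Each problem domain is merged into a labeled directed graph. Nodes are
normalized labels (Unicode NFC + edge-whitespace trim; width, case and
punctuation preserved) carrying role sets ⊆ {category, preferred, synonym}.
Edges, deduplicated by (subject, object) with the contributing terminology
IDs kept as provenance, use a fixed relation schema:

| relation | subject → object |
|---|---|
| `rdfs:subClassOf` | preferred term → category term |
| `hasSynonym` | preferred term → synonym |
| `correspondenceOf` | preferred term → CDRH-NCIt term |
| `rdfs:isDefinedBy` | preferred term → definition sentence (literal) |

Six checks then run natively on the graph(s):

1. **Dual-role terms** — labels with both the category and preferred role;
   one pattern per (parent, term, child) hierarchy context.
2. **Preferred/synonym swaps** — a synonym of one set that is a preferred
   term of another.
3. **Polyhierarchy** — preferred terms with ≥ 2 distinct category parents.
4. **Multiple definitions** — ≥ 2 exact-string-distinct definition sentences.
5. **Multiple mappings** — ≥ 2 distinct CDRH-NCIt targets.
6. **Cross-domain terms** — labels with category/preferred roles in *both*
   problem domains (the domains are never merged).

plus enumeration of all elementary `subClassOf` cycles (1-cycles = identical
labels at both levels, 2-cycles = hypernym/hyponym inversion between sets).

## Worked example

```r
library(termaudit)

fx <- table_fixtures()                      # published worked examples
g  <- build_graph(fx$table4, "device")      # polyhierarchy rows
check_multi_parent(g)
#> <check_result multi_parent [device]> 4 pattern(s), 4 unique term(s), max multiplicity 11
```

The maximum of 11 is 変形 (deformation), filed under 11 different category
terms by different industry associations. Auditing the full worked-example
corpus from the shipped CSV:

```r
sets <- read_terminology_table(
  system.file("extdata", "worked_examples.csv", package = "termaudit"))
dev <- build_graph(sets, "device")
pat <- build_graph(sets, "patient")
res <- run_all_checks(dev, pat)
res$cross_domain$unique_term_count
#> [1] 8
detect_hierarchy_cycles(pat)[[5]]
#> [1] "外傷" "損傷"
```

Eight labels (損傷, 汚染, 発熱, 感染, 感電, その他の事象, その他, 不明) are
used in both problem domains; the patient hierarchy contains four
identical-label self loops (cycles 1–4) and the 損傷/外傷 hypernym/hyponym
inversion shown above. `summarize_audit()` + `write_report()` turn the results into
JSON/CSV/markdown reports; `export_rdf()` writes Turtle or N-Triples so the
graph can be queried with any external SPARQL engine.

A command-line interface wraps the pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/termaudit.R", package="termaudit"))')" \
  audit --input my_terms.csv --out audit_out
```

Synthetic corpora with planted, exactly countable inconsistencies come from
`synth_config()` / `generate_terminologies()`; the generator returns the
bookkeeping every check must reproduce.

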