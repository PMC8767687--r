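---
title: "Integrating and auditing two-level adverse-event terminologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating and auditing two-level adverse-event terminologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termaudit)
```

## The integration model

`termaudit` merges many independently authored two-level terminology sets —
the motivating corpus is the 89 JFMDA medical-device adverse-event
terminologies, split per set into *medical device problems* and *patient
problems* — into one labeled graph per problem domain. The merge key is
**term notation**: two cells denote the same term exactly when their labels
are identical after normalization. This is the core modeling assumption, and
it cuts both ways: it deduplicates the large overlap between sets written by
the same association for similar device groups, and it is precisely what
makes notation-level inconsistencies (one spelling, two hierarchy positions)
visible as graph structure.

### Label normalization

`normalize_label()` applies Unicode canonical composition (NFC) and strips
leading/trailing whitespace including the ideographic space U+3000 — nothing
else. Width, case and punctuation are preserved by default because definition
and mapping distinctness in this corpus is evidently sensitive to them: among
the published examples, definitions of 感染 differing only by a trailing 。
count as different definitions, and CDRH-NCIt cells mix "Material
deformation" with "material deformation". Optional `width_fold` / `case_fold`
flags exist on `table_dialect()` for exploratory runs and
`check_multi_mapping(ignore_case = TRUE)` counts mapping targets
case-insensitively, but all defaults are strict.

### Relations and provenance

Each record (one category term / preferred term row with its synonyms,
definition and CDRH-NCIt mappings) contributes edges under four predicates:
`subClassOf` (preferred → category), `hasSynonym`, `correspondenceOf`, and
`isDefinedBy` (definition sentences as literal objects — checks only ever
need the per-term multiset of definition strings, so definitions are not
nodes). Duplicate (subject, object) pairs merge; the set of contributing
terminology IDs is kept per edge so every finding can name the sets that
disagree, which is what a maintainer needs to route corrections. Raw
(pre-integration) multiplicities are also kept, giving the before/after
relation tallies in the report.

The device and patient graphs are **never merged**: a shared notation denotes
a device subject in one domain and a patient subject in the other, and
merging would splice their hierarchies together. Cross-domain reuse is
instead a dedicated check (6).

## The checks

1. **Dual-role terms.** A label with both the category and the preferred role
   would create ≥ 3 hierarchy levels on integration. One *pattern* is emitted
   per distinct (parent, term, child) context — the row semantics of a
   SPARQL query joining the term's upward and downward subclass edges — so
   pattern counts exceed unique-term counts, often by a lot. A self edge
   (category = preferred in a single record) is flagged with the
   `identical_label` sub-flag.
2. **Preferred/synonym swaps.** A term that is a synonym in one set and a
   preferred term in another; patterns are (preferred, term, synonym)
   contexts, with an open right side when the flagged term has no synonyms of
   its own. Because it is genuinely ambiguous whether "unique terms" should
   count only the flagged terms or also their partners, the result reports
   both (`unique_term_count`, `extra$unique_term_count_with_partners`).
3. **Polyhierarchy.** Preferred terms with ≥ 2 distinct category parents
   after integration; self parents count (e.g. アーチファクト under itself
   and 異常画像).
4. **Multiple definitions** and 5. **multiple mappings.** Subjects with ≥ 2
   distinct objects under `isDefinedBy` / `correspondenceOf`, with the
   strict distinctness described above; results carry the per-term
   multiplicity and the domain maximum.
6. **Cross-domain terms.** Labels holding a category or preferred role in
   both domain graphs; synonym-only occurrences do not count.

**Cycles.** A consistently integrated hierarchy should be a DAG, so the
package enumerates all elementary `subClassOf` cycles with Johnson's
algorithm (igraph supplies the strongly-connected-component decomposition;
the circuit enumeration is implemented here because no installed R package
enumerates elementary cycles). Cycles are reported once each, rotated to
start at their code-point-smallest label: 1-cycles are identical-label
records, 2-cycles are hypernym/hyponym inversions between sets.

All checks are pure functions of the graph; findings are sorted by pattern
under byte-order (code point) collation, so repeated runs — and therefore
reports — are byte-identical.

## Reporting conventions

`summarize_audit()` reports, per domain, pre-/post-integration term and
relation tallies and per-check counts. Two conventions are the package's own
choices and are stated here because the source material does not pin them
down:

* **Pre-integration term tallies** are sums over terminology sets of the
  per-set distinct category (resp. preferred) labels, and the duplicate
  reduction is `100 × (1 − post/pre)` on the combined tally.
* **Percentages per check** use the domain's post-integration combined
  (category + preferred) term count as denominator; the published
  percentages are not exactly derivable from any printed denominator, so the
  report names its own.

Empty inputs produce an all-zero report with a `degenerate` flag rather than
NaN percentages.

## Table dialect decisions

Input is a seven-field UTF-8 CSV/TSV (terminology ID, problem domain,
category term, preferred term, synonyms, definition, CDRH-NCIt).
Since the original spreadsheets' intra-cell convention is not documented, the
synonym and CDRH-NCIt cells are parsed with a configurable delimiter
(default: comma) honoring double-quoted items, so `"Vessels, perforation
of"` stays one label; `table_dialect()` / a YAML dialect file also override
header spellings (Japanese headers are accepted by default) and the
problem-domain vocabulary. A repeated-row dialect (one row per synonym) is
collapsed on read. One deliberate looseness: a record listing its own
preferred term among its synonyms is kept as-is so `validate_records()` can
report it as an error instead of it being silently repaired.

## RDF export

`export_rdf()` mints term IRIs by percent-encoding the normalized label under
a per-domain namespace — the IRI is a pure function of the label because
label identity is the merge key — and writes Turtle or N-Triples with fully
deterministic statement ordering. Hierarchy edges use `rdfs:subClassOf`,
definitions `rdfs:isDefinedBy`; `hasSynonym` and `correspondenceOf` live in a
project namespace. Provenance and raw multiplicities ride on standard RDF
reification so `import_rdf()` reconstructs the graph exactly; the export is
plain RDF 1.1, usable in any external SPARQL engine. The importer
intentionally parses only the dialect the exporter writes (one triple per
line); it is a round-trip facility, not a general RDF parser.

## The synthetic generator

`generate_terminologies(synth_config(...))` emulates the corpus shape:
`n_terminologies` sets, each with both problem domains, two-level background
hierarchies, and synonyms/definitions/mappings per preferred term. Background
labels are globally unique opaque tokens, and every planted inconsistency
draws from its own disjoint token pool, realized as the minimal record tuple
that triggers exactly one check — so the generator can return exact expected
counts (`expected`) and any disagreement is a detector bug, not noise. One
planned overlap is handled explicitly: a planted cycle's labels are
necessarily dual-role terms, so the dual-role bookkeeping adds the cycle
lengths. Default shape parameters (6 sets, 4 categories × 3 preferred terms
per domain, 1 synonym each) keep a run in the hundreds of records — large
enough for collisions to matter, small enough that hundreds of randomized
configurations run in seconds.

What the generator does **not** emulate: the label-frequency distribution of
the real corpus, semantically plausible Japanese labels, and inconsistencies
that interact (in real data one term can trigger several checks at once; the
checks themselves are exercised on interacting inputs by the random
collision-graph tests instead). Passing the planted-recovery suite therefore
demonstrates detector correctness, not distributional realism.

## Numerical and degenerate-input choices

* Ordering everywhere is byte-order on UTF-8 (radix sort), which equals code
  point order and is locale-independent — reports cannot reorder between
  machines.
* A dual-role term missing one side of its context (possible only in
  hand-built graphs, since records always create a subclass edge) yields an
  `NA` placeholder on that side rather than being dropped.
* `build_graph()` skips records of the other domain with a message and a
  count, never an error, since every set mixes both domains in one file.
* Infeasible generator configs (negative counts, multiplicity < 2, swaps with
  a single set) fail at `synth_config()` time with a named reason.

## Test scale and limitations

The shipped tests run the worked-example fixtures (transcribed from the
published audit of the JFMDA 1st edition), brute-force oracle comparisons on
random collision graphs of ≤ 50 nodes, exhaustive-permutation cycle oracles
on digraphs of ≤ 7 vertices, and 200 randomized planted-recovery
configurations — a few seconds to a few tens of seconds in total. The
full-corpus tallies of the original study (e.g. 1840/1629 integrated terms)
require downloading the JFMDA workbook, which this package deliberately does
not bundle; the same pipeline ingests that layout directly (the
Japanese-header fixture exercises it). Known limitations: no semantic
judgment of which hierarchy level is correct, no repair suggestions, no
OWL/description-logic reasoning, and no multilingual mapping improvement —
the tool detects and lists, with provenance, and leaves remediation to the
terminology owners.
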