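---
title: "Tracking functional-annotation drift across knowledgebase releases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking functional-annotation drift across knowledgebase releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annodrift)
```

## What the package models

A curated protein knowledgebase is distributed as dated snapshots
("releases"). Each release holds protein entries — accession, chromosome,
protein-existence level PE1–PE5 — each carrying function annotations in
six curation categories (catalytic activity, free-text function summaries,
GO biological process, GO molecular function, pathway, transport
activity). An annotation optionally carries a controlled-vocabulary term
and is backed by evidence records; an evidence record has a kind (two
experimental kinds — direct assay and physical interaction — plus sequence
similarity, curator inference, author statement), a negative flag
(asserting the *absence* of a function), and usually a dated publication.
Some publication dates are known only to the year, and that granularity is
carried explicitly because it limits how confidently "which came first"
can be decided.

`annodrift` follows a series of such releases and asks four questions:
how functional coverage of PE1 proteins grew; which annotations were
later removed; which terms are trending; and whether protein binding is
typically the first function shown for a protein.

The package defines its own compact XML dialect for releases (schema:
`inst/extdata/release.xsd`) rather than any production dump format: the
analyses need only the fields above, and a self-contained dialect keeps
every stage generatable, parseable and testable at desk scale. Removal of
an annotation between releases is encoded as plain absence in the later
file — no tombstone element — mirroring how a consumer of real dumps
experiences curation: a record silently stops being there.

## The synthetic release generator

`generate_series()` produces a deterministic, seeded series of releases
plus an *emission log* recording every annotation (with creation and
removal release) and every evidence record. The log is the ground truth
that the diff, trend and primacy stages are tested against: parameter
recovery — the generator injects a known structure and the pipeline must
recover it exactly — is the central correctness property of the package.

What the defaults emulate:

* **Inventory.** `n_proteins = 100` entries, `pe1_fraction = 0.87` at
  PE1 (roughly the share of protein-level-validated entries in a mature
  human-protein knowledgebase); ~8% of proteins enter the inventory in a
  later release (new-entry events). Chromosome and PE level are fixed per
  protein.
* **Accrual.** New annotations per release are Poisson draws per category
  (`per_category_rates`); the default profile keeps the empirical order of
  a curated corpus — biological-process records most common, catalytic
  activity rarest — scaled down ~100×.
* **Terms.** Controlled terms come from a bundled flat GO-like vocabulary
  (no DAG). Annotations are controlled with probability 0.9, except
  free-text function summaries, which never carry terms. Among
  molecular-function terms, "protein binding" is drawn with weight 0.5:
  in real corpora binding dominates first annotations, and the trend and
  cloud stages need a dominant label to exercise their exclusion rule.
* **Removals.** Exactly `removal_count` annotations are deleted at a
  later release than they were created, and never targeted at the final
  release — every removal is observable as presence-then-absence.
* **Evidence.** Each annotation gets 1 + Poisson(0.6) evidence records;
  a record is experimental with probability `experimental_fraction`
  (default 0.4), carries a publication with probability 0.9, and the
  publication date is year-only with probability 0.15. Exactly
  `negative_evidence_count` negative records are injected on top.

What it deliberately does **not** emulate: GO term hierarchy (flat
vocabulary only), accession merges/splits or secondary accessions,
proteoforms, the delay between an experiment and its curation into a
release, and realistic absolute counts. Passing tests therefore show the
pipeline's *logic* is exact on structurally faithful data; they say
nothing about the absolute magnitudes a full-scale corpus would produce.

`generate_sequencing_fixture()` builds single-release fixtures in which
each protein's publication-date pattern instantiates one of the five
temporal-order classes exactly, with configurable multiplicities, spacing
and year-only fraction. When a year-only date lands in an order-sensitive
pattern, the two publications are pushed into different years so the
order still holds at year precision; `date_spacing = 0` combined with
year-only dates is an intentional-ambiguity fixture and warns.

## Diff semantics

* "Annotated" means ≥ 1 annotation record of any category, regardless of
  its evidence — release-level accounting precedes evidence filtering,
  which belongs to the primacy stage only.
* Removal cases are keyed on (accession, category, term), with term-less
  annotations keyed on their absent term; the unit is the *case*, not the
  protein. Re-addition after removal does not cancel a case, and each key
  is reported once, at its earliest disappearance.
* "Newly annotated in a window" means a run of being annotated *starts*
  at a release dated inside the window — either the protein's very first
  annotation, or reappearance after all its annotations had been removed.
* Chromosome labels are taken per release; if an accession's label
  changes across releases the latest release wins and the conflict is
  logged.

## Trend partition and tag-cloud scaling

Frequencies count distinct proteins first annotated with a term, not raw
annotation records: the object of interest is the per-protein function
profile. Since no principled universal threshold exists for "began to be
detected more/less frequently", the partition is parameterised and the
defaults are explicit choices: `r_hi = 1.5` (recent rate at least 1.5× the
lifetime rate), `r_lo = 0.67` (its reciprocal, symmetric on the log
scale), `min_count = 5` (below five lifetime proteins a ratio is noise).
Boundaries are inclusive on both sides.

Cloud scores are `x' = 1 + 19(x − x_min)/(x_max − x_min)`, computed after
removing excluded labels (default: "protein binding") so the excluded
dominant term does not compress everything else toward 1. When all
surviving frequencies are equal the transform is undefined; all scores
are set to 1, the conservative bottom of the range. The transform is
affine-invariant and strictly order-preserving.

## Primacy resolution and the five classes

Eligibility: positive (non-negative) evidence of an experimental kind,
with a publication dated inside the analysis window; a year-only date
qualifies when its year overlaps the window. Records without a
publication can never establish primacy and are dropped (with a warning
at the resolution step if dated records were expected).

Per (accession, category, term) the oldest publication wins; ties on date
break on the smallest publication id, and year-only dates sort at
January 1st of their year. Both rules exist for determinism: the output
is invariant under any permutation of the input, and resolving twice is
the identity.

Classification per protein: binding only / other only when one side is
absent; otherwise the earliest binding publication is compared with the
earliest other-function publication at the coarsest granularity of the
two dates (a year-only date neither strictly precedes nor follows a date
of the same year). A shared publication is "same publication". Equal
dates from *different* publications are genuinely undecidable; the
package resolves them as binding-first — the analysis's question is
whether binding tends to come first, so the undecidable case is assigned
to the class it cannot refute strictly — and logs every such protein
(attribute `date_ties`). "Binding" is one configurable controlled term
(default GO:0005515); descendant terms are not folded in, because the
vocabulary is deliberately flat, and free-text annotations can never be
the binding function while still counting as "other" functions.

Publication statistics are exact ratios over the bipartite
protein–publication graph of primacy records. Because it is ambiguous
whether "fraction of functions that are binding" should be over proteins
or over function records, both fractions are reported
(`binding_fraction_proteins`, `binding_fraction_records`), and the
pipeline reports both the classified-set size and the eligible-record
count so any gap between them is explicit.

## Determinism and problem sizes

All randomness flows through a single seed per generator call
(`withr::with_seed`), so a config is a complete recipe: the pipeline
rerun with the same config and seed reproduces its report bundle
byte-for-byte, and the manifest records a config hash rather than a
timestamp.

The shipped analysis runs on a synthetic decade of 10 releases × 400
proteins; the test suite exercises series up to 10 releases × 60
proteins, 100-release round-trip checks, 500-row primacy fixtures under
100 permutations, and 20 random classification scenarios with up to 50
proteins per class — sizes chosen so the whole suite stays fast while
every code path, boundary and tie rule is hit.

## Known limitations

* Accession-identity mapping only: merges, splits and renames are out of
  scope, and a renamed protein looks like a retirement plus a new entry.
* The flat vocabulary means trend and binding analyses cannot see that
  some terms are specialisations of others; binding-adjacent terms are
  counted as "other" functions, so the binding-first signal is, if
  anything, understated.
* Year-only publication dates cap the achievable temporal resolution;
  the package surfaces (rather than hides) the resulting ties.
* Removal detection reports what the files show — presence then absence —
  and cannot distinguish curation correction from reorganisation of a
  record into a different category, which appears as one removal case
  plus one new annotation.
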