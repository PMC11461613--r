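---
title: "Methods: harmonized target-disease coverage analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized target-disease coverage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetatlas)
```

## The problem and the model

GWAS registries describe diseases with free-text traits mapped to
research ontologies (EFO, MONDO, HP, ...); drug databases describe
indications with MeSH headings; biobank phenotypes arrive as ICD-10
codes. None of these speak to each other directly. `targetatlas`
anchors all of them in a UMLS-style concept space — each disease is a
concept identifier (CUI) under which synonymous terms from many source
vocabularies are merged — and then counts everything in that one space.

The unit of analysis is the target–indication pairing `(g, d)`: a gene
crossed with a disease concept. Every headline quantity is set
arithmetic over such pairs: exact products for bounded sample spaces,
exclusive membership patterns for intersections, and complements for
unmet-need lists. The central modelling assumptions are:

* a disease is a CUI, and two datasets talk about the same disease
  exactly when they map to the same CUI — granularity mismatches
  between source vocabularies are *not* repaired beyond synonym
  merging;
* a target is a gene (multiple ChEMBL-style target identifiers collapse
  to their gene);
* GWAS interrogate all genes by design, so GWAS coverage is a property
  of diseases, not of `(g, d)` pairs;
* a development stage attaches to a pairing through the per-indication
  maximum clinical phase, not the compound's global maximum, so one
  disease may legitimately sit at several stages.

## The mapping cascade

`map_traits()` tries routes in a fixed order and labels each trait with
the first productive one:

1. **curation overlay** — a declarative map from trait text to accepted
   CUIs (possibly empty, forcing unmapped). Manual curation normally
   happens *after* automation; applying it first instead makes the
   pipeline idempotent under curation, and the audit retains what
   automation would have said, so no information is lost.
2. **direct string match** — exact lookup of the normalized trait text
   over all synonyms.
3. **candidate resolution** — a deterministic candidate generator
   (exact matches plus token-subset matches with a two-token floor)
   followed by `resolve_candidates()`: direct matches win outright;
   otherwise candidates carrying the highest-priority semantic type
   present are kept, scanning *Disease or Syndrome* → *Neoplastic
   Process* → *Mental or Behavioral Dysfunction* → *Congenital
   Abnormality* → *Sign or Symptom* → *Finding* → *Laboratory
   Procedure* → *Injury or Poisoning* → *Individual Behavior* →
   *Diagnostic Procedure*; candidates typed entirely outside the list
   are returned unchanged. Ties within a tier are all kept — the
   observed many-to-one structure of trait-to-concept mappings is
   preserved rather than broken arbitrarily.
4. **DisGeNET-style crossmap** of the trait's mapped ontology terms.
5. **Metathesaurus-style crossmap** of the same terms.
6. **PubMed major-MeSH lookup** — only MeSH terms flagged as major
   terms of the source publication are consulted, each by direct string
   match.

The candidate generator of route 3 is deliberately a stand-in behind a
clean interface: concept-recognition tools (MetaMap and kin) are
licensed, server-bound and non-deterministic across releases. The
token-subset rule is transparent, reproducible at desk scale, and an
adapter for a real recognizer could replace it without touching the
resolution policy. The two-token floor exists because single-token
subset matches would attach every short synonym to every long trait
description.

ICD-10 phenotypes bypass string matching entirely: `map_icd10_traits()`
matches on the source *code* column, which is how coding-system
identifiers should be joined. Malformed codes are record-level errors,
not fatal ones.

`collapse_to_disease_set()` reduces mapping results to a unique disease
set. A disease is dropped only when its chapter set is a *subset* of
the excluded chapters ("Animal diseases", "Findings, not elsewhere
classified", "Pregnancy, childbirth and the puerperium") — a disease
also classified in a kept chapter survives. Concepts without chapter
coverage fall into an explicit "Unclassified" chapter rather than being
silently dropped. The per-chapter rollup counts a disease once per
*kept* chapter, so chapter counts may sum to more than the unique
count; excluded chapters do not reappear in the rollup.

## Normalization

`normalize_term()` is the only string transformation in the package:
case-fold, punctuation to spaces, whitespace collapsed, ends trimmed.
It is idempotent and does **no stemming** — stemming would merge terms
the source vocabularies keep distinct and would manufacture false
concept matches. Case-insensitivity is required because MeSH headings,
reported traits and synonym tables vary freely in capitalization; the
choice is recorded in the store's load report. Semantic-type names are
also compared case-insensitively, since releases disagree on
capitalization and spelling conventions for some type names.

## Drug-side processing

Compounds flagged withdrawn or not intended for human use are excluded
*before* any pairing, so they contribute to no count; the exclusion
report lists them, and exclusion plus survival partition the input
(checked in the manifest). Stage classification is a configurable
code-to-label table (default: 4 approved, 1–3 clinical, 0 preclinical)
because max-phase encodings have changed across database releases. The
druggable genome is a fixed input gene list; the stage partition's
complement identity — undrugged genes plus the union of staged genes
equals the druggable set — is asserted on every call, not just in
tests.

## Coverage arithmetic and numerical choices

* `sample_space()` is exact integer arithmetic in doubles with a hard
  error above 2^53 (~9×10^15), eight orders of magnitude above any
  genome-by-disease-ome grid; silent precision loss is never possible.
* `percent_round()` rounds **half-up** (base R's `round()` is
  half-even) because that is how report percentages are conventionally
  printed; report-level percentages use one decimal, figure-level ones
  zero.
* `membership_matrix()` computes exclusive membership patterns; the
  invariant that pattern counts sum to the union size is asserted on
  every call.
* Quartiles of targets-per-indication use the median-of-halves method
  with the median excluded from both halves at odd counts
  (Moore–McCabe): three diseases with 1, 2 and 4 targets give Q1 = 1,
  median = 2, Q3 = 4. Tukey hinges (which include the median in both
  halves) would print 1.5 and 3 for the same data; the exclusive
  variant is the one consistent with the reported quartile style this
  package reproduces. A single observation is its own median and both
  quartiles.
* Degenerate inputs are defined, not accidental: empty vocabulary files
  load as empty stores with a warning, an empty candidate set skips
  resolution, empty sets give an empty membership matrix, and an empty
  pair set is a hard error only where a distribution is requested.

## Opportunity lists

`opportunity_lists()` strata are defined on genes, which makes the
three lists disjoint by construction: *indication expansion* takes
genes with an approved drug (paired with GWAS diseases lacking an
approved pair — a clinical-stage pairing does not block expansion to
approval), *repurposing* takes genes with clinical or preclinical but
no approved history (paired with GWAS diseases not yet investigated for
that gene), and *de novo* takes druggable genes with no development
history at all. A gene that is both approved and in clinical
development contributes to indication expansion only. The explored-pair
key ignores stage — `(g, d)` is "explored" if any development stage
touched it — matching how unique investigated pairings are counted.

## The synthetic world

`generate_world()` emulates the *schemas* and *structural hazards* of
the real inputs, not their marginal distributions: MRCONSO/MRSTY
dialects, one-to-many trait-to-concept ambiguity with semantic-type
decoys, stage overlap among approved/clinical/preclinical targets,
multi-chapter disease classification, and traits whose only route to a
concept is a PubMed major MeSH term. Names come from a pronounceable
synthetic lexicon of globally unique words — never real disease names —
which both prevents any reliance on real-world string knowledge and
makes the truth ledger exact: token-subset matches occur precisely
where planted. `plant_edge_cases()` adds the boundary conditions
(withdrawn and non-human compounds, a two-stage disease, a
multi-chapter disease spanning an excluded chapter, a two-CUI trait, a
duplicated target identifier).

Defaults are 150 concepts, 200 traits, 40 compounds, 300 genes with a
120-gene druggable subset, ambiguity rate 0, and a stage mix of
0.35/0.40/0.25 over approved/clinical/preclinical — a desk-scale world
large enough that every cascade route, stage and edge case occurs with
comfortable multiplicity, and small enough that the full test suite
runs in well under a minute. Route probabilities (0.30/0.25/0.15/0.10/
0.20) keep the direct route commonest, as it is in practice. These
sizes were chosen once, before validation, and are not tuned.

What passing tests on this world shows: the cascade's ordering,
resolution policy, exclusions and set arithmetic are implemented
exactly, since recovery against the planted ledger is required to be
exact. What it does not show: robustness to real-world messiness —
misspellings, cross-vocabulary granularity mismatch, semantic drift
between ontology releases, or the heavy-tailed indication counts of
real drug databases. Headline counts from the real survey (612
approved-indication diseases, 1,914 GWAS diseases, and so on) depend on
licensed, release-pinned databases plus manual curation and are
documented as constants, not recomputed; what *is* recomputed exactly
is every arithmetic identity among them (see
`emit_reference_arithmetic()`).

## Determinism and provenance

All generator randomness flows from one root seed; bundle files carry a
header naming seed and generator version, and identical seed and
configuration produce byte-identical files. The pipeline itself is
deterministic given its inputs; `run_pipeline()` writes a manifest with
input checksums, per-stage row counts (conserving rows at every stage)
and accumulated record-level errors, and never embeds timestamps, so
report bundles are byte-reproducible too.

## Known limitations

* The concept store is version-agnostic; vocabulary version is metadata
  the caller tracks. Real surveys mix releases across steps, which the
  package neither requires nor repairs.
* `load_compound_indications()` keeps the first CUI when a MeSH term
  resolves to several; real MeSH-to-UMLS mapping is near-unique, and
  the synthetic world plants unique mappings, but a real multi-CUI term
  would be silently narrowed.
* No broader/narrower concept relations: a trait mapped to a parent
  concept and an indication mapped to its child count as different
  diseases.
* Disease prevalence, mortality and tractability are out of scope; the
  opportunity lists rank nothing, they enumerate qualifying pairs with
  provenance.
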