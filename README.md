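# targetatlas

Where do genome-wide association studies (GWAS) and pharmaceutical
research and development meet — and where do they miss each other?
`targetatlas` harmonizes the disease vocabularies used by GWAS
registries and drug databases into a single UMLS-anchored concept
space, partitions the druggable genome by development stage, and
computes the target-by-disease *sample spaces*, set intersections and
opportunity lists that quantify the coverage, overlap and divergence of
the two efforts.

It is written for computational drug-discovery and genetic-epidemiology
groups who want to reproduce, stress-test or extend this kind of
harmonization survey without licensed vocabulary releases: every stage
runs on schema-faithful synthetic inputs with planted ground truth, and
equally on real MRCONSO/MRSTY, ChEMBL-export and GWAS-Catalog-style
files.

## The analysis in brief

All counting happens over **target–indication pairings** `(g, d)`: a
gene `g` crossed with a disease concept `d`. With `T` targets and `D`
diseases, the bounded sample space has exactly `|T| × |D|` pairings,
and the *explored fraction* is the share of unique pairings that drug
development has actually touched:

```
explored% = 100 · |{(g, d) investigated}| / (|T| · |D|)
```

Four nested spaces are reported: **A** all protein-coding genes ×
all diseases (19,813 × 11,158 = 221,073,454), **B** the druggable
genome × all diseases (4,729 × 11,158 = 52,766,182), **C** clinically
investigated targets × clinically investigated indications
(1,218 × 1,401 = 1,706,418, of which 42,199 pairings — 2.5% — are
explored), and **D** approved targets × approved indications
(755 × 612 = 462,060, 1% explored).

Getting to those counts requires three harmonization steps, each a
module of the package:

* **Vocabulary store** (`read_mrconso()`, `lookup_exact()`): a concept
  store over pipe-delimited MRCONSO/MRSTY-dialect tables with
  normalized exact lookup from free text to concept identifiers (CUIs).
* **Trait mapping** (`map_traits()`, `map_icd10_traits()`,
  `collapse_to_disease_set()`): a five-route cascade from GWAS trait
  strings to concepts — direct string match, deterministic candidate
  generation resolved by a semantic-type priority policy, two ontology
  crossmaps, and the major MeSH terms of the source publication — plus
  exact ICD-10 code matching and chapter-based exclusions, all
  pre-emptable by a declarative curation overlay.
* **Drug pairing** (`load_compound_indications()`, `build_pairs()`,
  `partition_genome()`): ChEMBL-style exports to `(gene, disease,
  stage)` pairs, excluding withdrawn/non-human compounds, classifying
  stage from the per-indication max phase (4 approved, 1–3 clinical, 0
  preclinical), and partitioning the druggable genome into
  approved/clinical/preclinical/undrugged gene sets.

On top sit the coverage operations: `sample_space_report()`,
`membership_matrix()` (UpSet-style exclusive intersection counts),
`gwas_overlap_partition()`, `targets_per_indication_stats()`,
`indications_per_target_counts()` and `opportunity_lists()` (indication
expansion / repurposing / de novo prospects prioritized by GWAS disease
coverage). `run_pipeline()` orchestrates everything from one config
into a deterministic report bundle with a checksummed manifest.

## Worked example

The `analysis/` directory holds the numbered workflow. Step 1 simulates
a seeded miniature world (150 concepts, 201 traits, 44 compounds, 300
genes of which 120 druggable) with planted truth; steps 2–5 harmonize,
pair, and analyse it:

```sh
Rscript analysis/01_simulate_world.R
Rscript analysis/02_map_traits.R
Rscript analysis/03_pair_drugs.R
Rscript analysis/04_coverage.R
Rscript analysis/05_reference_arithmetic.R
```

Step 3 prints the exclusions and the genome partition:

```
Compounds: 44 in, 42 kept, 2 excluded (CPDN001, CPDW001)
Indications: 86 kept, 0 unmapped MeSH terms
<stage_partition> druggable 120: approved 14, clinical 17, preclinical 18, undrugged 86
Wrote 134 unique (gene, disease, stage) pairs to results/pairs.tsv
```

i.e. the two planted withdrawn/non-human compounds were dropped before
pairing, and 34 of the 120 druggable genes have been touched by some
development stage. Step 4 then reports the sample spaces:

```
  label n_targets n_diseases      size explored explored_pct
1 A         19813      11158 221073454      128          0
2 B           120      11158   1338960      128          0
3 C            17         25       425       61         14.4
4 D            14         22       308       41         13.3

GWAS / drug-development disease overlap:
  overlap 41, GWAS-only 16, development-only 3

Targets per approved indication: median 2 (Q1 1, Q3 2)
```

Space A uses the published universe denominators (19,813 protein-coding
genes, 11,158 disease terms), so the 128 explored synthetic pairings
round to 0% of it; spaces C and D are bounded by the synthetic world's
own clinical and approved sets. The overlap line says 41 of the 57
GWAS-mapped diseases are also in development, 16 await any drug
programme — the synthetic analogue of the survey's headline gap.

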