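Package: targetatlas
Title: Harmonized Target-Disease Coverage Analysis for Drug Development and GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes disease vocabularies into a UMLS-anchored concept
    space and computes the coverage, overlap and divergence of genome-wide
    association studies and pharmaceutical research and development.
    Provides a concept store over MRCONSO/MRSTY-dialect vocabulary tables,
    a multi-route cascade that maps GWAS trait strings and ICD-10
    phenotypes to disease concepts with a semantic-type priority
    resolution policy, readers for ChEMBL-style compound, target and
    indication exports with stage classification over the druggable
    genome, target-by-disease sample-space and set-intersection (UpSet)
    analyses, and opportunity lists for indication expansion, repurposing
    and de novo drug development. A seeded synthetic-world generator with
    a planted truth ledger makes every stage testable without licensed
    external releases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
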