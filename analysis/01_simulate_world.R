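#!/usr/bin/env Rscript
# Step 1: simulate the study inputs.
#
# Builds a seeded synthetic world -- vocabulary tables, GWAS trait file,
# ICD-10 phenotype list, ChEMBL-style drug tables, druggable gene list,
# chapter map, crossmaps and curation overlay -- with the edge cases the
# pipeline must survive (withdrawn/non-human compounds, a multi-stage
# disease, a multi-chapter disease, an ambiguous trait, a duplicated
# target identifier), and a truth ledger for validation downstream.

suppressPackageStartupMessages(library(targetatlas))

world_dir <- "results/world"
world <- generate_world(world_config(seed = 1L), world_dir)
world <- plant_edge_cases(world)

cat("Simulated world written to", world_dir, "\n")
print(world)
cat(sprintf("  planted traits by intended mapping route:\n"))
print(table(world$ledger$trait_truth$stage))
cat(sprintf("  planted target-indication pairs: %d (%d excluded compounds)\n",
            nrow(world$ledger$pair_truth),
            length(world$ledger$excluded_compounds)))
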