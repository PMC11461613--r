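#!/usr/bin/env Rscript
# Step 2: harmonize trait descriptions into the concept space.
#
# Loads the vocabulary, runs the five-route mapping cascade over the
# GWAS trait file plus the ICD-10 phenotype list, collapses results to a
# unique disease set with the chapter exclusions, and writes the
# per-trait mapping table. Run 01_simulate_world.R first.

suppressPackageStartupMessages(library(targetatlas))

world_dir <- "results/world"
store <- read_mrconso(file.path(world_dir, "MRCONSO.RRF"))
types <- read_semantic_types(file.path(world_dir, "MRSTY.RRF"))
store <- attach_semantic_types(store, types)
print(store)

traits <- read_gwas_traits(file.path(world_dir, "gwas_traits.tsv"))
crossmaps <- list(
  disgenet = read_crossmap(file.path(world_dir, "crossmap_disgenet.tsv"),
                           "disgenet"),
  metathesaurus = read_crossmap(
    file.path(world_dir, "crossmap_metathesaurus.tsv"), "metathesaurus"))
overlay <- read_overlay(file.path(world_dir, "overlay.yaml"))
mapped <- map_traits(traits, store, types, crossmaps, overlay)

cat("Traits mapped per cascade stage:\n")
print(table(mapped$stage))

icd10 <- readr::read_tsv(file.path(world_dir, "icd10_phenotypes.tsv"),
                         comment = "#", col_types = readr::cols(
                           .default = readr::col_character()))
icd_mapped <- map_icd10_traits(icd10$code, store)
cat(sprintf("ICD-10 codes mapped: %d / %d\n",
            sum(icd_mapped$stage == "icd10_code"), nrow(icd_mapped)))

chapters <- readr::read_tsv(file.path(world_dir, "chapter_map.tsv"),
                            comment = "#", col_types = readr::cols(
                              cui = readr::col_character(),
                              chapter = readr::col_character()))
gwas_set <- collapse_to_disease_set(list(mapped, icd_mapped), chapters)
cat(sprintf("Unique GWAS diseases after chapter exclusion: %d (%d excluded)\n",
            gwas_set$n_unique, length(gwas_set$excluded_diseases)))

dir.create("results", showWarnings = FALSE)
out <- mapped[, c("reported_trait", "stage", "n_cuis")]
out$cuis <- vapply(mapped$cuis, paste, character(1), collapse = "|")
readr::write_tsv(out, "results/trait_mappings.tsv")
writeLines(gwas_set$diseases, "results/gwas_disease_set.txt")
cat("Wrote results/trait_mappings.tsv and results/gwas_disease_set.txt\n")
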