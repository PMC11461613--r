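#!/usr/bin/env Rscript
# Step 3: build the target-indication pair set and partition the
# druggable genome by development stage.
#
# Applies the compound exclusions (withdrawn / not for human use), maps
# each indication's MeSH term into the concept space, crosses surviving
# compounds with their target genes, and classifies each pair by its
# per-indication phase. Run 01_simulate_world.R first.

suppressPackageStartupMessages(library(targetatlas))

world_dir <- "results/world"
store <- read_mrconso(file.path(world_dir, "MRCONSO.RRF"))
tables <- read_drug_tables(world_dir)
loaded <- load_compound_indications(tables, store)

rep <- loaded$report
cat(sprintf("Compounds: %d in, %d kept, %d excluded (%s)\n",
            rep$compounds_in, rep$compounds_kept, rep$compounds_dropped,
            paste(rep$dropped_ids, collapse = ", ")))
cat(sprintf("Indications: %d kept, %d unmapped MeSH terms\n",
            rep$indications_kept, rep$indications_unmapped))

genemap <- list(rows = tables$target_genes, druggable = tables$druggable,
                compound_targets = tables$compound_targets)
pairs <- build_pairs(loaded$indications, tables$compounds, genemap)
partition <- partition_genome(pairs, tables$druggable)
print(partition)

dir.create("results", showWarnings = FALSE)
readr::write_tsv(tibble::as_tibble(pairs), "results/pairs.tsv")
cat(sprintf("Wrote %d unique (gene, disease, stage) pairs to results/pairs.tsv\n",
            nrow(pairs)))
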