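test_that("withdrawn and non-human compounds are excluded before pairing", {
  world <- edge_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  tables <- read_drug_tables(world$dir)
  loaded <- load_compound_indications(tables, store)
  rep <- loaded$report
  expect_true(all(c("CPDW001", "CPDN001") %in% rep$dropped_ids))
  expect_false(any(loaded$indications$compound_id %in% rep$dropped_ids))
  expect_equal(rep$compounds_kept + rep$compounds_dropped,
               rep$compounds_in)
})

test_that("unmappable MeSH terms are flagged and excluded from pairs", {
  world <- plain_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  tables <- read_drug_tables(world$dir)
  tables$indications <- dplyr::bind_rows(
    tables$indications,
    tibble::tibble(compound_id = tables$compounds$compound_id[1],
                   mesh_term = "No Such Heading Anywhere",
                   max_phase_for_indication = 4L))
  loaded <- load_compound_indications(tables, store)
  expect_equal(sum(loaded$indications$unmapped), 1L)
  genemap <- list(rows = tables$target_genes, druggable = tables$druggable,
                  compound_targets = tables$compound_targets)
  pairs <- build_pairs(loaded$indications, tables$compounds, genemap)
  expect_false(any(is.na(pairs$cui)))
})

test_that("dangling compound ids are record-level errors, not fatal", {
  world <- plain_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  tables <- read_drug_tables(world$dir)
  tables$indications <- dplyr::bind_rows(
    tables$indications,
    tibble::tibble(compound_id = "CPD_GHOST", mesh_term = "x",
                   max_phase_for_indication = 2L))
  loaded <- load_compound_indications(tables, store)
  expect_equal(loaded$report$dangling_ids, "CPD_GHOST")
})

test_that("classify_stage follows the max-phase convention and rejects unknown codes", {
  expect_equal(classify_stage(4L), "approved")
  expect_equal(classify_stage(c(1L, 2L, 3L)), rep("clinical", 3))
  expect_equal(classify_stage(0L), "preclinical")
  expect_error(classify_stage(7L), "outside the convention")
  # a different release encoding via a custom convention table
  conv <- tibble::tibble(code = c(-1L, 9L), stage = c("preclinical",
                                                      "approved"))
  expect_equal(classify_stage(9L, conv), "approved")
})

test_that("build_pairs crosses compounds, targets and indications and de-duplicates", {
  store <- tiny_store()
  compounds <- tibble::tibble(
    compound_id = c("K1", "K2"), pref_name = c("a", "b"),
    max_phase = c(4L, 4L), withdrawn = 0L, human_use = 1L)
  genemap <- list(
    rows = tibble::tibble(target_id = c("T1", "T2"),
                          uniprot = c("P1", "P2"),
                          ensembl_gene = c("G1", "G2")),
    druggable = c("G1"),
    compound_targets = tibble::tibble(
      compound_id = c("K1", "K1", "K2"), target_id = c("T1", "T2", "T1")))
  indications <- tibble::tibble(
    compound_id = c(rep("K1", 3), "K2"),
    mesh_term = c("Blue Fever", "Crohn's Disease", "Grey Fever",
                  "Blue Fever"),
    cui = c("C1", "C2", "C3", "C1"),
    max_phase_for_indication = 4L,
    stage = "approved", unmapped = FALSE)
  pairs <- build_pairs(indications, compounds, genemap)
  # 2 targets x 3 indications = 6 approved pairs for K1; K2 duplicates
  # (G1, C1, approved) and adds nothing
  expect_equal(nrow(pairs), 6L)
  expect_equal(sum(pairs$druggable), 3L)
  # adding a compound never removes a pair (monotonicity)
  more_ind <- dplyr::bind_rows(indications, tibble::tibble(
    compound_id = "K3", mesh_term = "Grey Fever", cui = "C3",
    max_phase_for_indication = 2L, stage = "clinical", unmapped = FALSE))
  more_cmp <- dplyr::bind_rows(compounds, tibble::tibble(
    compound_id = "K3", pref_name = "c", max_phase = 2L, withdrawn = 0L,
    human_use = 1L))
  genemap$compound_targets <- dplyr::bind_rows(
    genemap$compound_targets,
    tibble::tibble(compound_id = "K3", target_id = "T2"))
  pairs2 <- build_pairs(more_ind, more_cmp, genemap)
  expect_true(all(paste(pairs$gene, pairs$cui, pairs$stage) %in%
                    paste(pairs2$gene, pairs2$cui, pairs2$stage)))
})

test_that("the per-indication phase, not the compound maximum, drives the stage", {
  world <- edge_world()
  run <- run_world_pipeline(world, key = "edge_run")
  # the planted multi-stage disease appears at both approved and clinical
  pt <- world$ledger$pair_truth
  multi <- dplyr::count(dplyr::distinct(pt[, c("cui", "stage")]), cui)
  cui_multi <- multi$cui[multi$n >= 2][1]
  stages <- sort(unique(run$pairs$stage[run$pairs$cui == cui_multi]))
  expect_gte(length(stages), 2L)
})

test_that("partition_genome obeys the complement identity on planted and empty inputs", {
  world <- plain_world()
  run <- run_world_pipeline(world, key = "plain_run")
  part <- run$partition
  drugged <- union(part$approved, union(part$clinical, part$preclinical))
  expect_equal(length(part$undrugged) + length(drugged),
               length(part$druggable))
  gs <- world$ledger$gene_stage_truth
  expect_setequal(part$approved, gs$gene[gs$stage == "approved"])
  expect_setequal(part$clinical, gs$gene[gs$stage == "clinical"])
  expect_setequal(part$preclinical, gs$gene[gs$stage == "preclinical"])
  expect_setequal(part$undrugged, world$ledger$undrugged_truth)

  empty <- partition_genome(run$pairs[0, ], c("g1", "g2"))
  expect_equal(empty$undrugged, c("g1", "g2"))
})

test_that("pair set equals the planted truth ledger", {
  world <- edge_world()
  run <- run_world_pipeline(world, key = "edge_run")
  got <- dplyr::arrange(tibble::as_tibble(run$pairs)[, c("gene", "cui",
                                                         "stage")],
                        gene, cui, stage)
  want <- dplyr::arrange(world$ledger$pair_truth, gene, cui, stage)
  expect_equal(got, want)
})
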