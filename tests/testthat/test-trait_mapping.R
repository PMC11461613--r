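test_that("candidate_concepts applies the exact and token-subset rules", {
  store <- tiny_store()
  # exact synonym
  expect_true("C2" %in% candidate_concepts("Crohn's disease", store))
  # token-subset: all synonym tokens inside the trait token set
  expect_true("C2" %in%
                candidate_concepts("severe crohn s disease pediatric",
                                   store))
  # the two-token floor blocks single-token traits without exact match
  expect_equal(candidate_concepts("fever", store), character(0))
  expect_equal(candidate_concepts("", store), character(0))
})

test_that("resolve_candidates prefers direct matches, then semantic-type priority", {
  store <- tiny_store()
  types <- tiny_types()
  # C3 (MSH "Grey Fever") and C4 both match "grey fever" exactly: both
  # are direct matches and both are kept
  cand <- candidate_concepts("grey fever", store)
  expect_equal(resolve_candidates("grey fever", cand, store, types),
               c("C3", "C4"))
  # no direct match: Disease or Syndrome beats Finding
  cand2 <- c("C3", "C4")
  expect_equal(
    resolve_candidates("grey fever outcome xyz", cand2, store, types),
    "C3")
  # candidates all typed outside the priority list come back unchanged
  p <- write_tmp_lines(c(mrsty_line("C3", "Organism Function"),
                         mrsty_line("C4", "Clinical Attribute")))
  off_list <- read_semantic_types(p)
  expect_equal(
    resolve_candidates("grey fever outcome xyz", cand2, store, off_list),
    c("C3", "C4"))
})

test_that("resolve_candidates never grows and never empties its input", {
  world <- ambiguous_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  types <- read_semantic_types(world$paths[["mrsty"]])
  lt <- world$ledger$trait_truth
  set.seed(4)
  pick <- sample(nrow(lt), 50)
  for (i in pick) {
    cand <- candidate_concepts(lt$reported_trait[i], store)
    if (length(cand) == 0L) next
    res <- resolve_candidates(lt$reported_trait[i], cand, store, types)
    expect_gt(length(res), 0L)
    expect_true(all(res %in% cand))
  }
})

test_that("the cascade maps each planted trait at its intended stage", {
  world <- plain_world()
  run <- run_world_pipeline(world, key = "plain_run")
  lt <- world$ledger$trait_truth
  m <- run$mapped_traits
  key <- match(lt$reported_trait, m$reported_trait)
  expect_false(anyNA(key))
  expect_equal(m$stage[key], lt$stage)
  hit <- mapply(function(i, tc) tc %in% m$cuis[[i]], key, lt$true_cui)
  expect_true(all(hit))
})

test_that("stage buckets partition the trait set", {
  world <- plain_world()
  run <- run_world_pipeline(world, key = "plain_run")
  m <- run$mapped_traits
  expect_equal(sum(table(m$stage)), nrow(m))
  expect_true(all((m$stage == "unmapped") == (m$n_cuis == 0L)))
})

test_that("a trait resolvable only via its PubMed major MeSH term gets that stage", {
  world <- plain_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  types <- read_semantic_types(world$paths[["mrsty"]])
  traits <- read_gwas_traits(world$paths[["traits"]])
  lt <- world$ledger$trait_truth
  i <- which(lt$stage == "pubmed_mesh_major")[1]
  res <- map_trait_cascade(traits[i, ], store, types)
  expect_equal(res$stage, "pubmed_mesh_major")
  expect_true(lt$true_cui[i] %in% res$cuis)
  # the non-major decoy MeSH term is not consulted
  decoy_terms <- traits$mesh_terms[[i]][!traits$mesh_major[[i]]]
  decoy_cuis <- unlist(lapply(decoy_terms, lookup_exact, store = store))
  expect_false(any(decoy_cuis %in% res$cuis))
})

test_that("overlay decisions pre-empt automation and keep the automatic audit", {
  store <- tiny_store()
  types <- tiny_types()
  trait <- list(reported_trait = "blue fever")
  ov <- structure(list(decisions = list("blue fever" = character(0))),
                  class = "curation_overlay")
  res <- map_trait_cascade(trait, store, types, overlay = ov)
  expect_equal(res$stage, "curation_overlay")
  expect_equal(res$cuis, character(0))
  expect_equal(res$audit$auto_stage, "direct_string")
  expect_equal(res$audit$auto_cuis, "C1")

  ov2 <- structure(list(decisions = list("blue fever" = "C2")),
                   class = "curation_overlay")
  res2 <- map_trait_cascade(trait, store, types, overlay = ov2)
  expect_equal(res2$cuis, "C2")
})

test_that("ICD-10 phenotypes map by source code, not string", {
  world <- plain_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  truth <- world$ledger$icd10_truth
  res <- map_icd10_traits(truth$code, store)
  expect_true(all(res$stage == "icd10_code"))
  expect_equal(unlist(res$cuis), truth$cui)

  res2 <- map_icd10_traits(c("Z99", "bad code", truth$code[1],
                             truth$code[1]), store)
  expect_equal(res2$stage[1], "unmapped")
  expect_match(res2$error[2], "malformed")
  # duplicates each get one identical result
  expect_identical(res2$cuis[[3]], res2$cuis[[4]])
})

test_that("collapse_to_disease_set drops only diseases exclusively in excluded chapters", {
  chapters <- tibble::tibble(
    cui = c("D1", "D2", "D3", "D3", "D4"),
    chapter = c("Kept A", "Animal diseases", "Animal diseases", "Kept A",
                "Kept B"))
  res <- collapse_to_disease_set(c("D1", "D2", "D3", "D4", "D5"), chapters)
  # D2 exclusively excluded; D3 in both an excluded and a kept chapter is
  # retained; D5 uncovered goes to Unclassified and is kept
  expect_setequal(res$diseases, c("D1", "D3", "D4", "D5"))
  expect_equal(res$excluded_diseases, "D2")
  expect_equal(res$n_unique, 4L)
  expect_equal(sort(res$rollup$chapter),
               sort(c("Kept A", "Kept B", "Unclassified")))
  expect_equal(res$rollup$n[res$rollup$chapter == "Kept A"], 2L)
})

test_that("the cascade is a pure function of its inputs", {
  world <- plain_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  types <- read_semantic_types(world$paths[["mrsty"]])
  traits <- read_gwas_traits(world$paths[["traits"]])[1:25, ]
  m1 <- map_traits(traits, store, types)
  m2 <- map_traits(traits, store, types)
  expect_identical(m1, m2)
})
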