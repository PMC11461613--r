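# Seeded synthetic-world generator.
#
# Emits a miniature, schema-faithful bundle of every input the pipeline
# consumes (MRCONSO/MRSTY-dialect vocabulary, ChEMBL-style drug tables,
# a GWAS-Catalog-style trait file, an ICD-10 phenotype list, a druggable
# gene list, chapter map, crossmap tables, curation overlay) together with
# a truth ledger recording the planted answer for every downstream stage.
#
# Concept and trait names are drawn from a pronounceable synthetic lexicon
# of globally unique words, never real disease names. Because every word
# is unique, token-subset matches happen exactly where the generator
# plants them, which is what makes the truth ledger exact.

GENERATOR_VERSION <- "1"

#' Configuration of a synthetic world
#'
#' @param seed Integer root seed; all randomness in [generate_world()] is
#'   derived from it.
#' @param n_concepts Number of vocabulary concepts.
#' @param n_traits Number of GWAS trait records.
#' @param ambiguity_rate Fraction in `[0, 1]` of traits planted with more
#'   than one candidate concept (a lower-priority decoy sharing tokens).
#' @param n_genes Number of genes in the gene universe.
#' @param n_druggable Number of druggable genes (must be `<= n_genes`).
#' @param n_compounds Number of compounds.
#' @param stage_mix Named proportions over approved/clinical/preclinical
#'   compounds; must sum to 1.
#' @param n_diseases Number of concepts designated indication diseases
#'   (must be `<= n_concepts`).
#' @param chapter_count Number of regular disease chapters.
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_concepts = 150L,
                         n_traits = 200L,
                         ambiguity_rate = 0,
                         n_genes = 300L,
                         n_druggable = 120L,
                         n_compounds = 40L,
                         stage_mix = c(approved = 0.35, clinical = 0.4,
                                       preclinical = 0.25),
                         n_diseases = 60L,
                         chapter_count = 8L) {
  cfg <- list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
              n_traits = as.integer(n_traits),
              ambiguity_rate = ambiguity_rate,
              n_genes = as.integer(n_genes),
              n_druggable = as.integer(n_druggable),
              n_compounds = as.integer(n_compounds),
              stage_mix = stage_mix, n_diseases = as.integer(n_diseases),
              chapter_count = as.integer(chapter_count))
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  counts <- c(cfg$n_concepts, cfg$n_traits, cfg$n_genes, cfg$n_druggable,
              cfg$n_compounds, cfg$n_diseases, cfg$chapter_count)
  if (any(counts < 0)) abort_fmt("world_config: all counts must be >= 0")
  if (cfg$ambiguity_rate < 0 || cfg$ambiguity_rate > 1) {
    abort_fmt("world_config: ambiguity_rate must lie in [0, 1]")
  }
  if (cfg$n_druggable > cfg$n_genes) {
    abort_fmt("world_config: n_druggable (%d) exceeds n_genes (%d)",
              cfg$n_druggable, cfg$n_genes)
  }
  if (!setequal(names(cfg$stage_mix),
                c("approved", "clinical", "preclinical"))) {
    abort_fmt("world_config: stage_mix needs approved/clinical/preclinical")
  }
  if (abs(sum(cfg$stage_mix) - 1) > 1e-9) {
    abort_fmt("world_config: stage_mix proportions must sum to 1 (got %g)",
              sum(cfg$stage_mix))
  }
  if (cfg$n_diseases > cfg$n_concepts) {
    abort_fmt("world_config: n_diseases exceeds n_concepts")
  }
  invisible(cfg)
}

#' Chapters excluded from the unique-disease rollup
#'
#' Diseases classified exclusively in these chapters are dropped when
#' collapsing mapping results to a disease set.
#'
#' @return Character vector of the three excluded chapter names.
#' @export
excluded_chapters <- function() {
  c("Animal diseases",
    "Findings, not elsewhere classified",
    "Pregnancy, childbirth and the puerperium")
}

# A pool of globally unique pronounceable words, consumed sequentially.
make_word_pool <- function(n) {
  syllables <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu",
                 "ne", "po", "ra", "su", "ti", "vo", "wa", "xe", "yo",
                 "zu", "qa", "bel", "cor", "dan", "fir", "gal")
  words <- character(0)
  while (length(words) < n) {
    k <- sample(2:3, n, replace = TRUE)
    batch <- vapply(k, function(m) {
      paste(sample(syllables, m, replace = TRUE), collapse = "")
    }, character(1))
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

new_word_taker <- function(pool) {
  idx <- 0L
  function(k) {
    out <- pool[(idx + 1L):(idx + k)]
    idx <<- idx + k
    if (anyNA(out)) abort_fmt("synthetic word pool exhausted")
    out
  }
}

title_case <- function(x) {
  sub("^(\\w)", "\\U\\1", x, perl = TRUE)
}

#' Generate a synthetic world
#'
#' Builds every pipeline input from scratch under `out_dir` and returns a
#' `synthetic_world` object carrying the in-memory tables, the file paths
#' and the truth ledger. The same seed and configuration always produce
#' byte-identical files.
#'
#' @param config A [world_config()].
#' @param out_dir Directory to write the bundle into (created if needed).
#' @return An object of class `synthetic_world` with elements `config`,
#'   `dir`, `paths`, `tables` and `ledger`.
#' @export
generate_world <- function(config = world_config(), out_dir) {
  validate_world_config(config)
  set.seed(config$seed)
  pool <- make_word_pool(6L * config$n_concepts + 4L * config$n_traits + 500L)
  take <- new_word_taker(pool)

  ## ---- concepts -------------------------------------------------------
  nc <- config$n_concepts
  cuis <- sprintf("C%06d", seq_len(nc))
  pref_names <- vapply(seq_len(nc), function(i) {
    paste(take(2L), collapse = " ")
  }, character(1))
  is_disease <- seq_len(nc) <= config$n_diseases
  disease_types <- c("Disease or Syndrome", "Neoplastic Process",
                     "Mental or Behavioral Dysfunction", "Sign or Symptom")
  other_types <- c("Finding", "Laboratory Procedure", "Finding",
                   "Diagnostic Procedure", "Clinical Attribute")
  sty <- character(nc)
  sty[is_disease] <- sample(disease_types, sum(is_disease), replace = TRUE,
                            prob = c(0.6, 0.2, 0.1, 0.1))
  sty[!is_disease] <- sample(other_types, sum(!is_disease), replace = TRUE)
  concepts <- tibble::tibble(cui = cuis, preferred = title_case(pref_names),
                             sty = sty, is_disease = is_disease)

  # Synonym rows: an MSH row per concept (term = preferred name); some
  # concepts also get a longer SNOMED-style synonym and an ICD-10 code.
  syn <- tibble::tibble(cui = cuis, sab = "MSH",
                        code = sprintf("D%06d", seq_len(nc)),
                        term = concepts$preferred)
  has_snomed <- runif(nc) < 0.4
  if (any(has_snomed)) {
    extra <- vapply(which(has_snomed), function(i) {
      paste(pref_names[i], take(1L))
    }, character(1))
    syn <- dplyr::bind_rows(syn, tibble::tibble(
      cui = cuis[has_snomed], sab = "SNOMEDCT_US",
      code = sprintf("S%07d", which(has_snomed)), term = title_case(extra)))
  }
  icd_pool <- which(is_disease)
  icd_n <- length(icd_pool)
  icd_codes <- sprintf("%s%02d", LETTERS[((seq_len(icd_n) - 1L) %% 26L) + 1L],
                       seq_len(icd_n))
  syn <- dplyr::bind_rows(syn, tibble::tibble(
    cui = cuis[icd_pool], sab = "ICD10", code = icd_codes,
    term = concepts$preferred[icd_pool]))
  icd10_truth <- tibble::tibble(code = icd_codes, cui = cuis[icd_pool])

  ## ---- chapters -------------------------------------------------------
  chapter_names <- sprintf("Synthetic chapter %02d", seq_len(config$chapter_count))
  disease_cuis <- cuis[is_disease]
  chap1 <- sample(chapter_names, length(disease_cuis), replace = TRUE)
  chapter_map <- tibble::tibble(cui = disease_cuis, chapter = chap1)
  multi <- runif(length(disease_cuis)) < 0.1
  if (any(multi) && config$chapter_count > 1L) {
    second <- vapply(which(multi), function(i) {
      sample(setdiff(chapter_names, chap1[i]), 1L)
    }, character(1))
    chapter_map <- dplyr::bind_rows(chapter_map, tibble::tibble(
      cui = disease_cuis[multi], chapter = second))
  }
  chapter_map <- dplyr::arrange(dplyr::distinct(chapter_map),
                                .data$cui, .data$chapter)

  ## ---- traits ---------------------------------------------------------
  nt <- config$n_traits
  routes <- c("direct_string", "candidate_resolved", "crossmap_disgenet",
              "crossmap_metathesaurus", "pubmed_mesh_major")
  route <- sample(routes, nt, replace = TRUE,
                  prob = c(0.3, 0.25, 0.15, 0.1, 0.2))
  if (nt >= length(routes)) route[seq_along(routes)] <- routes
  n_amb <- round(config$ambiguity_rate * nt)
  is_cand <- which(route == "candidate_resolved")
  if (n_amb > length(is_cand)) {
    extra_idx <- setdiff(seq_len(nt), is_cand)[seq_len(n_amb - length(is_cand))]
    route[extra_idx] <- "candidate_resolved"
    is_cand <- which(route == "candidate_resolved")
  }
  ambiguous <- rep(FALSE, nt)
  if (n_amb > 0L) ambiguous[sample(is_cand, n_amb)] <- TRUE

  finding_pool <- cuis[!is_disease & sty == "Finding"]
  if (n_amb > 0L && length(finding_pool) == 0L) {
    abort_fmt("world_config: ambiguity requires at least one Finding concept")
  }
  true_cui <- sample(disease_cuis, nt, replace = TRUE)

  trait_text <- character(nt)
  mapped_terms <- character(nt)
  mesh_terms <- character(nt)
  decoy_cui <- rep(NA_character_, nt)
  efo_ids <- sprintf("EFO:%07d", seq_len(nt))
  mondo_ids <- sprintf("MONDO:%07d", seq_len(nt))
  disgenet_rows <- list()
  meta_rows <- list()
  pref_of <- stats::setNames(concepts$preferred, concepts$cui)

  for (i in seq_len(nt)) {
    tc <- true_cui[i]
    base <- tolower(pref_of[[tc]])
    if (route[i] == "direct_string") {
      trait_text[i] <- pref_of[[tc]]
    } else if (route[i] == "candidate_resolved") {
      extra <- take(1L)
      if (ambiguous[i]) {
        decoy_cui[i] <- sample(finding_pool, 1L)
        trait_text[i] <- paste(base, tolower(pref_of[[decoy_cui[i]]]), extra)
      } else {
        trait_text[i] <- paste(base, extra)
      }
    } else {
      trait_text[i] <- take(1L)
      if (route[i] == "crossmap_disgenet") {
        mapped_terms[i] <- efo_ids[i]
        disgenet_rows[[length(disgenet_rows) + 1L]] <-
          tibble::tibble(term_id = efo_ids[i], cui = tc)
      } else if (route[i] == "crossmap_metathesaurus") {
        mapped_terms[i] <- mondo_ids[i]
        meta_rows[[length(meta_rows) + 1L]] <-
          tibble::tibble(term_id = mondo_ids[i], cui = tc)
      } else {
        decoy <- sample(setdiff(disease_cuis, tc), 1L)
        mesh_terms[i] <- paste0(pref_of[[tc]], "*;", pref_of[[decoy]])
      }
    }
  }
  traits <- tibble::tibble(
    reported_trait = trait_text,
    mapped_ontology_terms = mapped_terms,
    pubmed_id = sprintf("%08d", 30000000L + seq_len(nt)),
    study_mesh_terms = mesh_terms
  )
  trait_truth <- tibble::tibble(
    reported_trait = trait_text, true_cui = true_cui, stage = route,
    ambiguous = ambiguous, decoy_cui = decoy_cui
  )
  empty_xmap <- tibble::tibble(term_id = character(), cui = character())
  crossmap_disgenet <- if (length(disgenet_rows)) {
    dplyr::bind_rows(disgenet_rows)
  } else empty_xmap
  crossmap_meta <- if (length(meta_rows)) {
    dplyr::bind_rows(meta_rows)
  } else empty_xmap

  ## ---- ICD-10 phenotype list -----------------------------------------
  n_icd <- min(icd_n, max(3L, icd_n %/% 2L))
  icd_sel <- sort(sample(seq_len(icd_n), n_icd))
  icd10_phenotypes <- tibble::tibble(
    code = icd10_truth$code[icd_sel],
    description = concepts$preferred[icd_pool][icd_sel]
  )

  ## ---- genes, targets, compounds -------------------------------------
  genes <- sprintf("SG%05d", seq_len(config$n_genes))
  druggable <- genes[seq_len(config$n_druggable)]
  n_targets <- max(2L, min(config$n_druggable,
                           round(config$n_compounds * 1.2)))
  target_ids <- sprintf("T%04d", seq_len(n_targets))
  target_gene <- sample(druggable, n_targets,
                        replace = n_targets > config$n_druggable)
  target_genes <- tibble::tibble(
    target_id = target_ids,
    uniprot = sprintf("P%05d", seq_len(n_targets)),
    ensembl_gene = target_gene
  )

  ncmp <- config$n_compounds
  stage_lab <- sample(names(config$stage_mix), ncmp, replace = TRUE,
                      prob = config$stage_mix)
  max_phase <- ifelse(stage_lab == "approved", 4L,
                      ifelse(stage_lab == "clinical",
                             sample(1:3, ncmp, replace = TRUE), 0L))
  compounds <- tibble::tibble(
    compound_id = sprintf("CPD%04d", seq_len(ncmp)),
    pref_name = title_case(vapply(seq_len(ncmp), function(i) {
      paste(take(1L), "mab")
    }, character(1))),
    max_phase = as.integer(max_phase),
    withdrawn = 0L, human_use = 1L
  )
  compound_targets <- dplyr::bind_rows(lapply(seq_len(ncmp), function(i) {
    k <- sample(1:2, 1L)
    tibble::tibble(compound_id = compounds$compound_id[i],
                   target_id = sample(target_ids, min(k, n_targets)))
  }))
  indications <- dplyr::bind_rows(lapply(seq_len(ncmp), function(i) {
    k <- sample(1:3, 1L)
    d <- sample(disease_cuis, k)
    tibble::tibble(compound_id = compounds$compound_id[i],
                   mesh_term = unname(pref_of[d]),
                   max_phase_for_indication = compounds$max_phase[i])
  }))

  tables <- list(concepts = concepts, synonyms = syn,
                 chapter_map = chapter_map, traits = traits,
                 crossmap_disgenet = crossmap_disgenet,
                 crossmap_metathesaurus = crossmap_meta,
                 icd10_phenotypes = icd10_phenotypes,
                 compounds = compounds, compound_targets = compound_targets,
                 target_genes = target_genes, indications = indications,
                 genes = genes, druggable = druggable)
  ledger <- build_ledger(config, tables, trait_truth, icd10_truth)
  world <- structure(list(config = config, dir = out_dir,
                          paths = world_paths(out_dir), tables = tables,
                          ledger = ledger),
                     class = "synthetic_world")
  write_world(world)
  world
}

world_paths <- function(dir) {
  files <- c(
    mrconso = "MRCONSO.RRF", mrsty = "MRSTY.RRF",
    traits = "gwas_traits.tsv", icd10 = "icd10_phenotypes.tsv",
    crossmap_disgenet = "crossmap_disgenet.tsv",
    crossmap_metathesaurus = "crossmap_metathesaurus.tsv",
    overlay = "overlay.yaml", compounds = "compounds.csv",
    compound_targets = "compound_targets.csv",
    target_genes = "target_genes.csv", indications = "indications.csv",
    druggable = "druggable_genes.txt", chapter_map = "chapter_map.tsv",
    ledger = "truth_ledger.json"
  )
  stats::setNames(file.path(dir, files), names(files))
}

# Pair truth and gene-stage truth are derived directly from the generated
# tables (compound survivors x targets x indications), so planted edge
# cases update the ledger automatically on rebuild.
build_ledger <- function(config, tables, trait_truth, icd10_truth) {
  cmp <- tables$compounds
  excluded <- cmp$compound_id[cmp$withdrawn == 1L | cmp$human_use == 0L]
  surviving <- cmp[!(cmp$compound_id %in% excluded), ]
  pref_to_cui <- stats::setNames(tables$concepts$cui,
                                 tables$concepts$preferred)
  ind <- tables$indications
  ind <- ind[ind$compound_id %in% surviving$compound_id, ]
  ind$cui <- unname(pref_to_cui[ind$mesh_term])
  ind$stage <- stage_from_phase(ind$max_phase_for_indication)
  pairs <- dplyr::inner_join(ind, tables$compound_targets,
                             by = "compound_id",
                             relationship = "many-to-many")
  pairs <- dplyr::inner_join(pairs, tables$target_genes, by = "target_id",
                             relationship = "many-to-many")
  pair_truth <- dplyr::distinct(
    dplyr::select(pairs, gene = "ensembl_gene", "cui", "stage"))
  pair_truth <- dplyr::arrange(pair_truth, .data$gene, .data$cui, .data$stage)
  gene_stage_truth <- dplyr::distinct(
    dplyr::select(pair_truth, "gene", "stage"))
  undrugged <- setdiff(tables$druggable, unique(gene_stage_truth$gene))
  list(
    generator_version = GENERATOR_VERSION,
    seed = config$seed,
    trait_truth = trait_truth,
    icd10_truth = icd10_truth,
    pair_truth = pair_truth,
    gene_stage_truth = gene_stage_truth,
    undrugged_truth = sort(undrugged),
    disease_chapter_truth = tables$chapter_map,
    excluded_compounds = excluded
  )
}

stage_from_phase <- function(phase) {
  ifelse(phase == 4L, "approved", ifelse(phase >= 1L, "clinical",
                                         "preclinical"))
}

world_header <- function(world) {
  sprintf("# targetatlas synthetic world v%s seed=%d",
          GENERATOR_VERSION, world$config$seed)
}

tsv_lines <- function(df, header) {
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  c(header, paste(names(df), collapse = "\t"), body)
}

csv_lines <- function(df, header) {
  body <- do.call(paste, c(lapply(df, as.character), sep = ","))
  c(header, paste(names(df), collapse = ","), body)
}

write_world <- function(world) {
  dir.create(world$dir, showWarnings = FALSE, recursive = TRUE)
  p <- world$paths
  tb <- world$tables
  hdr <- world_header(world)

  syn <- dplyr::arrange(tb$synonyms, .data$cui, .data$sab, .data$code,
                        .data$term)
  conso <- vapply(seq_len(nrow(syn)), function(i) {
    f <- rep("", 18L)
    f[1] <- syn$cui[i]; f[2] <- "ENG"; f[12] <- syn$sab[i]
    f[14] <- syn$code[i]; f[15] <- syn$term[i]
    paste0(paste(f, collapse = "|"), "|")
  }, character(1))
  write_lines_utf8(c(hdr, conso), p[["mrconso"]])

  sty <- dplyr::arrange(tb$concepts, .data$cui)
  sty_rows <- vapply(seq_len(nrow(sty)), function(i) {
    f <- rep("", 6L)
    f[1] <- sty$cui[i]; f[4] <- sty$sty[i]
    paste0(paste(f, collapse = "|"), "|")
  }, character(1))
  write_lines_utf8(c(hdr, sty_rows), p[["mrsty"]])

  write_lines_utf8(tsv_lines(tb$traits, hdr), p[["traits"]])
  write_lines_utf8(tsv_lines(tb$icd10_phenotypes, hdr), p[["icd10"]])
  write_lines_utf8(tsv_lines(tb$crossmap_disgenet, hdr),
                   p[["crossmap_disgenet"]])
  write_lines_utf8(tsv_lines(tb$crossmap_metathesaurus, hdr),
                   p[["crossmap_metathesaurus"]])
  write_lines_utf8(c(hdr, "decisions: {}"), p[["overlay"]])
  write_lines_utf8(csv_lines(tb$compounds, hdr), p[["compounds"]])
  write_lines_utf8(csv_lines(tb$compound_targets, hdr),
                   p[["compound_targets"]])
  write_lines_utf8(csv_lines(tb$target_genes, hdr), p[["target_genes"]])
  write_lines_utf8(csv_lines(tb$indications, hdr), p[["indications"]])
  write_lines_utf8(c(hdr, tb$druggable), p[["druggable"]])
  write_lines_utf8(tsv_lines(tb$chapter_map, hdr), p[["chapter_map"]])

  ledger_json <- jsonlite::toJSON(world$ledger, dataframe = "rows",
                                  auto_unbox = TRUE, pretty = TRUE,
                                  na = "null")
  write_lines_utf8(as.character(ledger_json), p[["ledger"]])
  invisible(world)
}

#' Inject edge cases into a generated world
#'
#' Adds the boundary conditions the pipeline must handle: a withdrawn
#' compound, a compound not intended for human use, a disease indicated at
#' multiple development stages, a disease classified in multiple chapters
#' (one of them an excluded chapter), a trait matching two concepts of
#' different semantic types, and a gene encoded by two distinct target
#' identifiers. The truth ledger is rebuilt so the planted answers stay
#' exact, and the bundle files are rewritten.
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @return The modified `synthetic_world`.
#' @export
plant_edge_cases <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(world$config$seed + 101L)
  tb <- world$tables
  con <- tb$concepts
  disease_cuis <- con$cui[con$is_disease]
  pref_of <- stats::setNames(con$preferred, con$cui)

  # Withdrawn and non-human compounds, with indications that must never
  # reach any count.
  bad <- tibble::tibble(
    compound_id = c("CPDW001", "CPDN001"),
    pref_name = c("Withdrawnex", "Veterinex"),
    max_phase = c(4L, 2L),
    withdrawn = c(1L, 0L), human_use = c(1L, 0L)
  )
  tb$compounds <- dplyr::bind_rows(tb$compounds, bad)
  some_target <- tb$target_genes$target_id[1]
  tb$compound_targets <- dplyr::bind_rows(
    tb$compound_targets,
    tibble::tibble(compound_id = bad$compound_id, target_id = some_target))
  tb$indications <- dplyr::bind_rows(
    tb$indications,
    tibble::tibble(compound_id = bad$compound_id,
                   mesh_term = unname(pref_of[disease_cuis[1:2]]),
                   max_phase_for_indication = bad$max_phase))

  # One disease indicated at two stages: a phase-2 compound for a disease
  # that already has (or now gains) an approved indication.
  multi_cui <- disease_cuis[3]
  tb$compounds <- dplyr::bind_rows(
    tb$compounds,
    tibble::tibble(compound_id = c("CPDM001", "CPDM002"),
                   pref_name = c("Stagemab A", "Stagemab B"),
                   max_phase = c(4L, 2L), withdrawn = 0L, human_use = 1L))
  tb$compound_targets <- dplyr::bind_rows(
    tb$compound_targets,
    tibble::tibble(compound_id = c("CPDM001", "CPDM002"),
                   target_id = tb$target_genes$target_id[2]))
  tb$indications <- dplyr::bind_rows(
    tb$indications,
    tibble::tibble(compound_id = c("CPDM001", "CPDM002"),
                   mesh_term = unname(pref_of[multi_cui]),
                   max_phase_for_indication = c(4L, 2L)))

  # One disease in two chapters, one of them excluded: the subset rule
  # must retain it.
  chap_cui <- disease_cuis[4]
  tb$chapter_map <- dplyr::distinct(dplyr::bind_rows(
    tb$chapter_map,
    tibble::tibble(cui = chap_cui, chapter = excluded_chapters()[1])))
  tb$chapter_map <- dplyr::arrange(tb$chapter_map, .data$cui, .data$chapter)

  # A gene with two ChEMBL-style target IDs.
  dup_gene <- tb$target_genes$ensembl_gene[1]
  tb$target_genes <- dplyr::bind_rows(
    tb$target_genes,
    tibble::tibble(target_id = "TDUP01", uniprot = "P99999",
                   ensembl_gene = dup_gene))
  tb$compound_targets <- dplyr::bind_rows(
    tb$compound_targets,
    tibble::tibble(compound_id = tb$compounds$compound_id[1],
                   target_id = "TDUP01"))

  # A trait matching two CUIs of different semantic types; the ledger
  # records the winner under the default priority policy.
  true_c <- con$cui[con$is_disease][5]
  finding_pool <- con$cui[!con$is_disease & con$sty == "Finding"]
  decoy <- finding_pool[1]
  amb_text <- paste(tolower(pref_of[[true_c]]), tolower(pref_of[[decoy]]))
  tb$traits <- dplyr::bind_rows(
    tb$traits,
    tibble::tibble(reported_trait = amb_text, mapped_ontology_terms = "",
                   pubmed_id = "39999999", study_mesh_terms = ""))
  trait_truth <- dplyr::bind_rows(
    world$ledger$trait_truth,
    tibble::tibble(reported_trait = amb_text, true_cui = true_c,
                   stage = "candidate_resolved", ambiguous = TRUE,
                   decoy_cui = decoy))

  world$tables <- tb
  world$ledger <- build_ledger(world$config, tb, trait_truth,
                               world$ledger$icd10_truth)
  write_world(world)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> seed=%d: %d concepts, %d traits, %d compounds, %d genes\n",
    x$config$seed, x$config$n_concepts, nrow(x$tables$traits),
    nrow(x$tables$compounds), x$config$n_genes))
  cat("  dir:", x$dir, "\n")
  invisible(x)
}
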