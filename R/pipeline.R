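# End-to-end orchestration: vocabulary load -> trait mapping -> drug
# pairing -> coverage analysis -> deterministic report bundle with a
# provenance manifest.

#' Reference denominator constants
#'
#' The published universe sizes and headline counts used by the
#' printed-identity arithmetic checks: 19,813 protein-coding genes
#' (Ensembl v.108), 11,158 disease terms (Disease Ontology, 2022-09-29),
#' the 4,729-gene druggable genome and its stage partition, and the
#' disease/pairing counts of the source survey.
#'
#' @return Named list of constants.
#' @export
reference_constants <- function() {
  list(
    n_protein_coding = 19813,
    n_diseases_do = 11158,
    n_druggable = 4729,
    n_approved_targets = 755,
    n_clinical_targets = 1218,
    n_preclinical_targets = 418,
    n_investigated_targets = 1234,
    n_undrugged = 3495,
    n_approved_diseases = 612,
    n_clinical_diseases = 1401,
    n_preclinical_diseases = 210,
    n_devel_diseases = 1549,
    n_gwas_diseases = 1914,
    n_overlap_diseases = 703,
    explored_pairs_clinical = 42199,
    explored_pairs_approved = 5221,
    icd10_diseases_before_exclusion = 983,
    icd10_diseases_excluded = 30
  )
}

#' Printed-identity arithmetic checks
#'
#' Recomputes the twelve report identities from the denominator constants
#' through [sample_space()], [percent_round()] and set subtraction, and
#' marks each pass/fail: the four sample-space sizes A-D, the explored
#' fractions of C (2.5%) and D (1%), C as a share of B (3.2%) and of A
#' (0.8%), the undrugged complement (3495, 73.9%), the GWAS-only disease
#' count (1211), the development-coverage share (13.9%, with the GWAS
#' share 17.2%), and the chapter-exclusion rollup (953).
#'
#' @param constants A [reference_constants()] list; an empty list yields an
#'   empty table.
#' @return Tibble with columns `id`, `description`, `computed`,
#'   `expected`, `pass`.
#' @export
emit_reference_arithmetic <- function(constants = reference_constants()) {
  empty <- tibble::tibble(id = character(), description = character(),
                          computed = numeric(), expected = numeric(),
                          pass = logical())
  if (length(constants) == 0L) return(empty)
  k <- constants
  size_A <- sample_space(k$n_protein_coding, k$n_diseases_do)
  size_B <- sample_space(k$n_druggable, k$n_diseases_do)
  size_C <- sample_space(k$n_clinical_targets, k$n_clinical_diseases)
  size_D <- sample_space(k$n_approved_targets, k$n_approved_diseases)
  rows <- list(
    list("size_A", "gene universe x disease universe", size_A, 221073454),
    list("size_B", "druggable genome x disease universe", size_B, 52766182),
    list("size_C", "clinical targets x clinical indications", size_C,
         1706418),
    list("size_D", "approved targets x approved indications", size_D,
         462060),
    list("pct_explored_C", "explored share of space C",
         percent_round(k$explored_pairs_clinical, size_C, 1L), 2.5),
    list("pct_C_of_B", "space C as share of space B",
         percent_round(size_C, size_B, 1L), 3.2),
    list("pct_C_of_A", "space C as share of space A",
         percent_round(size_C, size_A, 1L), 0.8),
    list("pct_explored_D", "explored share of space D",
         percent_round(k$explored_pairs_approved, size_D, 0L), 1),
    list("undrugged_complement",
         "druggable minus clinically investigated targets",
         k$n_druggable - k$n_investigated_targets, 3495),
    list("gwas_only_diseases",
         "GWAS diseases minus development overlap",
         k$n_gwas_diseases - k$n_overlap_diseases, 1211),
    list("pct_devel_coverage",
         "development diseases as share of disease universe",
         percent_round(k$n_devel_diseases, k$n_diseases_do, 1L), 13.9),
    list("chapter_exclusion_kept",
         "unique diseases after excluded-chapter removal",
         k$icd10_diseases_before_exclusion - k$icd10_diseases_excluded, 953)
  )
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(id = r[[1]], description = r[[2]],
                   computed = as.numeric(r[[3]]),
                   expected = as.numeric(r[[4]]))
  }))
  out$pass <- out$computed == out$expected
  out
}

#' Build a run configuration
#'
#' Collects input paths, denominator constants, policy settings, the
#' output directory and the seed into a validated configuration. All
#' referenced files must exist at validation time, so a broken run aborts
#' before any output is written.
#'
#' @param input_dir Directory holding a world bundle (the file names of
#'   [generate_world()]), used as a default for every path.
#' @param out_dir Output directory for the report bundle.
#' @param paths Optional named overrides for individual input paths.
#' @param constants Denominator constants (gene and disease universe
#'   sizes); defaults to [reference_constants()].
#' @param policy A [resolution_policy()].
#' @param excluded Chapters excluded from disease rollups.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir,
                       paths = list(),
                       constants = reference_constants(),
                       policy = resolution_policy(),
                       excluded = excluded_chapters(),
                       seed = 1L) {
  p <- as.list(world_paths(input_dir))
  p$ledger <- NULL
  p[names(paths)] <- paths
  missing <- names(p)[!vapply(unlist(p), file.exists, logical(1))]
  if (length(missing) > 0L) {
    abort_fmt("run_config: missing input file(s): %s",
              paste(unlist(p[missing]), collapse = ", "))
  }
  if (constants$n_protein_coding <= 0 || constants$n_diseases_do <= 0) {
    abort_fmt("run_config: universe constants must be positive")
  }
  structure(list(paths = p, out_dir = out_dir, constants = constants,
                 policy = policy, excluded = excluded,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The document needs `input_dir` and `out_dir`; `seed`, `constants` and
#' `paths` overrides are optional.
#'
#' @param path Path to the configuration document.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_fmt("config file not found: %s", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  constants <- utils::modifyList(reference_constants(),
                                 doc$constants %||% list())
  run_config(doc$input_dir, doc$out_dir, paths = doc$paths %||% list(),
             constants = constants, seed = doc$seed %||% 1L)
}

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[targetatlas] ", fmt), ...))
}

write_tsv_out <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                        ~ vapply(.x, function(v) {
                                          paste(v, collapse = "|")
                                        }, character(1))))
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  write_lines_utf8(c(paste(names(df), collapse = "\t"), body), path)
}

#' Run the full coverage pipeline
#'
#' Executes vocabulary load, trait mapping (GWAS cascade and ICD-10
#' codes), drug pairing, genome partition and coverage analysis, and
#' writes a deterministic report bundle under the configured output
#' directory: per-trait mappings, the pair table, stage partition,
#' sample-space report, membership matrices for gene and disease sets,
#' the GWAS overlap, the three opportunity lists, the arithmetic checks
#' and a manifest with input checksums and per-stage row counts.
#' Identical configuration and inputs produce byte-identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `atlas_run` with every intermediate
#'   object and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$paths
  for (f in unlist(p)) {
    if (!file.exists(f)) abort_fmt("run_pipeline: input vanished: %s", f)
  }

  log_stage("loading vocabulary")
  store <- read_mrconso(p$mrconso)
  types <- read_semantic_types(p$mrsty)
  store <- attach_semantic_types(store, types)

  log_stage("mapping traits")
  traits <- read_gwas_traits(p$traits)
  crossmaps <- list(
    disgenet = read_crossmap(p$crossmap_disgenet, "disgenet"),
    metathesaurus = read_crossmap(p$crossmap_metathesaurus,
                                  "metathesaurus"))
  overlay <- read_overlay(p$overlay)
  mapped <- map_traits(traits, store, types, crossmaps, overlay,
                       config$policy)
  icd10 <- readr::read_tsv(p$icd10, comment = "#",
                           col_types = readr::cols(
                             .default = readr::col_character()))
  icd10_mapped <- map_icd10_traits(icd10$code, store)
  chapters <- readr::read_tsv(p$chapter_map, comment = "#",
                              col_types = readr::cols(
                                cui = readr::col_character(),
                                chapter = readr::col_character()))
  gwas_set <- collapse_to_disease_set(list(mapped, icd10_mapped), chapters,
                                      config$excluded)

  log_stage("pairing drugs")
  tables <- read_drug_tables(dirname(p$compounds))
  loaded <- load_compound_indications(tables, store)
  genemap <- list(rows = tables$target_genes,
                  druggable = tables$druggable,
                  compound_targets = tables$compound_targets)
  pairs <- build_pairs(loaded$indications, tables$compounds, genemap)
  partition <- partition_genome(pairs, tables$druggable)

  log_stage("coverage analysis")
  stage_dis <- function(stage) sort(unique(pairs$cui[pairs$stage == stage]))
  devel_diseases <- sort(unique(pairs$cui))
  overlap <- gwas_overlap_partition(gwas_set$diseases, devel_diseases)
  gene_matrix <- membership_matrix(list(
    approved = partition$approved, clinical = partition$clinical,
    preclinical = partition$preclinical))
  disease_matrix <- membership_matrix(list(
    approved = stage_dis("approved"), clinical = stage_dis("clinical"),
    preclinical = stage_dis("preclinical"), gwas = gwas_set$diseases))
  spaces <- sample_space_report(pairs, partition, list(
    n_protein_coding = config$constants$n_protein_coding,
    n_diseases = config$constants$n_diseases_do))
  approved_pairs <- pairs[pairs$stage == "approved", ]
  tpi <- if (nrow(approved_pairs) > 0L) {
    targets_per_indication_stats(approved_pairs)
  } else NULL
  ipt <- indications_per_target_counts(approved_pairs, chapters,
                                       threshold = 0L)
  opps <- opportunity_lists(partition, pairs, gwas_set$diseases)
  arithmetic <- emit_reference_arithmetic(config$constants)

  manifest <- list(
    package_version = as.character(utils::packageVersion("targetatlas")),
    seed = config$seed,
    inputs = as.list(tools::md5sum(unlist(p))),
    counts = list(
      vocabulary = store$load_report,
      traits_in = nrow(traits),
      traits_mapped = sum(mapped$stage != "unmapped"),
      traits_unmapped = sum(mapped$stage == "unmapped"),
      trait_stages = as.list(table(mapped$stage)),
      icd10_in = nrow(icd10_mapped),
      icd10_mapped = sum(icd10_mapped$stage == "icd10_code"),
      compounds = loaded$report[c("compounds_in", "compounds_kept",
                                  "compounds_dropped")],
      indications = loaded$report[c("indications_in", "indications_kept",
                                    "indications_unmapped")],
      pairs = nrow(pairs),
      gwas_diseases = gwas_set$n_unique,
      devel_diseases = length(devel_diseases)
    ),
    record_errors = list(
      dangling_compounds = loaded$report$dangling_ids,
      icd10_errors = icd10_mapped$error[!is.na(icd10_mapped$error)]
    )
  )

  log_stage("writing report bundle to %s", config$out_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_tsv_out(mapped[, c("reported_trait", "stage", "cuis", "n_cuis")],
                out("trait_mappings.tsv"))
  write_tsv_out(icd10_mapped, out("icd10_mappings.tsv"))
  write_tsv_out(pairs, out("pairs.tsv"))
  write_tsv_out(spaces, out("sample_spaces.tsv"))
  write_tsv_out(gene_matrix$patterns, out("gene_membership.tsv"))
  write_tsv_out(disease_matrix$patterns, out("disease_membership.tsv"))
  for (nm in names(opps)) {
    write_tsv_out(opps[[nm]], out(sprintf("opportunities_%s.tsv", nm)))
  }
  write_tsv_out(arithmetic, out("arithmetic_checks.tsv"))
  write_json_out <- function(x, f) {
    write_lines_utf8(as.character(jsonlite::toJSON(
      x, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")),
      out(f))
  }
  write_json_out(list(approved = partition$approved,
                      clinical = partition$clinical,
                      preclinical = partition$preclinical,
                      undrugged = partition$undrugged),
                 "stage_partition.json")
  write_json_out(overlap, "gwas_overlap.json")
  write_json_out(manifest, "manifest.json")

  invisible(structure(list(
    store = store, types = types, mapped_traits = mapped,
    icd10_mapped = icd10_mapped, gwas_diseases = gwas_set,
    indications = loaded, pairs = pairs, partition = partition,
    overlap = overlap, gene_matrix = gene_matrix,
    disease_matrix = disease_matrix, sample_spaces = spaces,
    targets_per_indication = tpi, indications_per_target = ipt,
    opportunities = opps, arithmetic = arithmetic, manifest = manifest,
    config = config
  ), class = "atlas_run"))
}

#' @export
print.atlas_run <- function(x, ...) {
  cat("<atlas_run>\n")
  cat(sprintf("  traits: %d mapped / %d\n",
              x$manifest$counts$traits_mapped, x$manifest$counts$traits_in))
  cat(sprintf("  pairs: %d; gwas diseases: %d; devel diseases: %d\n",
              x$manifest$counts$pairs, x$manifest$counts$gwas_diseases,
              x$manifest$counts$devel_diseases))
  invisible(x)
}
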