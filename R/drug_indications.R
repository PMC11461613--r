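# ChEMBL-style compound/target/indication tables -> target-indication
# pairs with development-stage labels, and the stage partition of the
# druggable genome.

#' Stage-code convention for clinical max-phase integers
#'
#' Maps development-stage codes to stage labels. The default follows the
#' ChEMBL max-phase integers: 4 approved, 1-3 clinical, 0 preclinical.
#' Releases have changed encodings, so the convention is a configurable
#' table rather than a constant.
#'
#' @return Tibble with columns `code` and `stage`.
#' @export
chembl_stage_convention <- function() {
  tibble::tibble(code = c(0L, 1L, 2L, 3L, 4L),
                 stage = c("preclinical", "clinical", "clinical",
                           "clinical", "approved"))
}

#' Classify a development-stage code
#'
#' @param max_phase Integer-like vector of stage codes.
#' @param convention A stage-convention table
#'   ([chembl_stage_convention()] by default).
#' @return Character vector of stage labels
#'   (`approved`/`clinical`/`preclinical`). A code outside the convention
#'   is a hard error.
#' @export
classify_stage <- function(max_phase, convention = chembl_stage_convention()) {
  idx <- match(as.integer(max_phase), convention$code)
  if (anyNA(idx)) {
    abort_fmt("stage code outside the convention: %s",
              paste(unique(max_phase[is.na(idx)]), collapse = ", "))
  }
  convention$stage[idx]
}

#' Read ChEMBL-style export tables from a directory
#'
#' Expects `compounds.csv` (compound_id, pref_name, max_phase, withdrawn,
#' human_use), `compound_targets.csv` (compound_id, target_id),
#' `target_genes.csv` (target_id, uniprot, ensembl_gene) and
#' `indications.csv` (compound_id, mesh_term, max_phase_for_indication),
#' plus `druggable_genes.txt` (one gene per line). `#` lines are skipped.
#'
#' @param dir Directory holding the four CSVs and the gene list.
#' @return List with tibbles `compounds`, `compound_targets`,
#'   `target_genes`, `indications` and character vector `druggable`.
#' @export
read_drug_tables <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort_fmt("drug table not found: %s", p)
    p
  }
  rd <- function(f, types) {
    readr::read_csv(path(f), comment = "#", col_types = types)
  }
  list(
    compounds = rd("compounds.csv", readr::cols(
      compound_id = readr::col_character(),
      pref_name = readr::col_character(),
      max_phase = readr::col_integer(),
      withdrawn = readr::col_integer(),
      human_use = readr::col_integer())),
    compound_targets = rd("compound_targets.csv", readr::cols(
      compound_id = readr::col_character(),
      target_id = readr::col_character())),
    target_genes = rd("target_genes.csv", readr::cols(
      target_id = readr::col_character(),
      uniprot = readr::col_character(),
      ensembl_gene = readr::col_character())),
    indications = rd("indications.csv", readr::cols(
      compound_id = readr::col_character(),
      mesh_term = readr::col_character(),
      max_phase_for_indication = readr::col_integer())),
    druggable = {
      lines <- read_data_lines(path("druggable_genes.txt"))$lines
      sort(unique(lines))
    }
  )
}

#' Load compound indications with exclusions and concept mapping
#'
#' Compounds flagged withdrawn or not intended for human use are dropped
#' before any pairing, and their identifiers are listed in the exclusion
#' report. Each surviving indication's MeSH term is resolved to a concept
#' through the store (MSH source vocabulary); unresolvable terms are
#' flagged unmapped and take no part in coverage counts. An indication
#' row whose compound is absent from the compound table is a record-level
#' error: it is reported and processing continues.
#'
#' @param tables A [read_drug_tables()] list.
#' @param store A `concept_store` holding the MeSH vocabulary.
#' @param mesh_sab Source-vocabulary code for MeSH rows.
#' @return List with `indications` (tibble compound_id, mesh_term, cui,
#'   max_phase_for_indication, stage, unmapped) and `report` (counts,
#'   dropped and dangling identifiers).
#' @export
load_compound_indications <- function(tables, store, mesh_sab = "MSH") {
  cmp <- tables$compounds
  dropped <- cmp$compound_id[cmp$withdrawn == 1L | cmp$human_use == 0L]
  surviving <- setdiff(cmp$compound_id, dropped)
  ind <- tables$indications
  dangling <- setdiff(unique(ind$compound_id), cmp$compound_id)
  ind <- ind[ind$compound_id %in% surviving, ]

  cui_of <- vapply(ind$mesh_term, function(tm) {
    hits <- lookup_exact(store, tm, source_filter = mesh_sab)
    if (length(hits) == 0L) NA_character_ else hits[1]
  }, character(1), USE.NAMES = FALSE)
  out <- tibble::tibble(
    compound_id = ind$compound_id,
    mesh_term = ind$mesh_term,
    cui = cui_of,
    max_phase_for_indication = ind$max_phase_for_indication,
    stage = classify_stage(ind$max_phase_for_indication),
    unmapped = is.na(cui_of)
  )
  list(
    indications = out,
    report = list(
      compounds_in = nrow(cmp),
      compounds_kept = length(surviving),
      compounds_dropped = length(dropped),
      dropped_ids = sort(dropped),
      dangling_ids = sort(dangling),
      indications_in = nrow(tables$indications),
      indications_kept = nrow(out),
      indications_unmapped = sum(out$unmapped)
    )
  )
}

#' Build the target-indication pair set
#'
#' Emits one `(gene, cui, stage)` row for each surviving compound crossed
#' with its target genes and mapped indications, de-duplicated on that
#' key. The stage comes from the per-indication phase, not the compound's
#' global maximum. Genes outside the druggable set are retained and
#' flagged. Multiple target identifiers per gene collapse to the gene.
#'
#' @param indications The `indications` tibble from
#'   [load_compound_indications()] (unmapped rows are ignored).
#' @param compounds Compound table (used only to honour exclusion flags
#'   if the caller passes a raw table).
#' @param genemap List with `rows` (tibble target_id, uniprot,
#'   ensembl_gene) and `druggable` (character vector), plus the
#'   compound-target link table as `compound_targets`.
#' @return Tibble of class `pair_table` with columns `gene`, `cui`,
#'   `stage`, `druggable`.
#' @export
build_pairs <- function(indications, compounds, genemap) {
  keep <- compounds$compound_id[compounds$withdrawn == 0L &
                                  compounds$human_use == 1L]
  ind <- indications[!indications$unmapped &
                       indications$compound_id %in% keep, ]
  links <- genemap$compound_targets[
    genemap$compound_targets$compound_id %in% keep, ]
  x <- dplyr::inner_join(ind, links, by = "compound_id",
                         relationship = "many-to-many")
  x <- dplyr::inner_join(x, genemap$rows, by = "target_id",
                         relationship = "many-to-many")
  pairs <- dplyr::distinct(tibble::tibble(
    gene = x$ensembl_gene, cui = x$cui, stage = x$stage))
  pairs$druggable <- pairs$gene %in% genemap$druggable
  pairs <- dplyr::arrange(pairs, .data$gene, .data$cui, .data$stage)
  class(pairs) <- c("pair_table", class(pairs))
  pairs
}

#' Partition the druggable genome by development stage
#'
#' Per-stage gene sets are taken from the pairs restricted to druggable
#' genes; a gene may sit in several stage sets. The undrugged set is the
#' complement within the druggable genome, so
#' `|undrugged| + |approved U clinical U preclinical| = |druggable|`
#' always holds (checked on every call).
#'
#' @param pairs A [build_pairs()] table.
#' @param druggable Character vector of druggable genes.
#' @return An object of class `stage_partition`: list with gene sets
#'   `approved`, `clinical`, `preclinical`, `undrugged` and the
#'   `druggable` universe.
#' @export
partition_genome <- function(pairs, druggable) {
  druggable <- sort(unique(druggable))
  gset <- function(stage) {
    sort(unique(pairs$gene[pairs$stage == stage &
                             pairs$gene %in% druggable]))
  }
  approved <- gset("approved")
  clinical <- gset("clinical")
  preclinical <- gset("preclinical")
  drugged <- sort(unique(c(approved, clinical, preclinical)))
  undrugged <- setdiff(druggable, drugged)
  stopifnot(length(undrugged) + length(drugged) == length(druggable))
  structure(list(approved = approved, clinical = clinical,
                 preclinical = preclinical, undrugged = undrugged,
                 druggable = druggable),
            class = "stage_partition")
}

#' @export
print.stage_partition <- function(x, ...) {
  cat(sprintf(
    "<stage_partition> druggable %d: approved %d, clinical %d, preclinical %d, undrugged %d\n",
    length(x$druggable), length(x$approved), length(x$clinical),
    length(x$preclinical), length(x$undrugged)))
  invisible(x)
}
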