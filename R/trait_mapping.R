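# Multi-route cascade from GWAS trait strings (and ICD-10 phenotypes) to
# disease concepts.
#
# Routes are tried in a fixed order and the first productive one labels
# the result: curation overlay, direct string match, deterministic
# candidate generation with semantic-type resolution, ontology crossmaps
# (DisGeNET-style then Metathesaurus-style), and finally the major MeSH
# terms of the source publication. The candidate generator is a
# deterministic stand-in behind the same interface a concept-recognition
# tool (e.g. MetaMap) would occupy.

#' Default semantic-type priority order
#'
#' The order in which semantic types are preferred when a trait maps to
#' multiple concepts and none is a direct string match.
#'
#' @return Character vector of semantic-type names, highest priority
#'   first.
#' @export
default_semantic_priority <- function() {
  c("Disease or Syndrome", "Neoplastic Process",
    "Mental or Behavioral Dysfunction", "Congenital Abnormality",
    "Sign or Symptom", "Finding", "Laboratory Procedure",
    "Injury or Poisoning", "Individual Behavior", "Diagnostic Procedure")
}

#' Resolution policy for ambiguous trait mappings
#'
#' @param priority Ordered character vector of semantic-type names
#'   (unique, highest priority first).
#' @param direct_match_first If `TRUE`, candidates that are exact
#'   normalized matches of the trait string win outright.
#' @return A list of class `resolution_policy`.
#' @export
resolution_policy <- function(priority = default_semantic_priority(),
                              direct_match_first = TRUE) {
  if (anyDuplicated(priority)) {
    abort_fmt("resolution_policy: priority entries must be unique")
  }
  structure(list(priority = priority,
                 direct_match_first = isTRUE(direct_match_first)),
            class = "resolution_policy")
}

#' Deterministic candidate concepts for a trait string
#'
#' Returns the union of exact normalized matches and token-subset matches:
#' concepts owning a synonym of at least two tokens whose tokens are all
#' contained in the trait's token set. The two-token floor prevents every
#' single-word synonym from flooding long trait strings. Ranking is
#' deferred to [resolve_candidates()].
#'
#' @param trait Trait string.
#' @param store A `concept_store`.
#' @return Sorted character vector of candidate CUIs (possibly empty).
#' @export
candidate_concepts <- function(trait, store) {
  stopifnot(inherits(store, "concept_store"))
  q <- normalize_term(trait)
  if (!nzchar(q)) return(character(0))
  toks <- norm_tokens(q)
  syn <- store$synonyms
  exact <- syn$cui[syn$norm == q]
  uniq <- dplyr::distinct(syn[, c("cui", "norm")])
  subset_hit <- vapply(seq_len(nrow(uniq)), function(i) {
    st <- norm_tokens(uniq$norm[i])
    length(st) >= 2L && all(st %in% toks)
  }, logical(1))
  sort(unique(c(exact, uniq$cui[subset_hit])))
}

#' Resolve a multi-concept candidate set
#'
#' Direct (exact normalized) matches win outright when the policy says
#' so; otherwise all candidates carrying the highest-priority semantic
#' type present are kept (ties within a tier are preserved, not broken
#' arbitrarily); if no candidate carries any listed type, the full
#' candidate set is returned unchanged. Never returns more than its input
#' and never empties a nonempty input.
#'
#' @param trait Trait string the candidates were generated for.
#' @param candidates Nonempty character vector of candidate CUIs.
#' @param store A `concept_store`.
#' @param types A `semantic_type_table`.
#' @param policy A [resolution_policy()].
#' @return Character vector of retained CUIs.
#' @export
resolve_candidates <- function(trait, candidates, store, types,
                               policy = resolution_policy()) {
  stopifnot(length(candidates) > 0L)
  candidates <- sort(unique(candidates))
  if (policy$direct_match_first) {
    direct <- intersect(candidates, lookup_exact(store, trait))
    if (length(direct) > 0L) return(direct)
  }
  ctypes <- semantic_types_of(types, candidates)
  for (ty in policy$priority) {
    hit <- vapply(ctypes, function(v) any(tolower(v) == tolower(ty)),
                  logical(1))
    if (any(hit)) return(candidates[hit])
  }
  candidates
}

#' Read a GWAS-Catalog-style trait file
#'
#' Tab-separated with columns `reported_trait`, `mapped_ontology_terms`
#' (pipe-separated ontology identifiers), `pubmed_id` and
#' `study_mesh_terms` (semicolon-separated; a trailing `*` marks a major
#' term). Column names are configurable. `#`-prefixed lines are skipped.
#'
#' @param path Path to the TSV file.
#' @param col_names Named character vector mapping the four roles to the
#'   file's column names.
#' @return Tibble with columns `reported_trait`, `mapped_ontology_terms`
#'   (list), `pubmed_id`, `mesh_terms` (list), `mesh_major` (list of
#'   logical flags parallel to `mesh_terms`).
#' @export
read_gwas_traits <- function(path,
                             col_names = c(
                               reported_trait = "reported_trait",
                               mapped_ontology_terms = "mapped_ontology_terms",
                               pubmed_id = "pubmed_id",
                               study_mesh_terms = "study_mesh_terms")) {
  if (!file.exists(path)) abort_fmt("trait file not found: %s", path)
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()))
  missing <- setdiff(unname(col_names), names(df))
  if (length(missing) > 0L) {
    abort_fmt("trait file missing column(s): %s",
              paste(missing, collapse = ", "))
  }
  split_list <- function(x, sep) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else
        strsplit(s, sep, fixed = TRUE)[[1]]
    })
  }
  mesh_raw <- split_list(df[[col_names[["study_mesh_terms"]]]], ";")
  tibble::tibble(
    reported_trait = df[[col_names[["reported_trait"]]]],
    mapped_ontology_terms =
      split_list(df[[col_names[["mapped_ontology_terms"]]]], "|"),
    pubmed_id = df[[col_names[["pubmed_id"]]]],
    mesh_terms = lapply(mesh_raw, function(v) sub("\\*$", "", v)),
    mesh_major = lapply(mesh_raw, function(v) grepl("\\*$", v))
  )
}

#' Read a two-column ontology crossmap table
#'
#' @param path TSV with columns `term_id` and `cui`; `#` lines skipped.
#' @param provenance Label recorded on the table (e.g. `"disgenet"`).
#' @return A tibble of class `crossmap_table` with attribute
#'   `provenance`; rows with empty targets are rejected.
#' @export
read_crossmap <- function(path, provenance) {
  if (!file.exists(path)) abort_fmt("crossmap file not found: %s", path)
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    term_id = readr::col_character(), cui = readr::col_character()))
  if (any(is.na(df$cui) | !nzchar(df$cui))) {
    abort_fmt("crossmap %s has rows with empty target CUIs", provenance)
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("crossmap_table", class(df))
  df
}

crossmap_lookup <- function(crossmap, term_ids) {
  if (is.null(crossmap) || length(term_ids) == 0L) return(character(0))
  sort(unique(crossmap$cui[crossmap$term_id %in% term_ids]))
}

#' Read a curation overlay
#'
#' A YAML or JSON document with a top-level `decisions` map from trait
#' text to a (possibly empty) vector of accepted CUIs. An empty decision
#' forces the trait to be unmapped. Overlay decisions pre-empt every
#' automatic stage; what automation would have produced is preserved in
#' the audit.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `curation_overlay`.
#' @export
read_overlay <- function(path) {
  if (!file.exists(path)) abort_fmt("overlay file not found: %s", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  decisions <- doc$decisions %||% list()
  decisions <- lapply(decisions, function(v) as.character(unlist(v)))
  structure(list(decisions = decisions), class = "curation_overlay")
}

#' An empty curation overlay
#' @return A `curation_overlay` with no decisions.
#' @export
empty_overlay <- function() {
  structure(list(decisions = list()), class = "curation_overlay")
}

# Automatic cascade (everything except the overlay); returns stage, cuis
# and the per-stage audit of candidate sets.
auto_cascade <- function(trait, store, types, crossmaps, policy) {
  audit <- list()
  text <- trait$reported_trait %||% ""

  direct <- lookup_exact(store, text)
  audit$direct_string <- direct
  if (length(direct) > 0L) {
    return(list(stage = "direct_string", cuis = direct, audit = audit))
  }

  cand <- candidate_concepts(text, store)
  audit$candidates <- cand
  if (length(cand) > 0L) {
    res <- resolve_candidates(text, cand, store, types, policy)
    audit$candidate_rejected <- setdiff(cand, res)
    return(list(stage = "candidate_resolved", cuis = res, audit = audit))
  }

  onto <- trait$mapped_ontology_terms %||% character(0)
  dg <- crossmap_lookup(crossmaps$disgenet, onto)
  audit$crossmap_disgenet <- dg
  if (length(dg) > 0L) {
    return(list(stage = "crossmap_disgenet", cuis = dg, audit = audit))
  }
  mt <- crossmap_lookup(crossmaps$metathesaurus, onto)
  audit$crossmap_metathesaurus <- mt
  if (length(mt) > 0L) {
    return(list(stage = "crossmap_metathesaurus", cuis = mt, audit = audit))
  }

  mesh <- trait$mesh_terms %||% character(0)
  major <- trait$mesh_major %||% logical(0)
  major_terms <- mesh[which(major)]
  pm <- unlist(lapply(major_terms, function(tm) lookup_exact(store, tm)))
  pm <- sort(unique(as.character(pm %||% character(0))))
  audit$pubmed_mesh_major <- pm
  if (length(pm) > 0L) {
    return(list(stage = "pubmed_mesh_major", cuis = pm, audit = audit))
  }
  list(stage = "unmapped", cuis = character(0), audit = audit)
}

#' Map one trait record through the full cascade
#'
#' Stages in order: curation overlay, direct string match, candidate
#' generation plus semantic-type resolution, DisGeNET-style crossmap,
#' Metathesaurus-style crossmap, PubMed major-MeSH lookup. The first
#' productive stage labels the result; when the overlay decides, the
#' automatic outcome is still computed and kept in the audit.
#'
#' @param trait A list or one-row tibble with fields `reported_trait`,
#'   `mapped_ontology_terms`, `mesh_terms`, `mesh_major` (as produced by
#'   [read_gwas_traits()]; missing fields are treated as empty).
#' @param store A `concept_store`.
#' @param types A `semantic_type_table`.
#' @param crossmaps Named list with optional elements `disgenet` and
#'   `metathesaurus`, each a [read_crossmap()] table.
#' @param overlay A [read_overlay()] object (or [empty_overlay()]).
#' @param policy A [resolution_policy()].
#' @return A list of class `mapping_result`: `reported_trait`, `cuis`,
#'   `stage`, `audit`.
#' @export
map_trait_cascade <- function(trait, store, types,
                              crossmaps = list(),
                              overlay = empty_overlay(),
                              policy = resolution_policy()) {
  if (is.data.frame(trait)) trait <- as.list(trait[1, ])
  trait$mapped_ontology_terms <- unlist(trait$mapped_ontology_terms)
  trait$mesh_terms <- unlist(trait$mesh_terms)
  trait$mesh_major <- unlist(trait$mesh_major)
  text <- trait$reported_trait %||% ""

  auto <- auto_cascade(trait, store, types, crossmaps, policy)
  if (text %in% names(overlay$decisions)) {
    decided <- as.character(overlay$decisions[[text]])
    return(structure(list(
      reported_trait = text, cuis = decided, stage = "curation_overlay",
      audit = c(list(overlay = decided, auto_stage = auto$stage,
                     auto_cuis = auto$cuis), auto$audit)
    ), class = "mapping_result"))
  }
  structure(list(reported_trait = text, cuis = auto$cuis,
                 stage = auto$stage, audit = auto$audit),
            class = "mapping_result")
}

#' Map a table of traits through the cascade
#'
#' @param traits Tibble from [read_gwas_traits()].
#' @inheritParams map_trait_cascade
#' @return Tibble with one row per trait: `reported_trait`, `stage`,
#'   `cuis` (list-column), `n_cuis`, `audit` (list-column).
#' @export
map_traits <- function(traits, store, types, crossmaps = list(),
                       overlay = empty_overlay(),
                       policy = resolution_policy()) {
  rows <- lapply(seq_len(nrow(traits)), function(i) {
    map_trait_cascade(traits[i, ], store, types, crossmaps, overlay, policy)
  })
  tibble::tibble(
    reported_trait = vapply(rows, `[[`, character(1), "reported_trait"),
    stage = vapply(rows, `[[`, character(1), "stage"),
    cuis = lapply(rows, `[[`, "cuis"),
    n_cuis = vapply(rows, function(r) length(r$cuis), integer(1)),
    audit = lapply(rows, `[[`, "audit")
  )
}

#' Map ICD-10 phenotype codes to concepts
#'
#' Matches on the ICD-10 source *code* column of the store (not the term
#' string). Malformed codes produce a record-level error flag and
#' processing continues; duplicate input codes each get their own result.
#'
#' @param codes Character vector of ICD-10 codes.
#' @param store A `concept_store` containing an `ICD10` source
#'   vocabulary.
#' @param sab Source-vocabulary code holding the ICD-10 rows.
#' @return Tibble with columns `code`, `cuis` (list), `stage`
#'   (`"icd10_code"` or `"unmapped"`), `error`.
#' @export
map_icd10_traits <- function(codes, store, sab = "ICD10") {
  stopifnot(inherits(store, "concept_store"))
  if (!any(store$synonyms$sab == sab)) {
    abort_fmt("store has no %s source vocabulary", sab)
  }
  res <- lapply(codes, function(cd) {
    if (!grepl("^[A-Z][0-9]{2}(\\.[0-9]+)?$", cd %||% "")) {
      return(list(cuis = character(0), stage = "unmapped",
                  error = sprintf("malformed ICD-10 code: %s", cd)))
    }
    hits <- lookup_code(store, cd, sab)
    list(cuis = hits,
         stage = if (length(hits)) "icd10_code" else "unmapped",
         error = NA_character_)
  })
  tibble::tibble(
    code = codes,
    cuis = lapply(res, `[[`, "cuis"),
    stage = vapply(res, `[[`, character(1), "stage"),
    error = vapply(res, `[[`, character(1), "error")
  )
}

#' Collapse mapping results into a disease set with chapter rollup
#'
#' Takes the union of all mapped concepts, drops every disease whose
#' chapter set is a *subset* of the excluded chapters (a disease also
#' classified in a kept chapter is retained), and reports a per-chapter
#' rollup over the kept chapters in which a disease is counted once per
#' chapter, alongside the unique-disease count.
#'
#' @param results A [map_traits()] or [map_icd10_traits()] tibble (or a
#'   list of them), or simply a character vector of CUIs.
#' @param chapters Tibble with columns `cui` and `chapter`; concepts not
#'   covered are assigned the `"Unclassified"` chapter.
#' @param excluded Character vector of chapter names to exclude.
#' @return List with `diseases` (sorted kept CUIs), `excluded_diseases`,
#'   `rollup` (tibble chapter/n over kept diseases), `n_unique`.
#' @export
collapse_to_disease_set <- function(results, chapters,
                                    excluded = excluded_chapters()) {
  cuis <- if (is.character(results)) {
    results
  } else {
    if (is.data.frame(results)) results <- list(results)
    unlist(lapply(results, function(df) unlist(df$cuis)))
  }
  cuis <- sort(unique(cuis))
  chap_of <- lapply(cuis, function(id) {
    ch <- chapters$chapter[chapters$cui == id]
    if (length(ch) == 0L) "Unclassified" else unique(ch)
  })
  names(chap_of) <- cuis
  drop <- vapply(chap_of, function(ch) all(ch %in% excluded), logical(1))
  kept <- cuis[!drop]
  rollup <- tibble::tibble(
    cui = rep(kept, lengths(chap_of[kept])),
    chapter = unlist(chap_of[kept], use.names = FALSE)
  )
  # a retained disease may still carry an excluded-chapter membership;
  # the per-chapter rollup reports kept chapters only
  rollup <- rollup[!rollup$chapter %in% excluded, ]
  rollup <- dplyr::count(rollup, .data$chapter, name = "n")
  list(diseases = kept, excluded_diseases = cuis[drop],
       rollup = dplyr::arrange(rollup, dplyr::desc(.data$n), .data$chapter),
       n_unique = length(kept))
}
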