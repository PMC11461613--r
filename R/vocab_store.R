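# Concept store over MRCONSO/MRSTY-dialect vocabulary tables.
#
# The Metathesaurus release format (RRF) is pipe-delimited with a fixed
# column order and a trailing pipe. Licensed releases cannot ship with the
# package, so the readers honour the public layout but take the column
# positions from a configuration object, which also lets desk-scale
# fixtures stay format-faithful.

#' MRCONSO column layout
#'
#' Column positions for the concept-names table, defaulting to the public
#' RRF layout (18 fields; CUI first, source vocabulary at 12, source code
#' at 14, term string at 15). A trailing pipe is tolerated.
#'
#' @param cui,sab,code,str 1-based positions of the concept identifier,
#'   source-vocabulary abbreviation, source code and term string.
#' @param n_fields Expected number of fields per row.
#' @return A list of class `mrconso_columns`.
#' @export
mrconso_columns <- function(cui = 1L, sab = 12L, code = 14L, str = 15L,
                            n_fields = 18L) {
  stopifnot(max(cui, sab, code, str) <= n_fields)
  structure(list(cui = cui, sab = sab, code = code, str = str,
                 n_fields = n_fields),
            class = "mrconso_columns")
}

#' MRSTY column layout
#'
#' @param cui,sty 1-based positions of the concept identifier and the
#'   semantic-type name.
#' @param n_fields Expected number of fields per row.
#' @return A list of class `mrsty_columns`.
#' @export
mrsty_columns <- function(cui = 1L, sty = 4L, n_fields = 6L) {
  stopifnot(max(cui, sty) <= n_fields)
  structure(list(cui = cui, sty = sty, n_fields = n_fields),
            class = "mrsty_columns")
}

#' Controlled list of semantic-type names
#'
#' The semantic types the store accepts, spanning the resolution-policy
#' priority list plus the neighbouring disease/phenotype categories that
#' occur in trait mapping. Comparison is case-insensitive (releases have
#' used both "Individual Behavior" and "Individual behaviour"-style
#' spellings).
#'
#' @return Character vector of canonical semantic-type names.
#' @export
umls_semantic_types <- function() {
  c("Disease or Syndrome",
    "Neoplastic Process",
    "Mental or Behavioral Dysfunction",
    "Congenital Abnormality",
    "Sign or Symptom",
    "Finding",
    "Laboratory Procedure",
    "Injury or Poisoning",
    "Individual Behavior",
    "Diagnostic Procedure",
    "Anatomical Abnormality",
    "Pathologic Function",
    "Cell or Molecular Dysfunction",
    "Clinical Attribute",
    "Organism Function")
}

split_rrf_row <- function(line) strsplit(line, "|", fixed = TRUE)[[1]]

#' Read an MRCONSO-dialect concept table
#'
#' Parses a pipe-delimited concept-names file into a concept store holding
#' one concept per distinct CUI with its full synonym set, and a
#' normalized-term index used by [lookup_exact()]. Matching downstream is
#' case-insensitive via [normalize_term()]; this choice is recorded in the
#' load report.
#'
#' @param path Path to the pipe-delimited file. Lines starting with `#`
#'   are treated as header comments and skipped.
#' @param source_filter Optional character vector of source-vocabulary
#'   codes (e.g. `"MSH"`, `"ICD10"`); rows from other vocabularies are
#'   skipped and counted in the load report.
#' @param columns An [mrconso_columns()] layout.
#' @return An object of class `concept_store`: a list with `synonyms`
#'   (tibble of cui/sab/code/term/norm rows), `semantic_types` (`NULL`
#'   until [attach_semantic_types()]), and `load_report`.
#' @export
read_mrconso <- function(path, source_filter = NULL,
                         columns = mrconso_columns()) {
  if (!file.exists(path)) abort_fmt("MRCONSO file not found: %s", path)
  dat <- read_data_lines(path)
  n_read <- length(dat$lines)
  if (n_read == 0L) {
    warning("empty MRCONSO file: ", path, call. = FALSE)
    return(new_concept_store(empty_synonyms(), n_read = 0L, n_kept = 0L))
  }
  fields <- lapply(dat$lines, split_rrf_row)
  n_fields <- lengths(fields)
  bad <- which(n_fields != columns$n_fields)
  if (length(bad) > 0L) {
    abort_fmt("malformed MRCONSO row at line %d: %d fields, expected %d",
              dat$lineno[bad[1]], n_fields[bad[1]], columns$n_fields)
  }
  m <- do.call(rbind, fields)
  syn <- tibble::tibble(
    cui = m[, columns$cui],
    sab = m[, columns$sab],
    code = m[, columns$code],
    term = m[, columns$str]
  )
  if (any(!nzchar(syn$cui))) abort_fmt("MRCONSO row with empty CUI")
  if (any(!nzchar(syn$term))) abort_fmt("MRCONSO row with empty term string")
  if (!is.null(source_filter)) {
    syn <- dplyr::filter(syn, .data$sab %in% source_filter)
  }
  syn$norm <- normalize_term(syn$term)
  syn <- dplyr::distinct(syn)
  new_concept_store(syn, n_read = n_read, n_kept = nrow(syn))
}

empty_synonyms <- function() {
  tibble::tibble(cui = character(), sab = character(), code = character(),
                 term = character(), norm = character())
}

new_concept_store <- function(synonyms, n_read, n_kept) {
  structure(
    list(
      synonyms = synonyms,
      semantic_types = NULL,
      load_report = list(
        rows_read = n_read,
        rows_kept = n_kept,
        rows_skipped = n_read - n_kept,
        matching = "case-insensitive (normalize_term)"
      )
    ),
    class = "concept_store"
  )
}

#' @export
print.concept_store <- function(x, ...) {
  cat(sprintf("<concept_store> %d concepts, %d synonym rows\n",
              dplyr::n_distinct(x$synonyms$cui), nrow(x$synonyms)))
  rep <- x$load_report
  cat(sprintf("  load report: read %d, kept %d, skipped %d\n",
              rep$rows_read, rep$rows_kept, rep$rows_skipped))
  invisible(x)
}

#' Number of distinct concepts in a store
#' @param store A `concept_store`.
#' @return Integer count of distinct CUIs.
#' @export
n_concepts <- function(store) {
  stopifnot(inherits(store, "concept_store"))
  dplyr::n_distinct(store$synonyms$cui)
}

#' Write a concept store back to the MRCONSO dialect
#'
#' Emits one pipe-delimited row per synonym, with the standard 18-field
#' layout and trailing pipe, so that a written store round-trips through
#' [read_mrconso()].
#'
#' @param store A `concept_store`.
#' @param path Output path.
#' @param columns An [mrconso_columns()] layout.
#' @return The path, invisibly.
#' @export
write_mrconso <- function(store, path, columns = mrconso_columns()) {
  stopifnot(inherits(store, "concept_store"))
  syn <- dplyr::arrange(store$synonyms, .data$cui, .data$sab, .data$term)
  rows <- vapply(seq_len(nrow(syn)), function(i) {
    f <- rep("", columns$n_fields)
    f[columns$cui] <- syn$cui[i]
    f[columns$sab] <- syn$sab[i]
    f[columns$code] <- syn$code[i]
    f[columns$str] <- syn$term[i]
    paste0(paste(f, collapse = "|"), "|")
  }, character(1))
  write_lines_utf8(rows, path)
}

#' Read an MRSTY-dialect semantic-type table
#'
#' @param path Path to the pipe-delimited file; `#`-prefixed lines are
#'   skipped.
#' @param columns An [mrsty_columns()] layout.
#' @param controlled Character vector of admissible semantic-type names;
#'   a name outside the list (case-insensitively) is a hard error naming
#'   the offending string.
#' @return An object of class `semantic_type_table`: a tibble with one
#'   `cui`/`sty` row per (concept, type), types canonicalized to the
#'   controlled spelling.
#' @export
read_semantic_types <- function(path, columns = mrsty_columns(),
                                controlled = umls_semantic_types()) {
  if (!file.exists(path)) abort_fmt("MRSTY file not found: %s", path)
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) {
    return(new_semantic_type_table(
      tibble::tibble(cui = character(), sty = character())))
  }
  fields <- lapply(dat$lines, split_rrf_row)
  n_fields <- lengths(fields)
  bad <- which(n_fields != columns$n_fields)
  if (length(bad) > 0L) {
    abort_fmt("malformed MRSTY row at line %d: %d fields, expected %d",
              dat$lineno[bad[1]], n_fields[bad[1]], columns$n_fields)
  }
  m <- do.call(rbind, fields)
  sty_raw <- m[, columns$sty]
  idx <- match(tolower(sty_raw), tolower(controlled))
  if (anyNA(idx)) {
    abort_fmt("semantic type outside the controlled list: \"%s\"",
              sty_raw[which(is.na(idx))[1]])
  }
  tab <- tibble::tibble(cui = m[, columns$cui], sty = controlled[idx])
  new_semantic_type_table(dplyr::distinct(tab))
}

new_semantic_type_table <- function(tab) {
  structure(list(rows = tab), class = "semantic_type_table")
}

#' @export
print.semantic_type_table <- function(x, ...) {
  cat(sprintf("<semantic_type_table> %d concepts, %d (cui, type) rows\n",
              dplyr::n_distinct(x$rows$cui), nrow(x$rows)))
  invisible(x)
}

#' Semantic types of one or more concepts
#'
#' @param types A `semantic_type_table`.
#' @param cuis Character vector of concept identifiers.
#' @return Named list mapping each cui to its (possibly empty) character
#'   vector of semantic-type names.
#' @export
semantic_types_of <- function(types, cuis) {
  stopifnot(inherits(types, "semantic_type_table"))
  out <- lapply(cuis, function(id) {
    sort(types$rows$sty[types$rows$cui == id])
  })
  names(out) <- cuis
  out
}

#' Attach a semantic-type table to a concept store
#'
#' @param store A `concept_store`.
#' @param types A `semantic_type_table`.
#' @return The store with `semantic_types` populated.
#' @export
attach_semantic_types <- function(store, types) {
  stopifnot(inherits(store, "concept_store"),
            inherits(types, "semantic_type_table"))
  store$semantic_types <- types
  store
}

#' Exact normalized lookup of a term
#'
#' Returns every CUI owning a synonym whose normalized form equals the
#' normalized query, optionally restricted to a source vocabulary. This is
#' the "direct string matching" primitive of the trait-mapping cascade.
#'
#' @param store A `concept_store`.
#' @param term Query string.
#' @param source_filter Optional character vector of source-vocabulary
#'   codes to restrict the match.
#' @return Sorted character vector of CUIs; empty when no synonym matches.
#' @export
lookup_exact <- function(store, term, source_filter = NULL) {
  stopifnot(inherits(store, "concept_store"))
  q <- normalize_term(term)
  if (!nzchar(q)) return(character(0))
  syn <- store$synonyms
  hit <- syn$norm == q
  if (!is.null(source_filter)) hit <- hit & syn$sab %in% source_filter
  sort(unique(syn$cui[hit]))
}

#' Exact source-code lookup
#'
#' Matches on the source *code* column (e.g. an ICD-10 code), not the term
#' string.
#'
#' @param store A `concept_store`.
#' @param code Source code to look up.
#' @param sab Source vocabulary the code belongs to.
#' @return Sorted character vector of CUIs.
#' @export
lookup_code <- function(store, code, sab) {
  stopifnot(inherits(store, "concept_store"))
  syn <- store$synonyms
  sort(unique(syn$cui[syn$sab == sab & syn$code == code]))
}
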