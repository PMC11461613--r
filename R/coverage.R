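# Sample spaces, explored fractions, set-intersection (UpSet) matrices,
# per-target/per-disease statistics, GWAS overlap and opportunity lists.

#' Exact size of a target-by-disease sample space
#'
#' Integer product with no floating rounding. Errors on negative input
#' and on products beyond exact double precision (2^53), which leaves
#' eight orders of magnitude of headroom over any genome-by-disease-ome
#' grid.
#'
#' @param n_targets,n_diseases Non-negative integer counts.
#' @return The exact product as a numeric scalar.
#' @examples
#' sample_space(19813, 11158) # 221073454
#' @export
sample_space <- function(n_targets, n_diseases) {
  if (length(n_targets) != 1L || length(n_diseases) != 1L ||
      is.na(n_targets) || is.na(n_diseases) ||
      n_targets < 0 || n_diseases < 0 ||
      n_targets != trunc(n_targets) || n_diseases != trunc(n_diseases)) {
    abort_fmt("sample_space: inputs must be non-negative integers")
  }
  prod <- as.numeric(n_targets) * as.numeric(n_diseases)
  if (prod > 2^53) {
    abort_fmt("sample_space: product %g exceeds exact integer range", prod)
  }
  prod
}

#' Percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up to the stated
#' number of decimals (base `round()` is half-even and would not
#' reproduce printed report percentages).
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @param decimals 0 or 1 decimal places.
#' @return Numeric percentage.
#' @examples
#' percent_round(42199, 1706418, 1) # 2.5
#' @export
percent_round <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) abort_fmt("percent_round: denominator must be > 0")
  if (!decimals %in% c(0L, 1L)) {
    abort_fmt("percent_round: decimals must be 0 or 1")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Exclusive membership-pattern matrix over named sets
#'
#' The UpSet decomposition: every element of the union is assigned the
#' unique bit-pattern of the sets it belongs to, and patterns are
#' counted. Counts therefore always sum to the union size (checked on
#' every call). Per-set totals and pairwise overlaps are also emitted.
#'
#' @param named_sets Named list of at most 16 sets (character vectors).
#' @return Object of class `membership_matrix`: list with `set_names`,
#'   `patterns` (tibble pattern/count, pattern a bit-string in set
#'   order), `set_totals`, `pairwise` (matrix of intersection sizes),
#'   `n_union`.
#' @export
membership_matrix <- function(named_sets) {
  stopifnot(is.list(named_sets), length(named_sets) >= 1L,
            length(named_sets) <= 16L, !is.null(names(named_sets)))
  sets <- lapply(named_sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  bits <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) bits <- matrix(bits, nrow = 1L)
  if (length(universe) == 0L) {
    bits <- matrix(logical(0), nrow = 0L, ncol = length(sets))
  }
  pattern <- apply(bits, 1L, function(b) {
    paste(as.integer(b), collapse = "")
  })
  patterns <- if (length(pattern) > 0L) {
    dplyr::count(tibble::tibble(pattern = pattern), .data$pattern,
                 name = "count")
  } else {
    tibble::tibble(pattern = character(), count = integer())
  }
  stopifnot(sum(patterns$count) == length(universe))
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  structure(list(set_names = names(sets),
                 patterns = dplyr::arrange(patterns,
                                           dplyr::desc(.data$count),
                                           .data$pattern),
                 set_totals = vapply(sets, length, integer(1)),
                 pairwise = pairwise, n_union = length(universe)),
            class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("<membership_matrix> %d sets, union %d, %d patterns\n",
              length(x$set_names), x$n_union, nrow(x$patterns)))
  invisible(x)
}

#' Two-set overlap partition of GWAS and development diseases
#'
#' @param gwas_diseases,devel_diseases Character vectors of concept
#'   identifiers.
#' @return List of counts `overlap`, `gwas_only`, `devel_only` (the
#'   identity `overlap + gwas_only == |gwas|` is checked on every call).
#' @export
gwas_overlap_partition <- function(gwas_diseases, devel_diseases) {
  g <- unique(gwas_diseases)
  d <- unique(devel_diseases)
  out <- list(overlap = length(intersect(g, d)),
              gwas_only = length(setdiff(g, d)),
              devel_only = length(setdiff(d, g)))
  stopifnot(out$overlap + out$gwas_only == length(g),
            out$overlap + out$devel_only == length(d))
  out
}

# Median-of-halves quartiles (Moore-McCabe): the halves are the values
# strictly below and above the median position, so with an odd count the
# median belongs to neither half. A single observation is its own
# median and both quartiles.
median_of_halves <- function(x) {
  stopifnot(length(x) > 0L)
  x <- sort(x)
  n <- length(x)
  med <- stats::median(x)
  m <- n %/% 2L
  if (m == 0L) return(list(q1 = x, median = x, q3 = x))
  lower <- x[seq_len(m)]
  upper <- x[seq.int(n - m + 1L, n)]
  list(q1 = stats::median(lower), median = med, q3 = stats::median(upper))
}

#' Distribution of distinct targets per disease indication
#'
#' For a pair set (typically restricted to the approved stage), counts
#' distinct genes per disease and summarises the distribution with the
#' median-of-halves quartile method (the median is excluded from the
#' halves when the count is odd, so three diseases with 1, 2 and 4
#' targets give Q1 = 1, median = 2, Q3 = 4).
#'
#' @param pairs Tibble with columns `gene` and `cui`.
#' @return List with `per_disease` (tibble cui/n_targets), `median`,
#'   `q1`, `q3`. Empty input is a hard error.
#' @export
targets_per_indication_stats <- function(pairs) {
  if (nrow(pairs) == 0L) {
    abort_fmt("targets_per_indication_stats: empty pair set")
  }
  per <- dplyr::summarise(dplyr::group_by(
    dplyr::distinct(pairs[, c("gene", "cui")]), .data$cui),
    n_targets = dplyr::n(), .groups = "drop")
  q <- median_of_halves(per$n_targets)
  list(per_disease = per, median = q$median, q1 = q$q1, q3 = q$q3)
}

#' Per-target indication counts by disease chapter
#'
#' For each gene with more than `threshold` distinct indication diseases,
#' reports the per-chapter disease counts (a disease is counted once per
#' chapter it is classified in, so chapter counts can sum to more than
#' the unique count) and the distinct-disease count, sorted descending.
#'
#' @param pairs Tibble with columns `gene` and `cui` (typically the
#'   approved-stage pairs).
#' @param chapters Tibble with columns `cui` and `chapter`; uncovered
#'   concepts fall into `"Unclassified"`.
#' @param threshold Keep genes with strictly more than this many unique
#'   diseases.
#' @return List with `summary` (tibble gene/unique_diseases, sorted
#'   descending) and `by_chapter` (long tibble gene/chapter/n).
#' @export
indications_per_target_counts <- function(pairs, chapters, threshold = 25L) {
  uniq <- dplyr::distinct(pairs[, c("gene", "cui")])
  per_gene <- dplyr::summarise(dplyr::group_by(uniq, .data$gene),
                               unique_diseases = dplyr::n(),
                               .groups = "drop")
  keep <- per_gene$gene[per_gene$unique_diseases > threshold]
  summary <- dplyr::arrange(per_gene[per_gene$gene %in% keep, ],
                            dplyr::desc(.data$unique_diseases), .data$gene)
  sub <- uniq[uniq$gene %in% keep, ]
  if (nrow(sub) > 0L) {
    ch <- dplyr::left_join(sub, chapters, by = "cui",
                           relationship = "many-to-many")
    ch$chapter[is.na(ch$chapter)] <- "Unclassified"
    by_chapter <- dplyr::count(ch, .data$gene, .data$chapter, name = "n")
  } else {
    by_chapter <- tibble::tibble(gene = character(), chapter = character(),
                                 n = integer())
  }
  list(summary = summary, by_chapter = by_chapter)
}

#' Opportunity lists informed by GWAS disease coverage
#'
#' Builds the three disjoint prospect lists over GWAS-studied diseases:
#' * `indication_expansion` - genes already targeted by an approved drug,
#'   paired with GWAS diseases for which no approved pair exists;
#' * `repurposing` - genes with clinical/preclinical but no approved
#'   history, paired with GWAS diseases not yet investigated for that
#'   gene;
#' * `de_novo` - druggable but undrugged genes paired with GWAS diseases.
#'
#' Gene strata are disjoint by construction (a gene that is both approved
#' and in clinical development contributes to indication expansion only),
#' and a pair already approved is excluded from every list.
#'
#' @param partition A [partition_genome()] result.
#' @param pairs A [build_pairs()] table (used for existing-pair
#'   exclusions).
#' @param gwas_diseases Character vector of GWAS disease concepts.
#' @return Object of class `opportunity_lists`: named list of three
#'   tibbles with columns `gene`, `cui`, `gene_stage`, `reason`.
#' @export
opportunity_lists <- function(partition, pairs, gwas_diseases) {
  gwas <- sort(unique(gwas_diseases))
  explored <- dplyr::distinct(pairs[, c("gene", "cui")])
  approved_pairs <- dplyr::distinct(
    pairs[pairs$stage == "approved", c("gene", "cui")])
  pair_key <- function(df) paste(df$gene, df$cui, sep = "\r")

  grid <- function(genes, stage_label, reason, exclude) {
    if (length(genes) == 0L || length(gwas) == 0L) {
      return(tibble::tibble(gene = character(), cui = character(),
                            gene_stage = character(), reason = character()))
    }
    g <- tidyr::expand_grid(gene = sort(genes), cui = gwas)
    g <- g[!(pair_key(g) %in% pair_key(exclude)), ]
    g$gene_stage <- stage_label
    g$reason <- reason
    g
  }
  expansion_genes <- partition$approved
  repurposing_genes <- setdiff(union(partition$clinical,
                                     partition$preclinical),
                               partition$approved)
  out <- list(
    indication_expansion = grid(
      expansion_genes, "approved",
      "approved-target gene x GWAS disease without an approved pair",
      approved_pairs),
    repurposing = grid(
      repurposing_genes, "clinical_investigation",
      "clinically investigated gene x GWAS disease without any investigated pair",
      explored),
    de_novo = grid(
      partition$undrugged, "undrugged",
      "druggable undrugged gene x GWAS disease",
      explored[0, c("gene", "cui")])
  )
  structure(out, class = "opportunity_lists")
}

#' Sample-space report A-D
#'
#' The four nested target-by-disease grids: (A) the gene universe by the
#' disease universe, (B) the druggable genome by the disease universe,
#' (C) clinically investigated targets by clinically investigated
#' indications, (D) approved targets by approved indications. `explored`
#' counts unique `(gene, cui)` pairings (stage ignored) inside each
#' bounding box; percentages are half-up rounded to one decimal.
#'
#' @param pairs A [build_pairs()] table.
#' @param partition A [partition_genome()] result.
#' @param constants List with `n_protein_coding` and `n_diseases` (the
#'   universe denominators).
#' @return Tibble with columns `label`, `n_targets`, `n_diseases`,
#'   `size`, `explored`, `explored_pct`.
#' @export
sample_space_report <- function(pairs, partition, constants) {
  uniq <- dplyr::distinct(pairs[, c("gene", "cui")])
  stage_diseases <- function(stage) {
    sort(unique(pairs$cui[pairs$stage == stage]))
  }
  clin_genes <- partition$clinical
  clin_dis <- stage_diseases("clinical")
  appr_genes <- partition$approved
  appr_dis <- stage_diseases("approved")
  in_box <- function(genes, diseases) {
    sum(uniq$gene %in% genes & uniq$cui %in% diseases)
  }
  appr_uniq <- dplyr::distinct(
    pairs[pairs$stage == "approved", c("gene", "cui")])
  rows <- tibble::tibble(
    label = c("A", "B", "C", "D"),
    n_targets = c(constants$n_protein_coding,
                  length(partition$druggable),
                  length(clin_genes), length(appr_genes)),
    n_diseases = c(constants$n_diseases, constants$n_diseases,
                   length(clin_dis), length(appr_dis)),
    explored = c(nrow(uniq),
                 sum(uniq$gene %in% partition$druggable),
                 in_box(clin_genes, clin_dis),
                 nrow(appr_uniq))
  )
  rows$size <- mapply(sample_space, rows$n_targets, rows$n_diseases)
  rows$explored_pct <- ifelse(
    rows$size > 0,
    mapply(percent_round, rows$explored, pmax(rows$size, 1),
           MoreArgs = list(decimals = 1L)),
    NA_real_)
  rows[, c("label", "n_targets", "n_diseases", "size", "explored",
           "explored_pct")]
}
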