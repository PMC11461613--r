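test_that("sample_space computes exact products and guards its domain", {
  expect_equal(sample_space(19813, 11158), 221073454)
  expect_equal(sample_space(4729, 11158), 52766182)
  expect_equal(sample_space(0, 11158), 0)
  expect_error(sample_space(-1, 5), "non-negative")
  expect_error(sample_space(2.5, 5), "non-negative")
  expect_error(sample_space(1e9, 1e9), "exceeds")
  # commutative and strictly monotone in each argument
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:5000, 1); b <- sample(1:5000, 1)
    expect_equal(sample_space(a, b), sample_space(b, a))
    expect_lt(sample_space(a, b), sample_space(a + 1, b))
    expect_lt(sample_space(a, b), sample_space(a, b + 1))
  }
})

test_that("percent_round rounds half-up at the stated precision", {
  expect_equal(percent_round(42199, 1706418, 1), 2.5)
  expect_equal(percent_round(3495, 4729, 1), 73.9)
  expect_equal(percent_round(5, 5, 0), 100)
  expect_equal(percent_round(125, 1000, 0), 13)   # 12.5 rounds up
  expect_equal(percent_round(1, 8, 1), 12.5)
  expect_error(percent_round(1, 0), "denominator")
})

test_that("membership_matrix handles disjoint, nested and degenerate cases", {
  m <- membership_matrix(list(x = "a", y = "b"))
  expect_equal(m$patterns$count[m$patterns$pattern == "10"], 1L)
  expect_equal(m$patterns$count[m$patterns$pattern == "01"], 1L)

  A <- letters[1:3]; B <- letters[1:10]
  m2 <- membership_matrix(list(A = A, B = B))
  expect_equal(m2$patterns$count[m2$patterns$pattern == "11"], 3L)
  expect_equal(m2$patterns$count[m2$patterns$pattern == "01"], 7L)
  expect_equal(m2$n_union, 10L)
  expect_equal(unname(m2$pairwise["A", "B"]), 3L)

  m3 <- membership_matrix(list(a = character(0), b = character(0)))
  expect_equal(m3$n_union, 0L)
  expect_equal(nrow(m3$patterns), 0L)
})

test_that("membership_matrix equals brute-force enumeration on random instances", {
  set.seed(12)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    sets <- lapply(seq_len(k), function(i) {
      sample(paste0("e", 1:50), sample(0:50, 1))
    })
    names(sets) <- paste0("s", seq_len(k))
    m <- membership_matrix(sets)
    oracle <- brute_membership(sets)
    got <- dplyr::arrange(m$patterns, pattern)
    want <- dplyr::arrange(oracle, pattern)
    expect_equal(got$pattern, want$pattern)
    expect_equal(got$count, want$count)
    expect_equal(sum(m$patterns$count), m$n_union)
  }
})

test_that("gwas_overlap_partition matches brute-force membership on random sets", {
  set.seed(21)
  for (rep in 1:100) {
    g <- sample(paste0("d", 1:100), sample(0:100, 1))
    d <- sample(paste0("d", 1:100), sample(0:100, 1))
    res <- gwas_overlap_partition(g, d)
    expect_equal(res$overlap, sum(g %in% d))
    expect_equal(res$gwas_only, sum(!g %in% d))
    expect_equal(res$devel_only, sum(!d %in% g))
    expect_equal(res$overlap + res$gwas_only, length(g))
  }
  identical_sets <- gwas_overlap_partition(letters, letters)
  expect_equal(identical_sets$gwas_only, 0L)
})

test_that("targets-per-indication quartiles use the inclusive median-of-halves method", {
  mk <- function(counts) {
    dplyr::bind_rows(lapply(seq_along(counts), function(i) {
      tibble::tibble(gene = paste0("g", seq_len(counts[i])),
                     cui = paste0("d", i))
    }))
  }
  s <- targets_per_indication_stats(mk(c(1, 2, 4)))
  expect_equal(s$median, 2)
  expect_equal(s$q1, 1)
  expect_equal(s$q3, 4)
  one <- targets_per_indication_stats(mk(5))
  expect_equal(c(one$q1, one$median, one$q3), c(5, 5, 5))
  expect_error(targets_per_indication_stats(mk(integer(0))), "empty")
})

test_that("quartiles agree with a sort-and-index oracle on random pair sets", {
  set.seed(33)
  for (rep in 1:100) {
    n_dis <- sample(1:200, 1)
    counts <- sample(1:40, n_dis, replace = TRUE)
    pairs <- dplyr::bind_rows(lapply(seq_len(n_dis), function(i) {
      tibble::tibble(gene = paste0("g", seq_len(counts[i])),
                     cui = paste0("d", i))
    }))
    s <- targets_per_indication_stats(pairs)
    # independent oracle: per-disease tally via table(), quartiles by
    # explicit positional indexing
    want <- oracle_quartiles(as.integer(table(pairs$cui)))
    expect_equal(unname(c(s$q1, s$median, s$q3)), unname(want))
  }
})

test_that("indications_per_target counts once per chapter with a unique rollup", {
  pairs <- tibble::tibble(gene = "g1", cui = c("d1", "d2", "d3"))
  chapters <- tibble::tibble(cui = c("d1", "d1", "d2"),
                             chapter = c("ch A", "ch B", "ch A"))
  res <- indications_per_target_counts(pairs, chapters, threshold = 0L)
  expect_equal(res$summary$unique_diseases, 3L)
  # d1 counted in two chapters, d3 unclassified: chapter-sum 4 > unique 3
  expect_equal(sum(res$by_chapter$n), 4L)
  high <- indications_per_target_counts(pairs, chapters, threshold = 25L)
  expect_equal(nrow(high$summary), 0L)
})

test_that("opportunity lists respect their strata and are pairwise disjoint", {
  pairs <- tibble::tibble(
    gene = c("gA", "gA", "gC", "gP"),
    cui = c("d1", "d2", "d3", "d4"),
    stage = c("approved", "clinical", "clinical", "preclinical"),
    druggable = TRUE)
  part <- partition_genome(pairs, c("gA", "gC", "gP", "gU"))
  gwas <- c("d1", "d3", "d9")
  opp <- opportunity_lists(part, pairs, gwas)
  exp <- opp$indication_expansion
  # (gA, d1) already approved: excluded; (gA, d2) clinical-only pairing
  # still counts as unexplored for approval
  expect_false(any(exp$gene == "gA" & exp$cui == "d1"))
  expect_true(any(exp$gene == "gA" & exp$cui == "d9"))
  rep_ <- opp$repurposing
  expect_setequal(unique(rep_$gene), c("gC", "gP"))
  expect_false(any(rep_$gene == "gC" & rep_$cui == "d3"))
  dn <- opp$de_novo
  expect_setequal(unique(dn$gene), "gU")
  expect_equal(nrow(dn), 3L)
  # disjoint by gene strata
  keys <- lapply(opp, function(df) paste(df$gene, df$cui))
  expect_equal(length(unlist(keys)), length(unique(unlist(keys))))
})

test_that("sample_space_report bounds explored pairs by each box", {
  world <- plain_world()
  run <- run_world_pipeline(world, key = "plain_run")
  sp <- run$sample_spaces
  expect_equal(sp$label, c("A", "B", "C", "D"))
  expect_true(all(sp$size == sp$n_targets * sp$n_diseases))
  expect_true(all(sp$explored <= sp$size))
  # the universe and druggable boxes nest around the clinical box
  expect_true(sp$size[1] >= sp$size[2] && sp$size[2] >= sp$size[3])
})
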