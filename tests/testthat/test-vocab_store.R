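test_that("read_mrconso builds one concept per CUI and honours the source filter", {
  p <- write_tmp_lines(c(
    mrconso_line("C1", "MSH", "D1", "Blue Fever"),
    mrconso_line("C1", "SNOMEDCT_US", "S1", "Blue fever disorder"),
    mrconso_line("C2", "OMIM", "O2", "Green ague")
  ))
  store <- read_mrconso(p)
  expect_equal(n_concepts(store), 2L)
  expect_equal(sum(store$synonyms$cui == "C1"), 2L)
  expect_equal(store$load_report$rows_read, 3L)
  expect_equal(store$load_report$rows_kept +
                 store$load_report$rows_skipped,
               store$load_report$rows_read)

  filtered <- read_mrconso(p, source_filter = "MSH")
  expect_equal(n_concepts(filtered), 1L)
  expect_equal(filtered$synonyms$cui, "C1")
  expect_equal(filtered$load_report$rows_skipped, 2L)
})

test_that("malformed rows are a hard error with the line number; empty files warn", {
  bad <- write_tmp_lines(c(mrconso_line("C1", "MSH", "D1", "x"),
                           "C2|too|few|fields"))
  expect_error(read_mrconso(bad), "line 2")
  empty <- write_tmp_lines(character(0))
  expect_warning(store <- read_mrconso(empty), "empty")
  expect_equal(n_concepts(store), 0L)
})

test_that("a written store round-trips through the MRCONSO dialect", {
  store <- tiny_store()
  p <- tempfile()
  write_mrconso(store, p)
  again <- read_mrconso(p)
  ord <- function(s) dplyr::arrange(s$synonyms[, c("cui", "sab", "code",
                                                   "term", "norm")],
                                    cui, sab, code, term)
  expect_equal(ord(again), ord(store))
})

test_that("normalize_term applies the fixed rule and is idempotent", {
  expect_equal(normalize_term("Crohn's Disease "), "crohn s disease")
  expect_equal(normalize_term("non-small cell lung cancer"),
               "non small cell lung cancer")
  expect_equal(normalize_term(""), "")
  cases <- c("ab-ba  CD", "x", "A.B,C", "  spaced   out ")
  expect_equal(normalize_term(normalize_term(cases)),
               normalize_term(cases))
})

test_that("lookup_exact matches normalized synonyms with optional source restriction", {
  store <- tiny_store()
  expect_equal(lookup_exact(store, "blue fever"), "C1")
  expect_equal(lookup_exact(store, "CROHN S DISEASE"), "C2")
  expect_equal(lookup_exact(store, "Grey Fever"), c("C3", "C4"))
  expect_equal(lookup_exact(store, "grey fever", source_filter = "MSH"),
               "C3")
  expect_equal(lookup_exact(store, "zzz not present"), character(0))
  expect_equal(lookup_code(store, "A01", "ICD10"), "C4")
})

test_that("lookup_exact agrees with a brute-force synonym scan on a generated store", {
  world <- plain_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  syn <- store$synonyms
  set.seed(99)
  queries <- c(sample(syn$term, 80),
               paste(sample(syn$term, 20), "xq"))  # 20 guaranteed misses
  for (q in queries) {
    brute <- sort(unique(syn$cui[normalize_term(syn$term) ==
                                   normalize_term(q)]))
    expect_identical(lookup_exact(store, q), brute)
  }
})

test_that("generated worlds round-trip exactly the planted CUIs", {
  world <- plain_world()
  store <- read_mrconso(world$paths[["mrconso"]])
  expect_setequal(unique(store$synonyms$cui), world$tables$concepts$cui)
})

test_that("read_semantic_types unions types per CUI and rejects unknown names", {
  p <- write_tmp_lines(c(mrsty_line("C1", "Disease or Syndrome"),
                         mrsty_line("C1", "Finding")))
  tab <- read_semantic_types(p)
  expect_equal(semantic_types_of(tab, "C1")[["C1"]],
               c("Disease or Syndrome", "Finding"))

  expect_equal(nrow(read_semantic_types(
    write_tmp_lines(character(0)))$rows), 0L)

  bad <- write_tmp_lines(mrsty_line("C1", "Imaginary Category"))
  expect_error(read_semantic_types(bad), "Imaginary Category")

  # case-insensitive canonicalization
  brit <- write_tmp_lines(mrsty_line("C9", "individual behavior"))
  expect_equal(read_semantic_types(brit)$rows$sty, "Individual Behavior")
})

test_that("per-CUI semantic types equal the planted types in a generated world", {
  world <- plain_world()
  tab <- read_semantic_types(world$paths[["mrsty"]])
  got <- semantic_types_of(tab, world$tables$concepts$cui)
  expect_true(all(mapply(identical, unname(unlist(got)),
                         world$tables$concepts$sty)))
})
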