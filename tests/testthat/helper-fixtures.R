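# Shared fixture builders. Worlds are generated once per session and
# cached, since several test files exercise the same planted bundle.

mrconso_line <- function(cui, sab, code, str, n_fields = 18L) {
  f <- rep("", n_fields)
  f[1] <- cui; f[12] <- sab; f[14] <- code; f[15] <- str
  paste0(paste(f, collapse = "|"), "|")
}

mrsty_line <- function(cui, sty, n_fields = 6L) {
  f <- rep("", n_fields)
  f[1] <- cui; f[4] <- sty
  paste0(paste(f, collapse = "|"), "|")
}

write_tmp_lines <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# A small hand-built store: 4 concepts, mixed vocabularies, one shared
# synonym ("grey fever" under two CUIs).
tiny_store <- function() {
  p <- write_tmp_lines(c(
    mrconso_line("C1", "MSH", "D1", "Blue Fever"),
    mrconso_line("C1", "SNOMEDCT_US", "S1", "Blue fever disorder"),
    mrconso_line("C2", "MSH", "D2", "Crohn's Disease"),
    mrconso_line("C3", "MSH", "D3", "Grey Fever"),
    mrconso_line("C4", "OMIM", "O4", "grey fever"),
    mrconso_line("C4", "ICD10", "A01", "Grey fever (ICD)")
  ))
  read_mrconso(p)
}

tiny_types <- function() {
  p <- write_tmp_lines(c(
    mrsty_line("C1", "Disease or Syndrome"),
    mrsty_line("C2", "Disease or Syndrome"),
    mrsty_line("C3", "Disease or Syndrome"),
    mrsty_line("C4", "Finding")
  ))
  read_semantic_types(p)
}

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, maker) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- maker()
  .world_cache[[key]]
}

# Defaults: 150 concepts / 200 traits / 40 compounds, ambiguity 0.
plain_world <- function() {
  cached_world("plain", function() {
    generate_world(world_config(seed = 42L), tempfile("world_plain_"))
  })
}

edge_world <- function() {
  cached_world("edges", function() {
    plant_edge_cases(
      generate_world(world_config(seed = 42L), tempfile("world_edge_")))
  })
}

ambiguous_world <- function() {
  cached_world("amb", function() {
    generate_world(world_config(seed = 11L, ambiguity_rate = 0.25),
                   tempfile("world_amb_"))
  })
}

run_world_pipeline <- function(world, key = NULL) {
  maker <- function() {
    cfg <- run_config(world$dir, tempfile("atlas_out_"))
    suppressMessages(run_pipeline(cfg))
  }
  if (is.null(key)) maker() else cached_world(key, maker)
}

# Sort-and-index quartile oracle, independent of the package's grouped
# computation: explicit positional medians over the sorted halves (the
# median is left out of the halves when the count is odd).
oracle_quartiles <- function(v) {
  v <- sort(v)
  n <- length(v)
  mid <- function(w) {
    k <- length(w)
    if (k %% 2L == 1L) w[(k + 1L) / 2L] else (w[k / 2L] + w[k / 2L + 1L]) / 2
  }
  if (n == 1L) return(c(q1 = v, med = v, q3 = v))
  lower <- v[1:(n %/% 2L)]
  upper <- v[(n - n %/% 2L + 1L):n]
  c(q1 = mid(lower), med = mid(v), q3 = mid(upper))
}

# Brute-force membership oracle: classify every element of the union by
# direct membership tests, independent of membership_matrix().
brute_membership <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  pat <- vapply(universe, function(el) {
    paste(vapply(sets, function(s) as.integer(el %in% s), integer(1)),
          collapse = "")
  }, character(1))
  out <- table(pat)
  tibble::tibble(pattern = names(out), count = as.integer(out))
}
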