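# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a free-text term for exact matching
#'
#' Applies the fixed normalization rule used throughout the package for
#' "direct string matching": case-fold, replace punctuation with spaces,
#' collapse runs of whitespace, and strip leading/trailing space. The rule
#' is idempotent and performs no stemming, so morphological variants never
#' merge.
#'
#' @param term Character vector of terms. `NA` is treated as the empty
#'   string.
#' @return Character vector of normalized terms.
#' @examples
#' normalize_term("Crohn's Disease ")
#' normalize_term("non-small cell lung cancer")
#' @export
normalize_term <- function(term) {
  if (length(term) == 0L) return(character(0))
  term[is.na(term)] <- ""
  x <- tolower(term)
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(x)
}

# Tokenize an already-normalized string.
norm_tokens <- function(norm) {
  if (!nzchar(norm)) return(character(0))
  strsplit(norm, " ", fixed = TRUE)[[1]]
}

# Half-up rounding at `decimals` places (base round() is half-even).
round_half_up <- function(x, decimals = 0L) {
  p <- 10^decimals
  floor(x * p + 0.5) / p
}

# Write a character vector of lines with a trailing newline, LF endings,
# UTF-8 -- byte-identical across runs.
write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Read lines skipping '#'-prefixed header comments; returns lines plus the
# original line numbers (for error reporting).
read_data_lines <- function(path) {
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^#", raw) & nzchar(raw)
  list(lines = raw[keep], lineno = which(keep))
}

abort_fmt <- function(...) stop(sprintf(...), call. = FALSE)
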