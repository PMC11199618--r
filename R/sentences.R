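# Abbreviation-safe sentence splitting with faithful character offsets.

default_non_terminals <- function() {
  c("Fig.", "Figs.", "et al.", "e.g.", "i.e.", "cf.", "vs.", "ca.",
    "approx.", "no.", "No.", "Dr.", "Prof.")
}

#' Split document text into sentences
#'
#' Splits on runs of `.`, `!`, `?` followed by whitespace or end of text,
#' guarding a configurable list of non-terminal tokens (figure references,
#' Latin abbreviations) and single-letter initials ("A. B. took ...") so
#' they do not end a sentence. Offsets index the original text, so slicing
#' the input by each sentence's span reproduces its text exactly and the
#' slices plus inter-sentence gaps reconstruct the whole input.
#'
#' @param text A single document string.
#' @param non_terminals Character vector of dotted tokens that never end a
#'   sentence.
#' @return A tibble with one row per sentence: `index` (ordinal), `text`
#'   (whitespace-trimmed), `start`, `end` (1-based inclusive offsets into
#'   `text`). Empty/whitespace-only input yields zero rows.
#' @export
split_sentences <- function(text, non_terminals = default_non_terminals()) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble::tibble(index = integer(), text = character(),
                          start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  masked <- text
  # mask periods inside protected tokens (same-length substitution keeps offsets)
  for (tok in non_terminals) {
    hits <- gregexpr(tok, masked, fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      for (h in hits) {
        seg <- substr(masked, h, h + nchar(tok) - 1L)
        seg <- gsub(".", "\x01", seg, fixed = TRUE)
        substr(masked, h, h + nchar(tok) - 1L) <- seg
      }
    }
  }
  # mask single-letter initials: an uppercase letter + "." not preceded by a letter
  init <- gregexpr("(?<![[:alpha:]])[A-Z]\\.", masked, perl = TRUE)[[1]]
  if (init[1] != -1L) {
    for (h in init) substr(masked, h + 1L, h + 1L) <- "\x01"
  }

  ends <- gregexpr("[.!?]+(?=[[:space:]]|$)", masked, perl = TRUE)[[1]]
  lens <- attr(ends, "match.length")
  bounds <- if (ends[1] == -1L) integer() else as.integer(ends) + lens - 1L
  if (length(bounds) == 0L || max(bounds) < nchar(text)) {
    bounds <- c(bounds, nchar(text))
  }

  cursor <- 1L
  rows <- list()
  for (b in bounds) {
    raw <- substr(text, cursor, b)
    lead <- nchar(raw) - nchar(sub("^[[:space:]]+", "", raw))
    trail <- nchar(raw) - nchar(sub("[[:space:]]+$", "", raw))
    s <- cursor + lead
    e <- b - trail
    if (e >= s) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        text = substr(text, s, e), start = s, end = e)
    }
    cursor <- b + 1L
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  dplyr::bind_cols(tibble::tibble(index = seq_len(nrow(out))), out)
}
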