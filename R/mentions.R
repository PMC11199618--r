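# Dictionary matching within sentences and bait-partner co-mention
# extraction: the unit of mining evidence is a single sentence naming both
# the bait and at least one other dictionary entity.

#' Find dictionary mentions in a sentence
#'
#' Matches every dictionary alias against the sentence under the package
#' matching policy: matching is word-boundary anchored (the characters
#' flanking a hit must be non-alphanumeric), aliases of three characters or
#' fewer match case-sensitively while longer aliases match
#' case-insensitively, the longest alias wins at each position, and accepted
#' mentions never overlap. Greek letters and internal hyphens are normalised
#' on both the alias and the text side, so "HDAC-6" in text matches the
#' alias "HDAC6".
#'
#' @param sentence A single sentence string.
#' @param dict An `entity_dictionary` from [compile_dictionary()].
#' @return A tibble with one row per mention: `symbol`, `alias` (the
#'   dictionary surface form that matched), `start`, `end` (1-based
#'   inclusive offsets into `sentence`). Slicing the sentence by the span
#'   reproduces the alias up to the normalisation and case policy.
#' @export
find_mentions <- function(sentence, dict) {
  stopifnot(inherits(dict, "entity_dictionary"),
            is.character(sentence), length(sentence) == 1L)
  nm <- normalize_text_map(sentence)
  norm <- nm$norm
  lower <- tolower(norm)
  nlen <- nchar(norm)
  if (nlen == 0L) {
    return(tibble::tibble(symbol = character(), alias = character(),
                          start = integer(), end = integer()))
  }
  norm_chars <- strsplit(norm, "")[[1]]

  cand <- list()
  e <- dict$entries
  for (k in seq_len(nrow(e))) {
    pat <- e$alias_norm[k]
    hay <- if (e$case_sensitive[k]) norm else lower
    needle <- if (e$case_sensitive[k]) pat else tolower(pat)
    hits <- gregexpr(needle, hay, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    plen <- nchar(pat)
    for (h in as.integer(hits)) {
      before_ok <- h == 1L || !is_alnum_chr(norm_chars[h - 1L])
      after <- h + plen
      after_ok <- after > nlen || !is_alnum_chr(norm_chars[after])
      if (before_ok && after_ok) {
        cand[[length(cand) + 1L]] <- list(
          symbol = e$symbol[k], alias = e$alias[k], npos = h, nlen = plen)
      }
    }
  }
  if (length(cand) == 0L) {
    return(tibble::tibble(symbol = character(), alias = character(),
                          start = integer(), end = integer()))
  }
  cd <- dplyr::bind_rows(lapply(cand, tibble::as_tibble))
  cd <- dplyr::arrange(cd, .data$npos, dplyr::desc(.data$nlen), .data$symbol)
  keep <- logical(nrow(cd))
  last_end <- 0L
  for (i in seq_len(nrow(cd))) {
    if (cd$npos[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cd$npos[i] + cd$nlen[i] - 1L
    }
  }
  cd <- cd[keep, , drop = FALSE]
  tibble::tibble(
    symbol = cd$symbol,
    alias = cd$alias,
    start = nm$map[cd$npos],
    end = nm$map[cd$npos + cd$nlen - 1L]
  )
}

#' Extract bait-partner co-mentions from a document
#'
#' Splits the document into sentences and keeps every sentence that names
#' both the bait and at least one other dictionary entity. Sentences naming
#' only the bait, or only partners, contribute nothing.
#'
#' @param text Document plain text.
#' @param doc_id Article identifier attached to the evidence.
#' @param dict An `entity_dictionary`; must contain the bait.
#' @param non_terminals Passed to [split_sentences()].
#' @return A tibble with one row per qualifying sentence: `doc_id`,
#'   `sentence_index`, `sentence`, `sentence_start`, `sentence_end`,
#'   `bait_symbol`, `bait_alias`, `bait_start`, `bait_end`, and `partners`
#'   (a list-column of per-partner mention tibbles; partner symbols are
#'   distinct within a sentence).
#' @export
extract_comentions <- function(text, doc_id, dict,
                               non_terminals = default_non_terminals()) {
  stopifnot(inherits(dict, "entity_dictionary"))
  bait <- dict$bait_symbol
  if (!bait %in% dict$entries$symbol) {
    abort("The dictionary does not contain the bait symbol.")
  }
  sents <- split_sentences(text, non_terminals)
  empty <- tibble::tibble(
    doc_id = character(), sentence_index = integer(), sentence = character(),
    sentence_start = integer(), sentence_end = integer(),
    bait_symbol = character(), bait_alias = character(),
    bait_start = integer(), bait_end = integer(), partners = list()
  )
  if (nrow(sents) == 0L) return(empty)

  rows <- list()
  for (i in seq_len(nrow(sents))) {
    m <- find_mentions(sents$text[i], dict)
    if (nrow(m) == 0L) next
    bm <- m[m$symbol == bait, , drop = FALSE]
    pm <- m[m$symbol != bait, , drop = FALSE]
    if (nrow(bm) == 0L || nrow(pm) == 0L) next
    pm <- dplyr::distinct(pm, .data$symbol, .keep_all = TRUE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      doc_id = doc_id,
      sentence_index = sents$index[i],
      sentence = sents$text[i],
      sentence_start = sents$start[i],
      sentence_end = sents$end[i],
      bait_symbol = bait,
      bait_alias = bm$alias[1],
      bait_start = bm$start[1],
      bait_end = bm$end[1],
      partners = list(pm)
    )
  }
  if (length(rows) == 0L) return(empty)
  dplyr::bind_rows(rows)
}

#' Fan co-mentions out into a curation sheet
#'
#' One row per (document, sentence, partner symbol), with empty curator
#' columns for the manual classification step: `interaction_class`
#' (direct/indirect/reject), `subnetwork`, `direction`, `mode_of_action`,
#' `mode_direction`, `complex_id`, `binding_domains`, `notes`. Rows are
#' deduplicated and stably sorted by partner symbol, then document, then
#' sentence order, so identical inputs give byte-identical sheets.
#'
#' @param comentions Tibble from [extract_comentions()] (rows from several
#'   documents may be bound together).
#' @return The curation sheet tibble.
#' @export
export_curation_sheet <- function(comentions) {
  cols <- c("partner", "doc_id", "sentence", "interaction_class", "subnetwork",
            "direction", "mode_of_action", "mode_direction", "complex_id",
            "binding_domains", "notes")
  if (nrow(comentions) == 0L) {
    out <- tibble::as_tibble(setNames(rep(list(character()), length(cols)), cols))
    return(out)
  }
  long <- tidyr::unnest(
    dplyr::select(comentions, "doc_id", "sentence_index", "sentence", "partners"),
    "partners")
  out <- tibble::tibble(
    partner = long$symbol,
    doc_id = long$doc_id,
    sentence = long$sentence,
    interaction_class = "",
    subnetwork = "",
    direction = "",
    mode_of_action = "",
    mode_direction = "",
    complex_id = "",
    binding_domains = "",
    notes = "",
    .sentence_index = long$sentence_index
  )
  out <- dplyr::distinct(out, .data$partner, .data$doc_id, .data$sentence,
                         .keep_all = TRUE)
  out <- dplyr::arrange(out, .data$partner, .data$doc_id, .data$.sentence_index)
  dplyr::select(out, -".sentence_index")
}

#' Write / read a curation sheet as TSV
#'
#' @param sheet A curation sheet tibble.
#' @param path File path.
#' @return `write_curation_sheet` returns `path` invisibly;
#'   `read_curation_sheet` returns the sheet tibble with all columns as
#'   character (empty strings for blank curator cells).
#' @export
write_curation_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path, na = "")
  invisible(path)
}

#' @rdname write_curation_sheet
#' @export
read_curation_sheet <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  out[is.na(out)] <- ""
  tibble::as_tibble(out)
}
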