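# Entity dictionary: surface forms collected from annotation payloads (or
# supplied directly), normalised to approved gene symbols. Genes and their
# protein products are treated as one entity.

#' Compile an entity dictionary from a name shortlist
#'
#' Maps each shortlisted surface form to its approved gene symbol through the
#' supplied name-to-symbol table and assembles, per symbol, the alias set
#' used for sentence matching (the symbol itself plus every mapped surface
#' form). Names absent from the map are reported separately, never silently
#' dropped. An alias that would map to two different symbols after
#' normalisation is an error naming both symbols.
#'
#' @param shortlist Character vector of gene/protein names, or a tibble with
#'   an `exact_text` column (e.g. from [filter_annotations()]).
#' @param hgnc_map A data frame with columns `alias` (or `name`) and
#'   `symbol` giving the approved-symbol mapping.
#' @param bait_symbol Approved symbol of the bait protein; always entered in
#'   the dictionary.
#' @param bait_aliases Extra surface forms for the bait (defaults to the
#'   symbol plus its lexical variants via [alias_variants()]).
#' @return An `entity_dictionary`: list with `entries` (tibble `symbol`,
#'   `alias`, `alias_norm`, `case_sensitive`), `bait_symbol`, and `unmapped`
#'   (character vector of names the map did not cover).
#' @export
compile_dictionary <- function(shortlist, hgnc_map, bait_symbol,
                               bait_aliases = NULL) {
  if (is.data.frame(shortlist)) {
    if (!"exact_text" %in% names(shortlist)) {
      abort("A data-frame `shortlist` must have an `exact_text` column.")
    }
    shortlist <- shortlist$exact_text
  }
  shortlist <- unique(shortlist[!is.na(shortlist) & nzchar(shortlist)])
  hgnc_map <- tibble::as_tibble(hgnc_map)
  if ("name" %in% names(hgnc_map) && !"alias" %in% names(hgnc_map)) {
    hgnc_map <- dplyr::rename(hgnc_map, alias = "name")
  }
  if (!all(c("alias", "symbol") %in% names(hgnc_map))) {
    abort("`hgnc_map` needs columns `alias` (or `name`) and `symbol`.")
  }

  lookup_key <- tolower(vapply(hgnc_map$alias, normalize_alias, character(1)))
  lut <- split(hgnc_map$symbol, lookup_key)

  resolve <- function(name) {
    key <- tolower(normalize_alias(name))
    syms <- unique(unlist(lut[key]))
    # a symbol maps to itself even without a map row
    if (length(syms) == 0L && name %in% hgnc_map$symbol) syms <- name
    syms
  }

  mapped <- lapply(shortlist, resolve)
  hit <- lengths(mapped) > 0L
  unmapped <- shortlist[!hit]
  multi <- lengths(mapped) > 1L
  if (any(multi)) {
    bad <- which(multi)[1]
    abort(sprintf("Alias '%s' maps to multiple symbols: %s.",
                  shortlist[bad], paste(mapped[[bad]], collapse = ", ")))
  }

  entries <- tibble::tibble(
    symbol = unlist(mapped[hit], use.names = FALSE) %||% character(),
    alias = shortlist[hit]
  )
  if (is.null(bait_aliases)) bait_aliases <- alias_variants(bait_symbol)
  entries <- dplyr::bind_rows(
    entries,
    tibble::tibble(symbol = bait_symbol, alias = bait_aliases),
    tibble::tibble(symbol = unique(entries$symbol), alias = unique(entries$symbol))
  )
  entries$alias_norm <- vapply(entries$alias, normalize_alias, character(1))
  entries$case_sensitive <- nchar(entries$alias_norm) <= 3L
  entries <- dplyr::distinct(entries, .data$symbol, .data$alias_norm,
                             .keep_all = TRUE)

  # cross-symbol collisions after normalisation must be resolved, not ignored
  key <- ifelse(entries$case_sensitive, entries$alias_norm,
                tolower(entries$alias_norm))
  coll <- split(entries$symbol, key)
  coll <- coll[vapply(coll, function(s) length(unique(s)) > 1L, logical(1))]
  if (length(coll) > 0L) {
    abort(sprintf("Alias '%s' maps to multiple symbols: %s.",
                  names(coll)[1], paste(unique(coll[[1]]), collapse = ", ")))
  }

  structure(
    list(entries = entries, bait_symbol = bait_symbol, unmapped = unmapped),
    class = "entity_dictionary"
  )
}

#' @export
print.entity_dictionary <- function(x, ...) {
  cat(sprintf("<entity_dictionary> bait %s; %d symbols, %d aliases; %d unmapped name(s)\n",
              x$bait_symbol, length(unique(x$entries$symbol)),
              nrow(x$entries), length(x$unmapped)))
  invisible(x)
}
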