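# Corpus ingestion: query construction, PRISMA-style screening ledger,
# and parsing of named-entity annotation payloads.

#' Build a boolean literature-search query
#'
#' Formats a query string combining bait-protein aliases with context terms:
#' aliases are OR-joined, and the alias block is AND-joined with the OR-joined
#' context block. Multi-word terms are double-quoted. With a single alias and
#' no context terms the query is the bare alias.
#'
#' @param bait_aliases Character vector of names for the bait protein
#'   (e.g. `c("HDAC6", "Histone Deacetylase 6")`). Must be non-empty.
#' @param context_terms Character vector of tissue/context terms OR-joined
#'   against the aliases (may be empty).
#' @param expand_variants If `TRUE`, each single-word alias is expanded with
#'   common lexical variants (hyphen before trailing digits, title case,
#'   lower case) via [alias_variants()].
#' @return A single query string; deterministic given its inputs.
#' @examples
#' build_query(c("HDAC6", "Histone Deacetylase 6"), c("Brain", "Neurons"))
#' @export
build_query <- function(bait_aliases, context_terms = character(),
                        expand_variants = FALSE) {
  bait_aliases <- bait_aliases[!is.na(bait_aliases) & nzchar(bait_aliases)]
  if (length(bait_aliases) == 0L) {
    abort("`bait_aliases` must contain at least one non-empty alias.")
  }
  if (isTRUE(expand_variants)) {
    bait_aliases <- unique(unlist(lapply(bait_aliases, alias_variants)))
  }
  context_terms <- context_terms[!is.na(context_terms) & nzchar(context_terms)]

  quote_term <- function(x) ifelse(grepl("\\s", x), paste0('"', x, '"'), x)
  alias_block <- paste(quote_term(unique(bait_aliases)), collapse = " OR ")
  if (length(context_terms) == 0L) {
    return(alias_block)
  }
  ctx_block <- paste(quote_term(unique(context_terms)), collapse = " OR ")
  paste0("(", alias_block, ") AND (", ctx_block, ")")
}

#' Lexical variants of a gene/protein alias
#'
#' For a single-word alias, returns the alias plus a hyphenated form at the
#' letter-digit boundary (HDAC6 -> HDAC-6), the title-case form (Hdac6), and
#' the lower-case form (hdac6). Multi-word aliases are returned unchanged.
#'
#' @param alias A single alias string.
#' @return Character vector of unique variants, the original first.
#' @export
alias_variants <- function(alias) {
  stopifnot(is.character(alias), length(alias) == 1L)
  if (grepl("\\s", alias)) return(alias)
  hyph <- sub("([A-Za-z])([0-9])", "\\1-\\2", alias)
  title <- paste0(toupper(substr(alias, 1, 1)), tolower(substring(alias, 2)))
  unique(c(alias, hyph, title, tolower(alias)))
}

#' Read an article-corpus manifest
#'
#' The manifest is a TSV with one row per retrieved article. Recognised
#' columns: `article_id` (required), `pmid`, `pmcid`, `title`, `language`
#' (ISO code), `open_access` (logical), `fulltext_ref` (path to a plain-text
#' body, relative to the manifest location), `abstract`. Missing optional
#' columns are filled with `NA`.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with the columns above.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"article_id" %in% names(df)) {
    abort("Manifest must contain an `article_id` column.")
  }
  for (col in c("pmid", "pmcid", "title", "language", "fulltext_ref", "abstract")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (!"open_access" %in% names(df)) {
    df$open_access <- NA
  } else {
    df$open_access <- as.logical(df$open_access)
  }
  dir <- dirname(path)
  df$fulltext_ref <- ifelse(
    is.na(df$fulltext_ref) | df$fulltext_ref == "", NA_character_,
    file.path(dir, df$fulltext_ref)
  )
  tibble::as_tibble(df)
}

record_identifiers <- function(df, i) {
  ids <- c(df$article_id[i],
           if ("pmid" %in% names(df)) df$pmid[i],
           if ("pmcid" %in% names(df)) df$pmcid[i])
  unique(ids[!is.na(ids) & nzchar(ids)])
}

#' Screen an article corpus into a PRISMA-style ledger
#'
#' Applies the screening rules in order: records sharing an identifier (PMID,
#' PMCID or article id) with an earlier retained record are marked
#' `duplicate`; non-English records are `excluded` (`not_english`); records
#' with neither a full-text reference nor an abstract are `excluded`
#' (`no_fulltext`); records whose identifier appears in `off_topic_ids` —
#' the externally supplied full-text screening verdicts — are `excluded`
#' (`off_topic`); everything else is `included`.
#'
#' @param records A data frame of article records (see [read_manifest()]);
#'   each record must carry at least one identifier.
#' @param off_topic_ids Character vector of identifiers judged off-topic
#'   during manual full-text screening. The tool records these verdicts, it
#'   does not make them.
#' @return A `screening_ledger`: the input tibble with `status`
#'   (`retrieved`/`duplicate`/`excluded`/`included` — `retrieved` never
#'   survives screening) and `exclusion_reason`
#'   (`not_english`/`no_fulltext`/`off_topic`/`none`) columns.
#'   Use [glance.screening_ledger()] for the summary counts.
#' @export
screen_articles <- function(records, off_topic_ids = character()) {
  records <- tibble::as_tibble(records)
  class(records) <- setdiff(class(records), "screening_ledger")
  if (nrow(records) > 0 &&
      any(vapply(seq_len(nrow(records)),
                 function(i) length(record_identifiers(records, i)) == 0L,
                 logical(1)))) {
    abort("Every record must carry at least one identifier.")
  }
  # drop any previous screening columns so re-screening is idempotent
  records$status <- NULL
  records$exclusion_reason <- NULL

  n <- nrow(records)
  status <- character(n)
  reason <- rep("none", n)
  seen <- new.env(parent = emptyenv())

  for (i in seq_len(n)) {
    ids <- record_identifiers(records, i)
    hit <- ids[vapply(ids, function(id) !is.null(seen[[id]]), logical(1))]
    if (length(hit) > 0L) {
      status[i] <- "duplicate"
      first <- seen[[hit[[1]]]]
      if (!identical(records$title[i], records$title[first]) &&
          !is.na(records$title[i]) && !is.na(records$title[first])) {
        warn(sprintf(
          "Identifier collision with conflicting metadata (%s); first-seen record retained.",
          hit[[1]]))
      }
      next
    }
    for (id in ids) seen[[id]] <- i
    lang <- records$language[i] %||% NA_character_
    has_text <- (!is.na(records$fulltext_ref[i]) && nzchar(records$fulltext_ref[i])) ||
      (!is.na(records$abstract[i]) && nzchar(records$abstract[i]))
    if (!is.na(lang) && !tolower(lang) %in% c("en", "eng", "english")) {
      status[i] <- "excluded"; reason[i] <- "not_english"
    } else if (!has_text) {
      status[i] <- "excluded"; reason[i] <- "no_fulltext"
    } else if (any(ids %in% off_topic_ids)) {
      status[i] <- "excluded"; reason[i] <- "off_topic"
    } else {
      status[i] <- "included"
    }
  }
  records$status <- status
  records$exclusion_reason <- reason
  class(records) <- c("screening_ledger", class(records))
  records
}

#' Summary counts of a screening ledger
#'
#' @param x A `screening_ledger` from [screen_articles()].
#' @param ... Unused.
#' @return A one-row tibble: `retrieved`, `duplicates`,
#'   `after_dedup_and_screen`, `excluded_not_english`,
#'   `excluded_no_fulltext`, `excluded_off_topic`, `included`. Satisfies
#'   `retrieved = duplicates + after_dedup_and_screen` and
#'   `included = after_dedup_and_screen - sum(excluded_*)`.
#' @method glance screening_ledger
#' @export
glance.screening_ledger <- function(x, ...) {
  tibble::tibble(
    retrieved = nrow(x),
    duplicates = sum(x$status == "duplicate"),
    after_dedup_and_screen = sum(x$status != "duplicate"),
    excluded_not_english = sum(x$exclusion_reason == "not_english"),
    excluded_no_fulltext = sum(x$exclusion_reason == "no_fulltext"),
    excluded_off_topic = sum(x$exclusion_reason == "off_topic"),
    included = sum(x$status == "included")
  )
}

#' @export
print.screening_ledger <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<screening_ledger> %d retrieved; %d duplicates; %d excluded (%d not English, %d no full text, %d off-topic); %d included\n",
    g$retrieved, g$duplicates,
    g$excluded_not_english + g$excluded_no_fulltext + g$excluded_off_topic,
    g$excluded_not_english, g$excluded_no_fulltext, g$excluded_off_topic,
    g$included))
  NextMethod()
}

#' Export a screening ledger to TSV
#'
#' Writes one row per article followed by a comment block with the summary
#' box counts.
#'
#' @param ledger A `screening_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  readr::write_tsv(tibble::as_tibble(ledger)[, , drop = FALSE], path)
  g <- glance(ledger)
  lines <- sprintf("# %s\t%d", names(g), as.integer(g[1, ]))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Parse a named-entity annotation payload
#'
#' Reads an annotation payload in the Europe PMC annotations-by-id response
#' shape: a JSON array of documents, each with identifier fields (`pmcid`,
#' `extId`, or `id`) and an `annotations` array whose elements carry `exact`
#' (the matched surface string), `type`, `section`, `prefix`, `postfix`, and
#' a `tags` array of `{name, uri}` objects. The surface string is preserved
#' byte-identically; no normalisation happens at parse time.
#'
#' @param payload Path to a JSON file, a JSON string, or an already-parsed
#'   list in the same shape.
#' @return A tibble with one row per annotation: `article_id`, `exact_text`,
#'   `ann_type`, `uri` (first tag URI or `NA`), `section`, `prefix`,
#'   `postfix`.
#' @export
parse_annotations <- function(payload) {
  docs <- if (is.list(payload)) {
    payload
  } else if (is.character(payload) && length(payload) == 1L) {
    tryCatch(jsonlite::fromJSON(payload, simplifyVector = FALSE),
             error = function(e) abort(paste0("Malformed annotation payload: ", conditionMessage(e))))
  } else {
    abort("`payload` must be a file path, JSON string, or parsed list.")
  }
  if (!is.null(docs$annotations)) docs <- list(docs)  # single-document payload

  rows <- purrr::imap(docs, function(doc, d) {
    if (!is.list(doc)) {
      abort(sprintf("Malformed annotation payload: document %s is not an object.", d))
    }
    id <- doc$pmcid %||% doc$extId %||% doc$id %||% doc$pmid
    if (is.null(id)) {
      abort(sprintf("Malformed annotation payload: document %s has no identifier.", d))
    }
    anns <- doc$annotations %||% list()
    purrr::imap(anns, function(a, j) {
      if (is.null(a$exact) || !nzchar(a$exact)) {
        abort(sprintf(
          "Malformed annotation payload: annotation %s of document %s lacks a non-empty 'exact' field.",
          j, d))
      }
      uri <- NA_character_
      if (length(a$tags) >= 1L && !is.null(a$tags[[1]]$uri)) uri <- a$tags[[1]]$uri
      tibble::tibble(
        article_id = as.character(id),
        exact_text = as.character(a$exact),
        ann_type = as.character(a$type %||% NA_character_),
        uri = uri,
        section = as.character(a$section %||% NA_character_),
        prefix = as.character(a$prefix %||% NA_character_),
        postfix = as.character(a$postfix %||% NA_character_)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0L) {
    out <- tibble::tibble(article_id = character(), exact_text = character(),
                          ann_type = character(), uri = character(),
                          section = character(), prefix = character(),
                          postfix = character())
  }
  out
}

#' Filter annotations to gene/protein evidence
#'
#' Retains annotations whose type equals the gene/protein category, or whose
#' type equals the gene-disease-relationship category *and* whose URI is a
#' UniProt identifier. A pure, order-preserving, idempotent filter. The
#' provider category strings are configurable because annotation
#' vocabularies drift between releases.
#'
#' @param records Tibble from [parse_annotations()].
#' @param gene_protein_type Provider string for gene/protein annotations.
#' @param gene_disease_type Provider string for gene-disease relationships.
#' @return The retained rows, original order preserved.
#' @export
filter_annotations <- function(records,
                               gene_protein_type = "Gene_Proteins",
                               gene_disease_type = "Gene Disease Relationship") {
  is_uniprot <- !is.na(records$uri) &
    grepl("uniprot", records$uri, ignore.case = TRUE)
  keep <- records$ann_type == gene_protein_type |
    (records$ann_type == gene_disease_type & is_uniprot)
  records[!is.na(keep) & keep, , drop = FALSE]
}
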