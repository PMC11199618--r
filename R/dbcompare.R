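# Comparison of the literature network against reference PPI edge sets,
# with identifier mapping (lowest-Entrez tie-break) and brain-expression
# filtering of database-only interactors.

#' Read a reference PPI edge table
#'
#' TSV with columns `bait_id`, `partner_id`, `namespace` (`uniprot` or
#' `entrez`), `source_db`.
#'
#' @param path Path to the TSV.
#' @return A tibble of reference edges.
#' @export
read_reference_edges <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("bait_id", "partner_id", "namespace", "source_db")
  if (!all(need %in% names(df))) {
    abort(paste0("Reference edge table must have columns: ",
                 paste(need, collapse = ", "), "."))
  }
  bad <- setdiff(unique(df$namespace), c("uniprot", "entrez"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown identifier namespace(s): ", paste(bad, collapse = ", "), "."))
  }
  tibble::as_tibble(df)
}

#' Map protein/gene identifiers to Entrez ids and symbols
#'
#' Resolves UniProt accessions and Entrez ids through a mapping table.
#' A UniProt accession with several Entrez candidates resolves to the
#' numerically smallest Entrez id (the earliest-assigned gene); the choice
#' is deterministic. Identifiers absent from the table are routed to the
#' unmapped report, never raised as errors.
#'
#' @param ids A data frame with columns `id` and `namespace` (`uniprot` or
#'   `entrez`), or a character vector of Entrez ids.
#' @param mapping A data frame with columns `uniprot`, `entrez`, `symbol`
#'   (one row per UniProt-Entrez pair; `uniprot` may be `NA` for
#'   Entrez-only rows).
#' @return A tibble `id`, `namespace`, `entrez`, `symbol` with `NA` for
#'   unmapped ids; the unmapped ids are also attached as the `unmapped`
#'   attribute.
#' @export
map_ids <- function(ids, mapping) {
  if (is.character(ids)) {
    ids <- tibble::tibble(id = ids, namespace = "entrez")
  }
  ids <- tibble::as_tibble(ids)
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("id", "namespace") %in% names(ids)),
            all(c("entrez", "symbol") %in% names(mapping)))
  if (!"uniprot" %in% names(mapping)) mapping$uniprot <- NA_character_
  mapping$entrez <- as.character(mapping$entrez)

  resolve_one <- function(id, ns) {
    if (ns == "entrez") {
      hit <- mapping[!is.na(mapping$entrez) & mapping$entrez == id, ]
      if (nrow(hit) == 0L) return(c(id, NA_character_))   # id kept, symbol unknown
      return(c(id, hit$symbol[1]))
    }
    hit <- mapping[!is.na(mapping$uniprot) & mapping$uniprot == id, ]
    if (nrow(hit) == 0L) return(c(NA_character_, NA_character_))
    # lowest-numbered Entrez id wins for non-unique mappings
    ord <- order(suppressWarnings(as.numeric(hit$entrez)))
    c(hit$entrez[ord[1]], hit$symbol[ord[1]])
  }
  res <- t(vapply(seq_len(nrow(ids)),
                  function(i) resolve_one(ids$id[i], ids$namespace[i]),
                  character(2)))
  out <- tibble::tibble(
    id = ids$id, namespace = ids$namespace,
    entrez = if (nrow(ids)) res[, 1] else character(),
    symbol = if (nrow(ids)) res[, 2] else character()
  )
  attr(out, "unmapped") <- out$id[is.na(out$entrez)]
  out
}

#' Merge two reference edge sets into one partner set
#'
#' Maps both edge sets to Entrez ids and takes their union, retaining
#' per-partner source-database provenance.
#'
#' @param setA,setB Reference edge tibbles (see [read_reference_edges()]).
#' @param mapping Identifier mapping table (see [map_ids()]).
#' @return A tibble `entrez`, `symbol`, `source_dbs` (semicolon-joined,
#'   sorted), one row per distinct Entrez partner; unmapped partner ids
#'   attached as the `unmapped` attribute.
#' @export
merge_references <- function(setA, setB, mapping) {
  both <- dplyr::bind_rows(tibble::as_tibble(setA), tibble::as_tibble(setB))
  if (nrow(both) == 0L) {
    out <- tibble::tibble(entrez = character(), symbol = character(),
                          source_dbs = character())
    attr(out, "unmapped") <- character()
    return(out)
  }
  mapped <- map_ids(
    tibble::tibble(id = both$partner_id, namespace = both$namespace), mapping)
  both$entrez <- mapped$entrez
  both$symbol <- mapped$symbol
  unmapped <- unique(both$partner_id[is.na(both$entrez)])
  both <- both[!is.na(both$entrez), , drop = FALSE]
  out <- both |>
    dplyr::group_by(.data$entrez) |>
    dplyr::summarise(
      symbol = dplyr::first(.data$symbol[!is.na(.data$symbol)]),
      source_dbs = paste(sort(unique(.data$source_db)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$entrez)
  attr(out, "unmapped") <- unmapped
  out
}

#' Compare the literature network with a reference partner set
#'
#' Three-way partition of partners by Entrez id: `shared` (in both),
#' `literature_only` (network only), `database_only` (references only).
#' The partition is disjoint and `shared + literature_only` equals the
#' number of mappable network partners.
#'
#' @param net A `ppi_network`.
#' @param reference Unified partner set from [merge_references()].
#' @param mapping Identifier mapping table with `entrez` and `symbol`
#'   columns; network symbols are joined to Entrez ids through it.
#' @return An `overlap_report` tibble with one row per partner: `symbol`,
#'   `entrez`, `category`; network symbols with no Entrez mapping are
#'   attached as the `unmapped` attribute (excluded from counts). Use
#'   [glance.overlap_report()] for the counts.
#' @export
compare_network <- function(net, reference, mapping) {
  mapping <- tibble::as_tibble(mapping)
  mapping$entrez <- as.character(mapping$entrez)
  net_symbols <- unique(net$nodes$partner)
  net_entrez <- mapping$entrez[match(net_symbols, mapping$symbol)]
  unmapped <- net_symbols[is.na(net_entrez)]
  keep <- !is.na(net_entrez)
  net_tbl <- tibble::tibble(symbol = net_symbols[keep],
                            entrez = net_entrez[keep])

  shared <- net_tbl[net_tbl$entrez %in% reference$entrez, , drop = FALSE]
  lit_only <- net_tbl[!net_tbl$entrez %in% reference$entrez, , drop = FALSE]
  db_only <- reference[!reference$entrez %in% net_tbl$entrez, , drop = FALSE]

  out <- dplyr::bind_rows(
    tibble::tibble(symbol = shared$symbol, entrez = shared$entrez,
                   category = "shared"),
    tibble::tibble(symbol = lit_only$symbol, entrez = lit_only$entrez,
                   category = "literature_only"),
    tibble::tibble(symbol = db_only$symbol, entrez = db_only$entrez,
                   category = "database_only")
  )
  out <- dplyr::arrange(out, .data$category, .data$symbol)
  attr(out, "unmapped") <- unmapped
  class(out) <- c("overlap_report", class(out))
  out
}

#' Counts of an overlap report
#'
#' @param x An `overlap_report` from [compare_network()].
#' @param ... Unused.
#' @return One-row tibble: `shared`, `literature_only`, `database_only`,
#'   `network_total` (shared + literature_only).
#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(
    shared = sum(x$category == "shared"),
    literature_only = sum(x$category == "literature_only"),
    database_only = sum(x$category == "database_only"),
    network_total = sum(x$category %in% c("shared", "literature_only"))
  )
}

#' Read a normal-tissue expression table
#'
#' Human Protein Atlas "Normal tissue" TSV dialect: columns `Gene` (Ensembl
#' id), `Gene name` (symbol), `Tissue`, `Level`, `Reliability` (case and
#' dots in names tolerated).
#'
#' @param path Path to the TSV.
#' @return A tibble `gene`, `gene_name`, `tissue`, `level`, `reliability`
#'   with lower-case level/reliability vocabularies.
#' @export
read_expression_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  nm <- tolower(gsub("[ .]", "_", names(df)))
  names(df) <- nm
  need <- c("gene", "tissue", "level", "reliability")
  if (!all(need %in% nm)) {
    abort(paste0("Expression table must have columns Gene, Tissue, Level, ",
                 "Reliability (HPA normal-tissue dialect)."))
  }
  if (!"gene_name" %in% nm) df$gene_name <- NA_character_
  tibble::tibble(
    gene = df$gene, gene_name = df$gene_name, tissue = tolower(df$tissue),
    level = tolower(df$level), reliability = tolower(df$reliability)
  )
}

#' Filter candidate partners by brain expression
#'
#' Retains candidates with at least one expression record in a selected
#' region at a kept level. Records with reliability `uncertain` are removed
#' before the level test. Candidates with no expression record at all are
#' flagged rather than silently dropped. The filter is monotone: enlarging
#' `regions` or `keep_levels` never shrinks the retained set.
#'
#' @param candidates Character vector of gene identifiers (Ensembl ids or
#'   symbols), or a data frame with a `gene` or `symbol` column.
#' @param expr Expression tibble from [read_expression_table()].
#' @param regions Tissue regions to accept (default: the seven brain
#'   regions of [brain_regions()]).
#' @param keep_levels Expression levels that count as expressed
#'   (default `c("medium", "high")`).
#' @return A tibble `gene`, `status` (`retained` / `not_retained` /
#'   `no_data`); rows in candidate order.
#' @export
filter_brain_expressed <- function(candidates, expr,
                                   regions = brain_regions(),
                                   keep_levels = c("medium", "high")) {
  if (is.data.frame(candidates)) {
    col <- intersect(c("gene", "symbol", "entrez"), names(candidates))[1]
    if (is.na(col)) abort("`candidates` must have a gene/symbol column.")
    candidates <- candidates[[col]]
  }
  candidates <- as.character(candidates)
  expr <- tibble::as_tibble(expr)
  expr <- expr[expr$reliability != "uncertain", , drop = FALSE]
  key <- function(g) {
    hit <- expr$gene == g
    if ("gene_name" %in% names(expr)) {
      hit <- hit | (!is.na(expr$gene_name) & expr$gene_name == g)
    }
    hit
  }
  status <- vapply(candidates, function(g) {
    rec <- expr[key(g), , drop = FALSE]
    if (nrow(rec) == 0L) return("no_data")
    ok <- rec$tissue %in% tolower(regions) & rec$level %in% tolower(keep_levels)
    if (any(ok)) "retained" else "not_retained"
  }, character(1))
  tibble::tibble(gene = candidates, status = unname(status))
}
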