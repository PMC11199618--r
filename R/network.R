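# The typed bait-centric interaction network: direct partners partitioned
# over five subnetworks, binding-domain annotations on the bait, and the
# catalog of indirect (inhibition-response) targets.

#' Ordered functional-domain map of the HDAC6 bait
#'
#' The N-to-C arrangement of HDAC6 functional domains: nuclear localization
#' signal (NLS), first nuclear export signal (NES1), catalytic deacetylase
#' domain 1 (DD1), dynein motor binding domain (DMB), catalytic deacetylase
#' domain 2 (DD2), the Ser-Glu tetradecapeptide repeat (SE14), second
#' nuclear export signal (NES2), and the zinc-finger ubiquitin-binding
#' domain (ZnF-UBP, also called BUZ). Amino-acid coordinates are optional;
#' comparisons are by domain name.
#'
#' @return A tibble with columns `domain`, `start`, `end` (1-based
#'   inclusive amino-acid coordinates or `NA`).
#' @export
hdac6_domain_map <- function() {
  tibble::tibble(
    domain = c("NLS", "NES1", "DD1", "DMB", "DD2", "SE14", "NES2", "ZNF_UBP"),
    start = NA_integer_,
    end = NA_integer_
  )
}

empty_evidence <- function() {
  tibble::tibble(article_id = character(), sentence = character())
}

new_network <- function(bait, nodes, bindings, indirect,
                        domain_map = hdac6_domain_map(),
                        provenance = list()) {
  structure(
    list(bait = bait, nodes = nodes, bindings = bindings,
         indirect = indirect, domain_map = domain_map,
         provenance = provenance),
    class = "ppi_network"
  )
}

default_direction <- function(subnets) {
  if ("PHOSPHORYLATION" %in% subnets || "REGULATORY" %in% subnets) {
    "partner_to_bait"          # kinases and regulators act on the bait
  } else if ("DEACETYLATION" %in% subnets || "AGGRESOME_AUTOPHAGY" %in% subnets) {
    "bait_to_partner"          # substrates and cargo are acted on by the bait
  } else {
    "undirected"
  }
}

direction_levels <- function() {
  c("bait_to_partner", "partner_to_bait", "bidirectional", "undirected")
}

# default edge label by interaction category
subnetwork_label <- function(subnet) {
  lut <- c(DEACETYLATION = "deacetylation",
           PHOSPHORYLATION = "phosphorylates",
           PROTEIN_COMPLEX = "complex member",
           REGULATORY = "regulates",
           AGGRESOME_AUTOPHAGY = "aggresome-autophagy")
  out <- unname(lut[subnet])
  out[is.na(out)] <- "interacts with"
  out
}

#' Build the bait-centric network from a curated sheet
#'
#' Consumes a curation sheet in which every row has been classified
#' (`interaction_class` one of direct/indirect/reject). Direct rows merge
#' per partner (union of subnetworks, union of evidence sentences); rows
#' with a `binding_domains` entry populate the binding annotations;
#' indirect rows populate the inhibition-response catalog (one entry per
#' mode of action); rejected rows are dropped. Partner names are normalised
#' to approved symbols through `hgnc_map` when supplied.
#'
#' @param curated_sheet Curation-sheet tibble (see [export_curation_sheet()]
#'   for the columns) with curator columns filled in.
#' @param hgnc_map Optional `alias`/`symbol` table; when given, every
#'   partner name must resolve or an error lists the unmapped names.
#' @param bait Approved symbol of the bait protein.
#' @return A `ppi_network` object: list with `bait`, `nodes` (tibble
#'   `partner`, `subnetworks` list-column, `primary_subnetwork`,
#'   `direction`, `interaction_label`, `complex_id`, `evidence`
#'   list-column), `bindings`, `indirect`, `domain_map`, `provenance`.
#' @export
build_network <- function(curated_sheet, hgnc_map = NULL, bait = "HDAC6") {
  sheet <- tibble::as_tibble(curated_sheet)
  sheet[is.na(sheet)] <- ""
  cls <- sheet$interaction_class
  bad <- which(!cls %in% c("direct", "indirect", "reject"))
  if (length(bad) > 0L) {
    abort(sprintf("Unclassified or invalid `interaction_class` in row(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  direct <- sheet[cls == "direct", , drop = FALSE]
  nosub <- which(!nzchar(direct$subnetwork))
  if (length(nosub) > 0L) {
    abort(sprintf("Direct row(s) missing a subnetwork assignment: %s.",
                  paste(nosub, collapse = ", ")))
  }

  normalise <- function(x) {
    if (is.null(hgnc_map)) return(x)
    map <- tibble::as_tibble(hgnc_map)
    if ("name" %in% names(map) && !"alias" %in% names(map)) {
      map <- dplyr::rename(map, alias = "name")
    }
    key <- tolower(map$alias)
    out <- map$symbol[match(tolower(x), key)]
    out[x %in% map$symbol] <- x[x %in% map$symbol]
    if (anyNA(out)) {
      abort(sprintf("Unmapped partner name(s): %s.",
                    paste(unique(x[is.na(out)]), collapse = ", ")))
    }
    out
  }
  direct$partner <- normalise(direct$partner)

  nodes <- direct |>
    dplyr::group_by(.data$partner) |>
    dplyr::summarise(
      subnetworks = list(unique(unlist(split_multi(.data$subnetwork)))),
      direction = {
        d <- unique(.data$direction[nzchar(.data$direction)])
        if (length(d) == 0L) NA_character_
        else if (length(d) == 1L) d
        else "bidirectional"
      },
      interaction_label = NA_character_,
      complex_id = dplyr::first(c(.data$complex_id[nzchar(.data$complex_id)],
                                  NA_character_)),
      evidence = {
        aid <- .data$doc_id
        sen <- .data$sentence
        list(dplyr::distinct(tibble::tibble(article_id = aid, sentence = sen)))
      },
      .groups = "drop"
    )
  nodes$primary_subnetwork <- vapply(
    nodes$subnetworks, function(s) s[[1]], character(1))
  nodes$interaction_label <- subnetwork_label(nodes$primary_subnetwork)
  nodes$direction <- vapply(seq_len(nrow(nodes)), function(i) {
    if (is.na(nodes$direction[i])) default_direction(nodes$subnetworks[[i]])
    else nodes$direction[i]
  }, character(1))
  nodes <- dplyr::arrange(nodes, .data$partner)
  nodes <- dplyr::relocate(nodes, "partner", "subnetworks",
                           "primary_subnetwork", "direction",
                           "interaction_label", "complex_id", "evidence")

  bind_rows_ <- direct[nzchar(direct$binding_domains), , drop = FALSE]
  bindings <- tibble::tibble(
    partner = bind_rows_$partner,
    domains = split_multi(bind_rows_$binding_domains),
    reference = bind_rows_$doc_id
  )
  bindings <- bindings[lengths(bindings$domains) > 0L, , drop = FALSE]

  ind <- sheet[cls == "indirect", , drop = FALSE]
  ind$partner <- normalise(ind$partner)
  indirect <- if (nrow(ind) == 0L) {
    tibble::tibble(symbol = character(), mode = character(),
                   mode_direction = character(), evidence = list())
  } else {
    long <- tibble::tibble(
      symbol = rep(ind$partner, lengths(split_multi(ind$mode_of_action))),
      mode = unlist(split_multi(ind$mode_of_action)),
      mode_direction = rep(ind$mode_direction,
                           lengths(split_multi(ind$mode_of_action))),
      article_id = rep(ind$doc_id, lengths(split_multi(ind$mode_of_action))),
      sentence = rep(ind$sentence, lengths(split_multi(ind$mode_of_action)))
    )
    long$mode_direction[!long$mode %in% directed_modes()] <- ""
    long |>
      dplyr::group_by(.data$symbol, .data$mode, .data$mode_direction) |>
      dplyr::summarise(
        evidence = {
          aid <- .data$article_id
          sen <- .data$sentence
          list(dplyr::distinct(tibble::tibble(article_id = aid, sentence = sen)))
        },
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$symbol, .data$mode)
  }

  new_network(
    bait = bait, nodes = nodes, bindings = bindings, indirect = indirect,
    provenance = list(built = "build_network", n_sheet_rows = nrow(sheet))
  )
}

#' Validate a network against its structural invariants
#'
#' Checks the closed vocabularies and cross-references of the network
#' content model. An empty report means every invariant holds.
#'
#' @param net A `ppi_network`.
#' @return A tibble of violations (`component`, `symbol`, `message`);
#'   zero rows when the network is well-formed.
#' @export
validate_network <- function(net) {
  v <- list()
  add <- function(component, symbol, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      component = component, symbol = symbol, message = message)
  }
  nd <- net$nodes
  if (anyDuplicated(nd$partner)) {
    add("nodes", nd$partner[duplicated(nd$partner)][1], "duplicate node symbol")
  }
  for (i in seq_len(nrow(nd))) {
    s <- nd$partner[i]
    if (identical(s, net$bait)) add("nodes", s, "partner equals the bait")
    subs <- nd$subnetworks[[i]]
    if (length(subs) == 0L) add("nodes", s, "node belongs to no subnetwork")
    bad <- setdiff(subs, subnetwork_levels())
    if (length(bad) > 0L) {
      add("nodes", s, paste0("unknown subnetwork: ", paste(bad, collapse = ", ")))
    }
    if (!nd$direction[i] %in% direction_levels()) {
      add("nodes", s, paste0("invalid direction: ", nd$direction[i]))
    }
    ev <- nd$evidence[[i]]
    if (is.null(ev) || nrow(ev) == 0L) add("nodes", s, "empty evidence")
    has_complex <- !is.na(nd$complex_id[i]) && nzchar(nd$complex_id[i])
    in_complex_subnet <- "PROTEIN_COMPLEX" %in% subs
    if (has_complex != in_complex_subnet) {
      add("nodes", s,
          "complex_id must be present exactly when the node is in the PROTEIN_COMPLEX subnetwork")
    }
  }
  for (i in seq_len(nrow(net$bindings))) {
    bad <- setdiff(net$bindings$domains[[i]], net$domain_map$domain)
    if (length(bad) > 0L) {
      add("bindings", net$bindings$partner[i],
          paste0("unknown domain: ", paste(bad, collapse = ", ")))
    }
    if (length(net$bindings$domains[[i]]) == 0L) {
      add("bindings", net$bindings$partner[i], "empty domain set")
    }
  }
  for (i in seq_len(nrow(net$indirect))) {
    if (!net$indirect$mode[i] %in% indirect_modes()) {
      add("indirect", net$indirect$symbol[i],
          paste0("unknown mode: ", net$indirect$mode[i]))
    }
    dir <- net$indirect$mode_direction[i]
    if (nzchar(dir) && !net$indirect$mode[i] %in% directed_modes()) {
      add("indirect", net$indirect$symbol[i],
          "direction attached to a mode that does not carry one")
    }
    if (nzchar(dir) && !dir %in% c("increased", "decreased")) {
      add("indirect", net$indirect$symbol[i],
          paste0("invalid mode direction: ", dir))
    }
  }
  if (length(v) == 0L) {
    return(tibble::tibble(component = character(), symbol = character(),
                          message = character()))
  }
  dplyr::bind_rows(v)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> bait %s: %d direct partner(s), %d binding annotation(s), %d indirect target(s)\n",
    x$bait, nrow(x$nodes), nrow(x$bindings),
    length(unique(x$indirect$symbol))))
  invisible(x)
}

#' Tidy the direct-interaction nodes of a network
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return A tibble with one row per partner: `partner`, `subnetworks`
#'   (semicolon-joined), `primary_subnetwork`, `direction`,
#'   `interaction_label`, `complex_id`, `n_evidence`.
#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) {
  tibble::tibble(
    partner = x$nodes$partner,
    subnetworks = join_multi(x$nodes$subnetworks),
    primary_subnetwork = x$nodes$primary_subnetwork,
    direction = x$nodes$direction,
    interaction_label = x$nodes$interaction_label,
    complex_id = x$nodes$complex_id,
    n_evidence = vapply(x$nodes$evidence, nrow, integer(1))
  )
}

#' One-row structural summary of a network
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return A one-row tibble: partner count, per-subnetwork sizes, number of
#'   binding-annotated partners, distinct indirect-target count.
#' @method glance ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  subs <- subnetwork_levels()
  counts <- vapply(subs, function(s) {
    sum(vapply(x$nodes$subnetworks, function(v) s %in% v, logical(1)))
  }, integer(1))
  out <- tibble::tibble(
    bait = x$bait,
    n_partners = nrow(x$nodes),
    n_binding_annotated = length(unique(x$bindings$partner)),
    n_indirect_targets = length(unique(x$indirect$symbol))
  )
  dplyr::bind_cols(out, tibble::as_tibble(as.list(setNames(
    counts, paste0("n_", tolower(subs))))))
}

#' Export subnetwork gene sets
#'
#' One gene set per populated subnetwork plus one for the full network;
#' symbols are deduplicated within a set, and a partner in k subnetworks
#' appears in k subnetwork sets and once in the full set.
#'
#' @param net A `ppi_network`.
#' @return Named list of character vectors (set name -> symbols).
#' @export
export_sets <- function(net) {
  sets <- list()
  for (s in subnetwork_levels()) {
    members <- net$nodes$partner[
      vapply(net$nodes$subnetworks, function(v) s %in% v, logical(1))]
    if (length(members) > 0L) sets[[s]] <- unique(members)
  }
  sets[["FULL_NETWORK"]] <- unique(net$nodes$partner)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors, e.g. from [export_sets()].
#' @param path Output path.
#' @param description Description field for each line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "litminer") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the network as SIF (simple interaction format)
#'
#' Exactly one row per (bait, interaction label, partner).
#'
#' @param net A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  lines <- sprintf("%s\t%s\t%s", net$bait,
                   gsub("\\s+", "_", net$nodes$interaction_label),
                   net$nodes$partner)
  writeLines(unique(lines), path)
  invisible(path)
}

#' Summarise binding-domain annotations
#'
#' For every bait domain (in N-to-C order), the set of partners annotated
#' to it. The number of partners with at least one annotated binding site
#' is attached as the `n_annotated` attribute.
#'
#' @param net A `ppi_network`.
#' @return A tibble `domain`, `n_partners`, `partners` (semicolon-joined,
#'   sorted), with attribute `n_annotated`.
#' @export
summarize_bindings <- function(net) {
  doms <- net$domain_map$domain
  per <- lapply(doms, function(d) {
    sort(unique(net$bindings$partner[
      vapply(net$bindings$domains, function(v) d %in% v, logical(1))]))
  })
  out <- tibble::tibble(
    domain = doms,
    n_partners = lengths(per),
    partners = vapply(per, paste, character(1), collapse = ";")
  )
  attr(out, "n_annotated") <- length(unique(net$bindings$partner))
  out
}

#' Summarise the indirect (inhibition-response) catalog
#'
#' Counts (target, mode, direction) links as a mode-by-direction matrix.
#' A target reported under two modes contributes two links but one target.
#' Totals are invariant under input row order.
#'
#' @param net A `ppi_network`.
#' @return A tibble with one row per mode: `mode`, `increased`,
#'   `decreased`, `unspecified`, `total_links`; attribute `n_targets` holds
#'   the distinct-target count.
#' @export
summarize_indirect <- function(net) {
  ind <- net$indirect
  modes <- indirect_modes()
  count_cell <- function(m, d) {
    sum(ind$mode == m &
          (if (d == "unspecified") !nzchar(ind$mode_direction)
           else ind$mode_direction == d))
  }
  out <- tibble::tibble(
    mode = modes,
    increased = vapply(modes, count_cell, integer(1), d = "increased", USE.NAMES = FALSE),
    decreased = vapply(modes, count_cell, integer(1), d = "decreased", USE.NAMES = FALSE),
    unspecified = vapply(modes, count_cell, integer(1), d = "unspecified", USE.NAMES = FALSE)
  )
  out$total_links <- out$increased + out$decreased + out$unspecified
  attr(out, "n_targets") <- length(unique(ind$symbol))
  out
}
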