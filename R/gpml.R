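# GPML (2013a) pathway I/O. One DataNode per partner around a central bait
# hub, complexes as Group elements, typed directed edges, and the full
# evidence/annotation content model carried in node comments and dynamic
# Attribute properties so that read(write(net)) is the identity on the
# network content model (PathVisio-compatible storage).

gpml_ns <- "http://pathvisio.org/GPML/2013a"

json_pack <- function(x) {
  as.character(jsonlite::toJSON(x, dataframe = "rows", auto_unbox = FALSE,
                                digits = NA, null = "null", na = "null"))
}

json_unpack_df <- function(txt, template) {
  out <- jsonlite::fromJSON(txt, simplifyDataFrame = TRUE)
  if (is.null(out) || length(out) == 0L || NROW(out) == 0L) return(template)
  out <- tibble::as_tibble(out)
  out[names(template)]
}

#' Write a network to a GPML pathway file
#'
#' Serialises the network as a GPML 2013a pathway: the bait as a central
#' hub DataNode, one DataNode per partner (HGNC label and Xref), complex
#' members grouped into `Group` elements of style Complex, and one typed
#' edge per partner whose arrowheads reflect the interaction direction.
#' Evidence sentences, subnetwork assignments, binding-domain annotations,
#' the indirect-target catalog and the domain map are stored in node
#' comments and dynamic properties, so the file round-trips losslessly
#' through [read_gpml()].
#'
#' @param net A validated `ppi_network`.
#' @param path Output path.
#' @param name Pathway title.
#' @return `path`, invisibly.
#' @export
write_gpml <- function(net, path, name = paste(net$bait, "interaction network")) {
  doc <- xml2::xml_new_root("Pathway", xmlns = gpml_ns,
                            Name = name, Version = "litminer",
                            Organism = "Homo sapiens")
  add_comment <- function(parent, source, text) {
    node <- xml2::xml_add_child(parent, "Comment", Source = source)
    xml2::xml_set_text(node, text)
  }
  add_comment(doc, "litminer:bait", net$bait)
  add_comment(doc, "litminer:provenance", json_pack(net$provenance))
  add_comment(doc, "litminer:domain_map", json_pack(as.data.frame(net$domain_map)))
  ind <- net$indirect
  ind_ser <- lapply(seq_len(nrow(ind)), function(i) {
    list(symbol = ind$symbol[i], mode = ind$mode[i],
         mode_direction = ind$mode_direction[i],
         evidence = as.data.frame(ind$evidence[[i]]))
  })
  add_comment(doc, "litminer:indirect",
              as.character(jsonlite::toJSON(ind_ser, dataframe = "rows",
                                            auto_unbox = TRUE, null = "null")))
  bd <- net$bindings
  bd_ser <- lapply(seq_len(nrow(bd)), function(i) {
    list(partner = bd$partner[i], domains = as.list(bd$domains[[i]]),
         reference = bd$reference[i])
  })
  add_comment(doc, "litminer:bindings",
              as.character(jsonlite::toJSON(bd_ser, auto_unbox = TRUE,
                                            null = "null")))

  xml2::xml_add_child(doc, "Graphics", BoardWidth = "1400.0",
                      BoardHeight = "1400.0")

  fmt <- function(x) sprintf("%.1f", x)
  hub <- xml2::xml_add_child(doc, "DataNode", TextLabel = net$bait,
                             GraphId = "bait", Type = "GeneProduct")
  xml2::xml_add_child(hub, "Graphics", CenterX = fmt(700), CenterY = fmt(700),
                      Width = "90.0", Height = "25.0", ZOrder = "32768",
                      FontSize = "10", Valign = "Middle")
  xml2::xml_add_child(hub, "Xref", Database = "HGNC", ID = net$bait)

  nd <- net$nodes
  n <- nrow(nd)
  for (i in seq_len(n)) {
    theta <- 2 * pi * (i - 1) / max(n, 1L)
    node <- xml2::xml_add_child(doc, "DataNode", TextLabel = nd$partner[i],
                                GraphId = paste0("n", i), Type = "GeneProduct")
    if (!is.na(nd$complex_id[i]) && nzchar(nd$complex_id[i])) {
      xml2::xml_set_attr(node, "GroupRef", nd$complex_id[i])
    }
    add_comment(node, "litminer:evidence",
                json_pack(as.data.frame(nd$evidence[[i]])))
    add_attr_prop <- function(key, value) {
      xml2::xml_add_child(node, "Attribute", Key = key, Value = value)
    }
    add_attr_prop("litminer:subnetworks", join_multi(nd$subnetworks[i]))
    add_attr_prop("litminer:primary_subnetwork", nd$primary_subnetwork[i])
    add_attr_prop("litminer:direction", nd$direction[i])
    add_attr_prop("litminer:interaction_label", nd$interaction_label[i])
    xml2::xml_add_child(node, "Graphics",
                        CenterX = fmt(700 + 550 * cos(theta)),
                        CenterY = fmt(700 + 550 * sin(theta)),
                        Width = "90.0", Height = "25.0", ZOrder = "32768",
                        FontSize = "10", Valign = "Middle")
    xml2::xml_add_child(node, "Xref", Database = "HGNC", ID = nd$partner[i])
  }

  for (i in seq_len(n)) {
    edge <- xml2::xml_add_child(doc, "Interaction")
    gfx <- xml2::xml_add_child(edge, "Graphics", ZOrder = "12288",
                               LineThickness = "1.0")
    dir <- nd$direction[i]
    from <- if (dir == "partner_to_bait") paste0("n", i) else "bait"
    to <- if (dir == "partner_to_bait") "bait" else paste0("n", i)
    p1 <- xml2::xml_add_child(gfx, "Point", GraphRef = from, RelX = "0.0",
                              RelY = "0.0", X = "0.0", Y = "0.0")
    p2 <- xml2::xml_add_child(gfx, "Point", GraphRef = to, RelX = "0.0",
                              RelY = "0.0", X = "0.0", Y = "0.0")
    if (dir %in% c("bait_to_partner", "partner_to_bait")) {
      xml2::xml_set_attr(p2, "ArrowHead", "Arrow")
    } else if (dir == "bidirectional") {
      xml2::xml_set_attr(p1, "ArrowHead", "Arrow")
      xml2::xml_set_attr(p2, "ArrowHead", "Arrow")
    }
    xml2::xml_add_child(edge, "Xref", Database = "", ID = "")
  }

  complexes <- unique(nd$complex_id[!is.na(nd$complex_id) & nzchar(nd$complex_id)])
  for (cx in complexes) {
    xml2::xml_add_child(doc, "Group", GroupId = cx, Style = "Complex")
  }
  xml2::xml_add_child(doc, "InfoBox", CenterX = "0.0", CenterY = "0.0")

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a network from a GPML pathway file
#'
#' Reads a GPML 2013a pathway. Files written by [write_gpml()] reconstruct
#' the full network content model; pathways from other tools yield the
#' partner nodes (one per non-bait DataNode with a gene-product label) with
#' whatever typed annotation is present.
#'
#' @param path Path to a `.gpml` file.
#' @param bait Bait symbol, used to identify the hub node when the file
#'   does not record one.
#' @return A `ppi_network`.
#' @export
read_gpml <- function(path, bait = NULL) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("GPML parse error in '", path, "': ",
                                     conditionMessage(e))))
  root_ns <- xml2::xml_ns(doc)
  if (!gpml_ns %in% unlist(root_ns) || xml2::xml_name(doc) != "Pathway") {
    abort(sprintf("Not a GPML 2013a pathway document: '%s'.", path))
  }
  xml2::xml_ns_strip(doc)

  comment_of <- function(node, source) {
    hit <- xml2::xml_find_first(
      node, sprintf(".//Comment[@Source='%s']", source))
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  pathway_comment <- function(source) {
    hit <- xml2::xml_find_first(doc, sprintf("./Comment[@Source='%s']", source))
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }

  if (is.null(bait)) bait <- pathway_comment("litminer:bait")
  datanodes <- xml2::xml_find_all(doc, "./DataNode")
  labels <- xml2::xml_attr(datanodes, "TextLabel")
  if (is.na(bait)) {
    # fall back: a node whose GraphId is 'bait', else nothing matches
    gid <- xml2::xml_attr(datanodes, "GraphId")
    bait <- if (any(gid == "bait", na.rm = TRUE)) labels[which(gid == "bait")[1]]
    else NA_character_
  }

  rows <- list()
  for (node in datanodes) {
    label <- xml2::xml_attr(node, "TextLabel")
    if (identical(label, bait)) next
    attrs <- xml2::xml_find_all(node, "./Attribute")
    avals <- setNames(xml2::xml_attr(attrs, "Value"), xml2::xml_attr(attrs, "Key"))
    amap <- function(key) if (key %in% names(avals)) avals[[key]] else NULL
    ev_txt <- comment_of(node, "litminer:evidence")
    evidence <- if (is.na(ev_txt)) empty_evidence() else
      json_unpack_df(ev_txt, empty_evidence())
    subs <- amap("litminer:subnetworks") %||% NA_character_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      partner = label,
      subnetworks = if (is.na(subs)) list(character()) else split_multi(subs),
      primary_subnetwork = amap("litminer:primary_subnetwork") %||% NA_character_,
      direction = amap("litminer:direction") %||% "undirected",
      interaction_label = amap("litminer:interaction_label") %||% NA_character_,
      complex_id = xml2::xml_attr(node, "GroupRef"),
      evidence = list(tibble::as_tibble(evidence))
    )
  }
  nodes <- if (length(rows) == 0L) {
    tibble::tibble(partner = character(), subnetworks = list(),
                   primary_subnetwork = character(), direction = character(),
                   interaction_label = character(), complex_id = character(),
                   evidence = list())
  } else {
    dplyr::arrange(dplyr::bind_rows(rows), .data$partner)
  }

  bd_txt <- pathway_comment("litminer:bindings")
  bindings <- tibble::tibble(partner = character(), domains = list(),
                             reference = character())
  if (!is.na(bd_txt)) {
    parsed <- jsonlite::fromJSON(bd_txt, simplifyVector = FALSE)
    if (length(parsed) > 0L) {
      bindings <- dplyr::bind_rows(lapply(parsed, function(b) {
        tibble::tibble(partner = b$partner,
                       domains = list(unlist(b$domains)),
                       reference = b$reference)
      }))
    }
  }

  ind_txt <- pathway_comment("litminer:indirect")
  indirect <- tibble::tibble(symbol = character(), mode = character(),
                             mode_direction = character(), evidence = list())
  if (!is.na(ind_txt)) {
    parsed <- jsonlite::fromJSON(ind_txt, simplifyVector = FALSE)
    if (length(parsed) > 0L) {
      indirect <- dplyr::bind_rows(lapply(parsed, function(r) {
        ev <- dplyr::bind_rows(lapply(r$evidence, tibble::as_tibble))
        if (nrow(ev) == 0L) ev <- empty_evidence()
        tibble::tibble(symbol = r$symbol, mode = r$mode,
                       mode_direction = r$mode_direction %||% "",
                       evidence = list(ev[c("article_id", "sentence")]))
      }))
    }
  }

  dm_txt <- pathway_comment("litminer:domain_map")
  domain_map <- if (is.na(dm_txt)) hdac6_domain_map() else {
    dm <- json_unpack_df(dm_txt, hdac6_domain_map())
    dm$start <- as.integer(dm$start)
    dm$end <- as.integer(dm$end)
    dm
  }

  prov_txt <- pathway_comment("litminer:provenance")
  provenance <- if (is.na(prov_txt)) list() else
    jsonlite::fromJSON(prov_txt, simplifyVector = TRUE)

  new_network(bait = bait, nodes = nodes, bindings = bindings,
              indirect = indirect, domain_map = domain_map,
              provenance = provenance)
}
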