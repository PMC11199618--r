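# End-to-end orchestration: configuration validation, staged execution
# (screen -> mine -> [external curation] -> build -> compare -> enrich),
# per-stage outputs and a reproducible JSON run manifest. The manual
# curation step is an explicit file handoff: the mine stage writes an
# evidence sheet, the build stage requires a curated sheet back.

#' Validate a pipeline run configuration
#'
#' The configuration is a named list (or path to a JSON file) with fields:
#' `bait` (symbol, required), `bait_aliases`, `manifest`, `off_topic`,
#' `hgnc_map`, `curated_sheet`, `reference_a`, `reference_b`, `id_mapping`,
#' `expression`, `de_table`, `alpha` (default 0.05), `alternative`
#' (`greater`/`two_sided`), `regions`, `keep_levels`, `seed`, `out_dir`
#' (required). All supplied paths must exist; enumerated fields are checked
#' against their closed vocabularies.
#'
#' @param config Named list or path to a JSON config file.
#' @return The validated config list, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("`config` must be a named list or a JSON path.")
  if (is.null(config$bait) || !nzchar(config$bait)) {
    abort("Config field `bait` is required.")
  }
  if (is.null(config$out_dir)) abort("Config field `out_dir` is required.")
  config$alpha <- config$alpha %||% 0.05
  stopifnot_scalar_prob(config$alpha, "alpha")
  config$alternative <- config$alternative %||% "greater"
  if (!config$alternative %in% c("greater", "two_sided")) {
    abort("`alternative` must be 'greater' or 'two_sided'.")
  }
  config$regions <- config$regions %||% brain_regions()
  config$keep_levels <- config$keep_levels %||% c("medium", "high")
  bad_lv <- setdiff(tolower(config$keep_levels),
                    c("not_detected", "not detected", "low", "medium", "high"))
  if (length(bad_lv) > 0L) {
    abort(paste0("Unknown expression level(s): ", paste(bad_lv, collapse = ", "), "."))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$bait_aliases <- config$bait_aliases %||% alias_variants(config$bait)
  for (f in c("manifest", "off_topic", "hgnc_map", "curated_sheet",
              "reference_a", "reference_b", "id_mapping", "expression",
              "de_table")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      abort(sprintf("Config path `%s` does not exist: %s", f, config[[f]]))
    }
  }
  config
}

stage_outputs <- function(out_dir) {
  list(
    ledger = file.path(out_dir, "ledger.tsv"),
    evidence = file.path(out_dir, "evidence.tsv"),
    unmapped = file.path(out_dir, "unmapped_names.txt"),
    network_gpml = file.path(out_dir, "network.gpml"),
    network_nodes = file.path(out_dir, "network_nodes.tsv"),
    network_sif = file.path(out_dir, "network.sif"),
    network_gmt = file.path(out_dir, "network_sets.gmt"),
    bindings = file.path(out_dir, "binding_summary.tsv"),
    indirect = file.path(out_dir, "indirect_summary.tsv"),
    overlap = file.path(out_dir, "overlap.tsv"),
    brain_filter = file.path(out_dir, "brain_filter.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    overlay = file.path(out_dir, "overlay.tsv"),
    run_manifest = file.path(out_dir, "run_manifest.json")
  )
}

#' Run the semi-automated mining pipeline
#'
#' Executes the requested stages in order on the inputs named in the
#' configuration, writing each stage's tabular outputs plus a JSON run
#' manifest (package version, parameters, input and output digests) under
#' `out_dir`. Re-running with identical inputs reproduces identical
#' outputs. The curation handoff is explicit: `mine` writes the evidence
#' sheet for the curator, and `build` requires `curated_sheet` in the
#' configuration.
#'
#' @param config Run configuration (see [validate_run_config()]).
#' @param stages Character vector of stages to run, a subset of
#'   `c("screen", "mine", "build", "compare", "enrich")`.
#' @return The run-manifest list, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("screen", "mine", "build", "compare",
                                    "enrich")) {
  cfg <- validate_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stage_outputs(cfg$out_dir)
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- c(log[[stage]], sprintf(...))
  }

  ledger <- NULL
  if ("screen" %in% stages) {
    if (is.null(cfg$manifest)) abort("The screen stage needs `manifest`.")
    manifest <- read_manifest(cfg$manifest)
    off <- if (!is.null(cfg$off_topic)) readLines(cfg$off_topic) else character()
    ledger <- screen_articles(manifest, off_topic_ids = off)
    write_ledger(ledger, paths$ledger)
    g <- glance(ledger)
    note("screen", "retrieved=%d duplicates=%d included=%d",
         g$retrieved, g$duplicates, g$included)
  }

  dict <- NULL
  if ("mine" %in% stages) {
    if (is.null(cfg$hgnc_map)) abort("The mine stage needs `hgnc_map`.")
    if (is.null(ledger)) {
      if (is.null(cfg$manifest)) abort("The mine stage needs `manifest`.")
      ledger <- screen_articles(read_manifest(cfg$manifest))
    }
    hgnc <- readr::read_tsv(cfg$hgnc_map, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
    shortlist <- cfg$shortlist %||% hgnc$alias
    dict <- compile_dictionary(shortlist, hgnc, bait_symbol = cfg$bait,
                               bait_aliases = cfg$bait_aliases)
    writeLines(dict$unmapped, paths$unmapped)
    included <- tibble::as_tibble(ledger)[ledger$status == "included", ]
    com <- lapply(seq_len(nrow(included)), function(i) {
      txt <- if (!is.na(included$fulltext_ref[i]) &&
                 file.exists(included$fulltext_ref[i])) {
        paste(readLines(included$fulltext_ref[i], warn = FALSE), collapse = "\n")
      } else {
        included$abstract[i] %||% ""
      }
      if (is.na(txt) || !nzchar(txt)) return(NULL)
      extract_comentions(txt, included$article_id[i], dict)
    })
    sheet <- export_curation_sheet(dplyr::bind_rows(com))
    write_curation_sheet(sheet, paths$evidence)
    note("mine", "comention_rows=%d unmapped_names=%d",
         nrow(sheet), length(dict$unmapped))
  }

  net <- NULL
  if ("build" %in% stages) {
    if (is.null(cfg$curated_sheet)) {
      abort(paste0(
        "The build stage needs `curated_sheet`: run the mine stage, curate ",
        "the evidence sheet (fill interaction_class/subnetwork/direction), ",
        "and point `curated_sheet` at the result."))
    }
    curated <- read_curation_sheet(cfg$curated_sheet)
    net <- build_network(curated, bait = cfg$bait)
    viol <- validate_network(net)
    if (nrow(viol) > 0L) {
      abort(paste0("Network validation failed: ",
                   paste(viol$message, collapse = "; ")))
    }
    write_gpml(net, paths$network_gpml)
    readr::write_tsv(tidy(net), paths$network_nodes)
    write_sif(net, paths$network_sif)
    write_gmt(export_sets(net), paths$network_gmt)
    readr::write_tsv(summarize_bindings(net), paths$bindings)
    readr::write_tsv(summarize_indirect(net), paths$indirect)
    g <- glance(net)
    note("build", "partners=%d indirect_targets=%d",
         g$n_partners, g$n_indirect_targets)
  }

  if ("compare" %in% stages) {
    if (is.null(net)) {
      if (!file.exists(paths$network_gpml)) {
        abort("The compare stage needs a built network (run build first).")
      }
      net <- read_gpml(paths$network_gpml)
    }
    if (is.null(cfg$reference_a) || is.null(cfg$id_mapping)) {
      abort("The compare stage needs `reference_a` (and optionally `reference_b`) plus `id_mapping`.")
    }
    refA <- read_reference_edges(cfg$reference_a)
    refB <- if (!is.null(cfg$reference_b)) read_reference_edges(cfg$reference_b)
    else refA[0, ]
    mapping <- readr::read_tsv(cfg$id_mapping, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character()))
    merged <- merge_references(refA, refB, mapping)
    report <- compare_network(net, merged, mapping)
    readr::write_tsv(tibble::as_tibble(report), paths$overlap)
    g <- glance(report)
    note("compare", "shared=%d literature_only=%d database_only=%d",
         g$shared, g$literature_only, g$database_only)
    if (!is.null(cfg$expression)) {
      expr <- read_expression_table(cfg$expression)
      db_only <- report$symbol[report$category == "database_only"]
      flt <- filter_brain_expressed(db_only, expr, regions = cfg$regions,
                                    keep_levels = cfg$keep_levels)
      readr::write_tsv(flt, paths$brain_filter)
      note("compare", "brain_expressed=%d of %d db-only",
           sum(flt$status == "retained"), length(db_only))
    }
  }

  if ("enrich" %in% stages) {
    if (is.null(net)) {
      if (!file.exists(paths$network_gpml)) {
        abort("The enrich stage needs a built network (run build first).")
      }
      net <- read_gpml(paths$network_gpml)
    }
    if (is.null(cfg$de_table)) abort("The enrich stage needs `de_table`.")
    de <- readr::read_tsv(cfg$de_table, show_col_types = FALSE)
    if ("probe" %in% names(de)) de <- collapse_probes(de)
    res <- subnetwork_enrichment(net, de, alpha = cfg$alpha,
                                 alternative = cfg$alternative)
    readr::write_tsv(tibble::as_tibble(res), paths$enrichment)
    readr::write_tsv(network_overlay(net, de, alpha = cfg$alpha),
                     paths$overlay)
    g <- glance(res)
    note("enrich", "deg_in_network=%d p_full=%.3g top=%s",
         g$deg_in_network, g$p_full_network, g$top_subnetwork)
  }

  digest_of <- function(p) unname(tools::md5sum(p))
  inputs <- Filter(function(p) is.character(p) && length(p) == 1L && file.exists(p),
                   cfg[c("manifest", "off_topic", "hgnc_map", "curated_sheet",
                         "reference_a", "reference_b", "id_mapping",
                         "expression", "de_table")])
  outputs <- Filter(file.exists, paths[setdiff(names(paths), "run_manifest")])
  manifest <- list(
    package = "litminer",
    version = as.character(utils::packageVersion("litminer")),
    stages = stages,
    parameters = list(bait = cfg$bait, alpha = cfg$alpha,
                      alternative = cfg$alternative, seed = cfg$seed,
                      regions = cfg$regions, keep_levels = cfg$keep_levels),
    inputs = lapply(inputs, digest_of),
    outputs = lapply(outputs, digest_of),
    log = log
  )
  jsonlite::write_json(manifest, paths$run_manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
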