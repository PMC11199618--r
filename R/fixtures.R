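# Seeded generators for every input the pipeline consumes, with ground
# truth attached, so every stage is testable offline. Each generator is a
# pure function of its arguments including the seed.

with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The packaged miniature bait network curation sheet
#'
#' A small, frozen curated sheet for a 12-partner HDAC6 network spanning
#' all five subnetworks, with three protein complexes, six binding-domain
#' annotations and eight indirect targets. It is the canonical test object
#' of the package; the partner symbols (CTTN, MAPT, HSP90AA1, SQSTM1, PRKN,
#' GSK3B, MAPK1, TUBA4A, VCP, STUB1, MIIP, XRCC6) are well-described HDAC6
#' interactors so documentation examples read naturally. The evidence
#' sentences are synthetic stand-ins, not quotations.
#'
#' @return A curation-sheet tibble ready for [build_network()].
#' @export
mini_curated_sheet <- function() {
  direct <- function(partner, doc, sentence, subnetwork, direction = "",
                     complex_id = "", binding = "") {
    tibble::tibble(
      partner = partner, doc_id = doc, sentence = sentence,
      interaction_class = "direct", subnetwork = subnetwork,
      direction = direction, mode_of_action = "", mode_direction = "",
      complex_id = complex_id, binding_domains = binding, notes = ""
    )
  }
  indirect <- function(partner, doc, sentence, modes, dir = "") {
    tibble::tibble(
      partner = partner, doc_id = doc, sentence = sentence,
      interaction_class = "indirect", subnetwork = "", direction = "",
      mode_of_action = modes, mode_direction = dir, complex_id = "",
      binding_domains = "", notes = ""
    )
  }
  dplyr::bind_rows(
    direct("CTTN", "PMID0001",
           "HDAC6 deacetylates cortactin to promote autophagosome-lysosome fusion.",
           "DEACETYLATION", "bait_to_partner", binding = "DD1;DD2"),
    direct("TUBA4A", "PMID0002",
           "HDAC6 removes acetyl groups from alpha-tubulin in cortical neurons.",
           "DEACETYLATION", "bait_to_partner"),
    direct("XRCC6", "PMID0003",
           "HDAC6 deacetylates XRCC6 and modulates BAX-dependent apoptosis.",
           "DEACETYLATION", "bait_to_partner"),
    direct("MAPT", "PMID0004",
           "HDAC6 binds tau via its second catalytic domain and the SE14 repeat.",
           "DEACETYLATION;AGGRESOME_AUTOPHAGY", "bait_to_partner",
           binding = "DD2;SE14"),
    direct("MAPT", "PMID0005",
           "Loss of HDAC6 activity alters tau aggresome processing.",
           "AGGRESOME_AUTOPHAGY", "bait_to_partner"),
    direct("HSP90AA1", "PMID0006",
           "HDAC6 deacetylates HSP90 and associates with the HSP90-HSF1 complex.",
           "DEACETYLATION;PROTEIN_COMPLEX", "bait_to_partner",
           complex_id = "HSP90_HSF1", binding = "DD1;DD2;ZNF_UBP"),
    direct("PRKN", "PMID0007",
           "HDAC6 forms a tight complex with Parkin under proteasome inhibition.",
           "PROTEIN_COMPLEX;AGGRESOME_AUTOPHAGY", "undirected",
           complex_id = "HDAC6_PRKN"),
    direct("VCP", "PMID0008",
           "The HDAC6-VCP complex controls the fate of polyubiquitinated proteins.",
           "PROTEIN_COMPLEX;AGGRESOME_AUTOPHAGY", "undirected",
           complex_id = "HDAC6_VCP"),
    direct("GSK3B", "PMID0009",
           "GSK3B phosphorylates HDAC6 to regulate mitochondrial transport.",
           "PHOSPHORYLATION", "partner_to_bait"),
    direct("MAPK1", "PMID0010",
           "MAPK1 phosphorylates HDAC6 and increases its deacetylase activity.",
           "PHOSPHORYLATION", "partner_to_bait"),
    direct("STUB1", "PMID0011",
           "STUB1 binds the second catalytic domain and ubiquitinates HDAC6.",
           "REGULATORY", "partner_to_bait", binding = "DD2"),
    direct("MIIP", "PMID0012",
           "MIIP binds both deacetylase domains of HDAC6 and inhibits its activity.",
           "REGULATORY", "partner_to_bait", binding = "DD1;DD2"),
    direct("SQSTM1", "PMID0013",
           "SQSTM1 binds HDAC6 at DD2 and restrains its deacetylase activity.",
           "REGULATORY;AGGRESOME_AUTOPHAGY", "partner_to_bait",
           binding = "DD2"),
    indirect("BDNF", "PMID0014",
             "HDAC6 inhibition increased BDNF mRNA levels in hippocampal neurons.",
             "expression_mRNA_protein", "increased"),
    indirect("TNF", "PMID0015",
             "Treatment with an HDAC6 inhibitor reduced TNF expression in microglia.",
             "expression_mRNA_protein", "decreased"),
    indirect("AKT1", "PMID0016",
             "HDAC6 knockdown decreased AKT1 phosphorylation in astrocytes.",
             "phosphorylation", "decreased"),
    indirect("TUBB3", "PMID0017",
             "HDAC6 inhibition elevated TUBB3 acetylation in dorsal root ganglia.",
             "acetylation"),
    indirect("CASP3", "PMID0018",
             "Pharmacological HDAC6 inhibition lowered CASP3 activity after injury.",
             "activity"),
    indirect("HTT", "PMID0019",
             "HDAC6 silencing slowed the degradation of mutant HTT aggregates.",
             "degradation"),
    indirect("TFEB", "PMID0020",
             "HDAC6 inhibition shifted TFEB localization toward the nucleus.",
             "transport_localization"),
    indirect("FOS", "PMID0021",
             "HDAC6 inhibition changed FOS promoter activity in treated cultures.",
             "other")
  )
}

#' Build the packaged miniature bait network
#'
#' @return A `ppi_network` built from [mini_curated_sheet()].
#' @export
mini_hdac6_network <- function() {
  build_network(mini_curated_sheet(), bait = "HDAC6")
}

#' Generate a synthetic bait network of controlled size
#'
#' Creates a network with `n_per_subnetwork` partners in each of the five
#' subnetworks (disjoint membership, synthetic symbols), useful for sized
#' simulation studies.
#'
#' @param n_per_subnetwork Partners per subnetwork.
#' @param bait Bait symbol.
#' @return A `ppi_network`.
#' @export
synthetic_network <- function(n_per_subnetwork = 20, bait = "HDAC6") {
  subs <- subnetwork_levels()
  rows <- lapply(seq_along(subs), function(k) {
    partners <- sprintf("%s%03d", substr(subs[k], 1, 3), seq_len(n_per_subnetwork))
    tibble::tibble(
      partner = partners,
      doc_id = sprintf("PMIDS%02d%03d", k, seq_len(n_per_subnetwork)),
      sentence = sprintf("%s interacts with %s in neurons.", bait, partners),
      interaction_class = "direct",
      subnetwork = subs[k],
      direction = "",
      mode_of_action = "", mode_direction = "",
      complex_id = ifelse(subs[k] == "PROTEIN_COMPLEX",
                          sprintf("CPLX%03d", seq_len(n_per_subnetwork)), ""),
      binding_domains = "", notes = ""
    )
  })
  build_network(dplyr::bind_rows(rows), bait = bait)
}

distractor_templates <- function() {
  c("The experiments were repeated three times with consistent results.",
    "Samples were incubated overnight at four degrees before imaging.",
    "Statistical significance was assessed with a mixed linear model.",
    "Mice were housed under a standard twelve-hour light cycle.",
    "Sections were counterstained and mounted for confocal microscopy.",
    "All reagents were obtained from commercial suppliers.",
    "The cultures reached confluence after five days in vitro.",
    "Lysates were cleared by centrifugation prior to immunoblotting.")
}

planted_templates <- function() {
  c("In cultured neurons, %s directly binds %s under stress conditions.",
    "Co-immunoprecipitation showed that %s interacts with %s in brain lysates.",
    "We found that %s associates with %s in the cerebellum.",
    "Knockdown experiments confirmed that %s regulates %s in glia.")
}

#' Generate a synthetic article corpus with planted co-mentions
#'
#' Each document contains `planted_pairs_per_doc` sentences that name the
#' bait and one dictionary partner using exact dictionary aliases, shuffled
#' among distractor sentences that contain no dictionary alias. The planted
#' (doc, partner) pairs are recorded as ground truth. A matching annotation
#' payload (gene/protein annotations for the planted names plus
#' non-gene annotations that the filter must drop) is generated per
#' document. Regenerating with the same arguments is byte-identical.
#'
#' @param dict An `entity_dictionary`.
#' @param n_docs Number of documents.
#' @param planted_pairs_per_doc Planted bait-partner sentences per document.
#' @param distractor_sentences Distractor sentences per document.
#' @param seed Integer seed.
#' @param planted_partners Optional character vector restricting the
#'   partner pool; every element must be in the dictionary.
#' @return A list: `corpus` (tibble `doc_id`, `text`), `manifest` (tibble in
#'   the article-manifest dialect), `truth_pairs` (tibble `doc_id`,
#'   `partner`), `annotations` (list of per-document payload lists).
#' @export
gen_corpus <- function(dict, n_docs = 5, planted_pairs_per_doc = 2,
                       distractor_sentences = 5, seed = 1,
                       planted_partners = NULL) {
  stopifnot(inherits(dict, "entity_dictionary"))
  pool <- setdiff(unique(dict$entries$symbol), dict$bait_symbol)
  if (!is.null(planted_partners)) {
    missing <- setdiff(planted_partners, dict$entries$symbol)
    if (length(missing) > 0L) {
      abort(paste0("Planted partner(s) absent from dictionary: ",
                   paste(missing, collapse = ", "), "."))
    }
    pool <- planted_partners
  }
  if (length(pool) == 0L && planted_pairs_per_doc > 0L) {
    abort("The dictionary contains no non-bait partner to plant.")
  }
  with_seed_(seed, {
    docs <- vector("list", n_docs)
    truth <- list()
    payloads <- vector("list", n_docs)
    for (d in seq_len(n_docs)) {
      doc_id <- sprintf("PMCSYN%04d", d)
      partners <- if (planted_pairs_per_doc > 0L) {
        sample(pool, planted_pairs_per_doc,
               replace = planted_pairs_per_doc > length(pool))
      } else character()
      partners <- unique(partners)
      planted <- vapply(partners, function(p) {
        sprintf(sample(planted_templates(), 1), dict$bait_symbol, p)
      }, character(1))
      distract <- sample(distractor_templates(), distractor_sentences,
                         replace = distractor_sentences > length(distractor_templates()))
      sentences <- sample(c(planted, distract))
      docs[[d]] <- tibble::tibble(doc_id = doc_id,
                                  text = paste(sentences, collapse = " "))
      if (length(partners) > 0L) {
        truth[[length(truth) + 1L]] <- tibble::tibble(doc_id = doc_id,
                                                      partner = partners)
      }
      anns <- c(
        lapply(c(dict$bait_symbol, partners), function(sym) {
          list(exact = sym, type = "Gene_Proteins", section = "Results",
               prefix = "the ", postfix = " protein",
               tags = list(list(name = sym,
                                uri = paste0("https://purl.uniprot.org/uniprot/SYN",
                                             sym))))
        }),
        list(list(exact = "Mus musculus", type = "Organisms",
                  section = "Methods", prefix = "", postfix = "",
                  tags = list(list(name = "Mus musculus",
                                   uri = "http://purl.obolibrary.org/obo/NCBITaxon_10090"))))
      )
      payloads[[d]] <- list(pmcid = doc_id, annotations = anns)
    }
    corpus <- dplyr::bind_rows(docs)
    manifest <- tibble::tibble(
      article_id = corpus$doc_id,
      pmid = sub("PMCSYN", "3", corpus$doc_id),
      pmcid = corpus$doc_id,
      title = sprintf("Synthetic article %s", corpus$doc_id),
      language = "en",
      open_access = TRUE,
      fulltext_ref = NA_character_,
      abstract = corpus$text
    )
    list(
      corpus = corpus,
      manifest = manifest,
      truth_pairs = if (length(truth) > 0L) dplyr::bind_rows(truth)
      else tibble::tibble(doc_id = character(), partner = character()),
      annotations = payloads
    )
  })
}

#' Generate reference edge sets with controlled overlap
#'
#' Builds two reference edge collections (sources "biogrid" and "intact")
#' and a matching identifier-mapping table such that comparing them against
#' a network with the given symbols reproduces, exactly, an overlap report
#' with `n_shared` shared, `length(network_symbols) - n_shared`
#' literature-only and `n_db_only` database-only partners. Some edges carry
#' UniProt identifiers (resolved through the mapping), others Entrez ids.
#'
#' @param network_symbols Symbols of the literature network partners.
#' @param n_shared Number of network partners also present in the
#'   references (`<= length(network_symbols)`).
#' @param n_db_only Number of reference-only partners.
#' @param seed Integer seed.
#' @param bait Bait symbol (used for the edge bait column).
#' @return A list: `setA`, `setB` (reference edge tibbles), `mapping`
#'   (identifier map), `expected` (one-row tibble of expected counts).
#' @export
gen_reference_sets <- function(network_symbols, n_shared, n_db_only,
                               seed = 1, bait = "HDAC6") {
  network_symbols <- unique(network_symbols)
  if (n_shared > length(network_symbols)) {
    abort("`n_shared` cannot exceed the number of network symbols.")
  }
  if (n_shared < 0 || n_db_only < 0) abort("Counts must be non-negative.")
  with_seed_(seed, {
    shared <- if (n_shared > 0) sample(network_symbols, n_shared) else character()
    db_only <- if (n_db_only > 0) sprintf("DBONLY%04d", seq_len(n_db_only))
    else character()
    all_ref <- c(shared, db_only)
    mapping <- tibble::tibble(
      symbol = c(network_symbols, db_only, bait),
      entrez = as.character(seq_len(length(network_symbols) + n_db_only + 1L) + 1000L),
      uniprot = sprintf("P%05d", seq_len(length(network_symbols) + n_db_only + 1L))
    )
    # redundant UniProt rows exercise the lowest-Entrez tie-break downstream
    entrez_of <- function(s) mapping$entrez[match(s, mapping$symbol)]
    uniprot_of <- function(s) mapping$uniprot[match(s, mapping$symbol)]

    n_ref <- length(all_ref)
    src <- if (n_ref > 0) sample(c("A", "B", "both"), n_ref, replace = TRUE)
    else character()
    # guarantee both sets are exercised when possible
    if (n_ref >= 2) { src[1] <- "A"; src[2] <- "B" }
    make_edges <- function(symbols, source_db) {
      if (length(symbols) == 0L) {
        return(tibble::tibble(bait_id = character(), partner_id = character(),
                              namespace = character(), source_db = character()))
      }
      use_uniprot <- seq_along(symbols) %% 2L == 0L
      tibble::tibble(
        bait_id = entrez_of(bait),
        partner_id = ifelse(use_uniprot, uniprot_of(symbols), entrez_of(symbols)),
        namespace = ifelse(use_uniprot, "uniprot", "entrez"),
        source_db = source_db
      )
    }
    setA <- make_edges(all_ref[src %in% c("A", "both")], "biogrid")
    setB <- make_edges(all_ref[src %in% c("B", "both")], "intact")
    list(
      setA = setA, setB = setB, mapping = mapping,
      expected = tibble::tibble(
        shared = n_shared,
        literature_only = length(network_symbols) - n_shared,
        database_only = n_db_only
      )
    )
  })
}

#' Generate a normal-tissue expression table with a known retention plan
#'
#' For each candidate gene, plants one of four profiles: reliably expressed
#' at medium/high in at least one selected brain region (retained), low or
#' not detected in brain (not retained), high in brain but only with
#' uncertain reliability (not retained — the reliability exclusion must
#' act before the level test), or expressed only outside the selected
#' regions (not retained).
#'
#' @param genes Candidate gene identifiers.
#' @param n_expressed How many genes to plant as brain-expressed.
#' @param seed Integer seed.
#' @param regions Brain regions to draw from.
#' @return A list: `expr` (expression tibble), `truth_expressed`
#'   (character vector of genes planted as retained).
#' @export
gen_expression_table <- function(genes, n_expressed, seed = 1,
                                 regions = brain_regions()) {
  genes <- unique(genes)
  if (n_expressed > length(genes)) {
    abort("`n_expressed` cannot exceed the number of candidate genes.")
  }
  with_seed_(seed, {
    expressed <- if (n_expressed > 0) sample(genes, n_expressed) else character()
    rest <- setdiff(genes, expressed)
    profile <- if (length(rest) > 0) {
      sample(c("low", "uncertain_high", "elsewhere"), length(rest), replace = TRUE)
    } else character()
    rows <- list()
    add <- function(g, tissue, level, reliability) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        gene = g, gene_name = g, tissue = tissue, level = level,
        reliability = reliability)
    }
    for (g in expressed) {
      add(g, sample(regions, 1), sample(c("medium", "high"), 1),
          sample(c("enhanced", "supported", "approved"), 1))
      add(g, "liver", "not detected", "approved")
    }
    for (i in seq_along(rest)) {
      g <- rest[i]
      switch(profile[i],
             low = add(g, sample(regions, 1),
                       sample(c("low", "not detected"), 1), "approved"),
             uncertain_high = add(g, sample(regions, 1), "high", "uncertain"),
             elsewhere = add(g, "liver", "high", "approved"))
    }
    list(expr = dplyr::bind_rows(rows), truth_expressed = expressed)
  })
}

#' Generate a differential-expression experiment with a planted enrichment
#'
#' Builds a gene-level statistics table over a background of
#' `background_size` genes containing every network partner. DEG membership
#' is drawn per gene as independent Bernoulli trials whose success
#' probabilities are solved so that the planted subnetwork's expected 2x2
#' odds ratio against the rest of the background equals
#' `planted_odds_ratio` while the expected total DEG count equals `n_deg`.
#' DEG p values are uniform on (0, alpha), non-DEG p values uniform on
#' (alpha, 1); the realised 2x2 table is recorded as ground truth.
#'
#' @param net A `ppi_network` whose partner symbols are embedded in the
#'   background.
#' @param background_size Total background gene count.
#' @param n_deg Expected number of DEGs (may be 0: no gene passes alpha).
#' @param planted_subnetwork One of [subnetwork_levels()].
#' @param planted_odds_ratio Target expected odds ratio (> 0).
#' @param seed Integer seed.
#' @param alpha DEG cutoff used for the p-value split.
#' @return A list: `stats` (tibble `gene`, `log2fc`, `p`), `background`
#'   (character vector), `truth` (list with the planted set, realised 2x2
#'   counts `a`,`b`,`c`,`d`, realised odds ratio and DEG genes).
#' @export
gen_de_experiment <- function(net, background_size = 5000, n_deg = 500,
                              planted_subnetwork = "PHOSPHORYLATION",
                              planted_odds_ratio = 4, seed = 1,
                              alpha = 0.05) {
  if (!planted_subnetwork %in% subnetwork_levels()) {
    abort("`planted_subnetwork` must be one of the five subnetwork categories.")
  }
  if (planted_odds_ratio <= 0 || !is.finite(planted_odds_ratio)) {
    abort("`planted_odds_ratio` must be a positive finite number.")
  }
  net_symbols <- unique(net$nodes$partner)
  if (background_size < length(net_symbols)) {
    abort("`background_size` must cover every network partner.")
  }
  if (n_deg < 0 || n_deg > background_size) {
    abort("`n_deg` must lie between 0 and `background_size`.")
  }
  sets <- export_sets(net)
  planted <- sets[[planted_subnetwork]] %||% character()
  if (length(planted) == 0L) {
    abort("The planted subnetwork has no members in this network.")
  }

  filler <- sprintf("BG%05d", seq_len(background_size - length(net_symbols)))
  background <- c(net_symbols, filler)
  m <- length(planted)
  N <- background_size
  OR <- planted_odds_ratio

  if (n_deg == 0) {
    p0 <- 0; p1 <- 0
  } else {
    p1_of <- function(p0) OR * p0 / (1 - p0 + OR * p0)
    f <- function(p0) m * p1_of(p0) + (N - m) * p0 - n_deg
    if (f(1 - 1e-12) < 0) abort("Infeasible DEG count for the given sizes.")
    p0 <- uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    p1 <- p1_of(p0)
  }

  with_seed_(seed, {
    in_set <- background %in% planted
    prob <- ifelse(in_set, p1, p0)
    is_deg <- runif(N) < prob
    p <- numeric(N)
    p[is_deg] <- runif(sum(is_deg), 0, alpha)
    p[!is_deg] <- runif(sum(!is_deg), alpha, 1)
    # keep strictly inside the half-open intervals so the cutoff is unambiguous
    p[is_deg] <- pmin(p[is_deg], alpha * (1 - 1e-12))
    log2fc <- rnorm(N, mean = 0, sd = 1) + ifelse(is_deg, sign(rnorm(N)) * 1, 0)
    stats <- tibble::tibble(gene = background, log2fc = log2fc, p = p)
    a <- sum(is_deg & in_set)
    b <- sum(!is_deg & in_set)
    c_ <- sum(is_deg & !in_set)
    d <- sum(!is_deg & !in_set)
    list(
      stats = stats,
      background = background,
      truth = list(
        planted_subnetwork = planted_subnetwork,
        planted_set = planted,
        planted_odds_ratio = OR,
        a = a, b = b, c = c_, d = d,
        realized_odds_ratio = odds_ratio_2x2(a, b, c_, d),
        deg_genes = background[is_deg]
      )
    )
  })
}
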