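test_that("identifier mapping picks the lowest Entrez id on ties", {
  mapping <- data.frame(
    uniprot = c("P11111", "P11111", "P22222", NA),
    entrez = c("2064", "100", "7430", "999"),
    symbol = c("ERBB2", "ADA", "VIM", "ZZZ3")
  )
  res <- map_ids(data.frame(id = "P11111", namespace = "uniprot"), mapping)
  expect_equal(res$entrez, "100")
  expect_equal(res$symbol, "ADA")

  # an Entrez id passes through unchanged
  res2 <- map_ids(data.frame(id = "999", namespace = "entrez"), mapping)
  expect_equal(res2$entrez, "999")

  # unknown ids land in the unmapped report, not an exception
  res3 <- map_ids(data.frame(id = "P99999", namespace = "uniprot"), mapping)
  expect_true(is.na(res3$entrez))
  expect_equal(attr(res3, "unmapped"), "P99999")
})

test_that("reference merging unions partners by Entrez id with provenance", {
  mapping <- data.frame(
    uniprot = c("P00001", "P00002", "P00003"),
    entrez = c("1", "2", "3"),
    symbol = c("G1", "G2", "G3"))
  edge <- function(id, ns, db) {
    data.frame(bait_id = "10013", partner_id = id, namespace = ns,
               source_db = db)
  }
  A <- rbind(edge("1", "entrez", "biogrid"), edge("2", "entrez", "biogrid"))
  B <- rbind(edge("2", "entrez", "intact"), edge("3", "entrez", "intact"))
  m <- merge_references(A, B, mapping)
  expect_setequal(m$entrez, c("1", "2", "3"))
  expect_equal(m$source_dbs[m$entrez == "2"], "biogrid;intact")

  expect_equal(merge_references(A, A[0, ], mapping)$entrez, c("1", "2"))

  # the same protein as UniProt in one set and Entrez in the other collapses
  C <- edge("P00002", "uniprot", "intact")
  m2 <- merge_references(A, C, mapping)
  expect_equal(sum(m2$entrez == "2"), 1)
  expect_equal(m2$source_dbs[m2$entrez == "2"], "biogrid;intact")
})

test_that("network/reference comparison partitions partners disjointly", {
  net <- mini_hdac6_network()
  fx <- gen_reference_sets(net$nodes$partner, n_shared = 5, n_db_only = 7,
                           seed = 11)
  merged <- merge_references(fx$setA, fx$setB, fx$mapping)
  rep <- compare_network(net, merged, fx$mapping)
  g <- glance(rep)
  expect_equal(g$shared, 5)
  expect_equal(g$literature_only, 7)
  expect_equal(g$database_only, 7)
  expect_equal(g$network_total, nrow(net$nodes))
  expect_equal(anyDuplicated(rep$entrez), 0)

  # identity: reference equal to the network leaves nothing unique
  fx2 <- gen_reference_sets(net$nodes$partner, n_shared = 12, n_db_only = 0,
                            seed = 12)
  g2 <- glance(compare_network(
    net, merge_references(fx2$setA, fx2$setB, fx2$mapping), fx2$mapping))
  expect_equal(g2$literature_only, 0)
  expect_equal(g2$database_only, 0)

  # disjoint: no shared partner
  fx3 <- gen_reference_sets(net$nodes$partner, n_shared = 0, n_db_only = 4,
                            seed = 13)
  g3 <- glance(compare_network(
    net, merge_references(fx3$setA, fx3$setB, fx3$mapping), fx3$mapping))
  expect_equal(g3$shared, 0)
})

test_that("comparison is symmetric up to swapping the unique categories", {
  net <- mini_hdac6_network()
  fx <- gen_reference_sets(net$nodes$partner, n_shared = 6, n_db_only = 9,
                           seed = 21)
  merged <- merge_references(fx$setA, fx$setB, fx$mapping)
  g <- glance(compare_network(net, merged, fx$mapping))

  # swap roles: a network made of the reference partners, compared against
  # the original network partners as the reference set
  swapped_net <- synthetic_network(1)
  swapped_net$nodes <- tibble::tibble(
    partner = merged$symbol, subnetworks = list("REGULATORY"),
    primary_subnetwork = "REGULATORY", direction = "undirected",
    interaction_label = "interacts with", complex_id = NA_character_,
    evidence = list(tibble::tibble(article_id = "X", sentence = "Y")))
  net_as_ref <- tibble::tibble(
    entrez = fx$mapping$entrez[match(net$nodes$partner, fx$mapping$symbol)],
    symbol = net$nodes$partner, source_dbs = "litnet")
  g_swapped <- glance(compare_network(swapped_net, net_as_ref, fx$mapping))
  expect_equal(g_swapped$shared, g$shared)
  expect_equal(g_swapped$literature_only, g$database_only)
  expect_equal(g_swapped$database_only, g$literature_only)
})

test_that("snapshot-shaped overlap arithmetic reproduces the printed partition", {
  # a 115-partner network compared against references holding 53 of its
  # partners plus 212 others must leave 62 literature-only partners
  symbols <- sprintf("LIT%03d", 1:115)
  fx <- gen_reference_sets(symbols, n_shared = 53, n_db_only = 212, seed = 5)
  net <- synthetic_network(23)  # 5 x 23 = 115 partners
  net$nodes$partner <- symbols
  merged <- merge_references(fx$setA, fx$setB, fx$mapping)
  g <- glance(compare_network(net, merged, fx$mapping))
  expect_equal(g$shared, 53)
  expect_equal(g$literature_only, 62)
  expect_equal(g$database_only, 212)
})

test_that("brain-expression filtering honours levels, regions and reliability", {
  expr <- tibble::tibble(
    gene = c("G1", "G1", "G2", "G3", "G4", "G5"),
    gene_name = c("G1", "G1", "G2", "G3", "G4", "G5"),
    tissue = c("cerebellum", "liver", "cerebral cortex", "hippocampus",
               "liver", "caudate"),
    level = c("high", "not detected", "low", "high", "high", "medium"),
    reliability = c("approved", "approved", "approved", "uncertain",
                    "approved", "supported"))
  flt <- filter_brain_expressed(c("G1", "G2", "G3", "G4", "G5", "G6"), expr)
  expect_equal(flt$status,
               c("retained", "not_retained", "no_data", "not_retained",
                 "retained", "no_data"))
  # G3 is high in hippocampus but uncertain: the reliability exclusion acts
  # before the level test, so it has no usable record at all
  expect_equal(flt$status[flt$gene == "G3"], "no_data")
})

test_that("brain-expression filtering is monotone in regions and levels", {
  fx <- gen_expression_table(sprintf("G%02d", 1:40), n_expressed = 15, seed = 3)
  cand <- sprintf("G%02d", 1:40)
  base <- filter_brain_expressed(cand, fx$expr)
  expect_setequal(base$gene[base$status == "retained"], fx$truth_expressed)

  wider_regions <- filter_brain_expressed(
    cand, fx$expr, regions = c(brain_regions(), "liver"))
  wider_levels <- filter_brain_expressed(
    cand, fx$expr, keep_levels = c("low", "medium", "high"))
  retained <- function(x) x$gene[x$status == "retained"]
  expect_true(all(retained(base) %in% retained(wider_regions)))
  expect_true(all(retained(base) %in% retained(wider_levels)))
})
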