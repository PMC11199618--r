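test_that("direct rows merge per partner with unioned evidence", {
  sheet <- mini_curated_sheet()
  extra <- sheet[sheet$partner == "CTTN", ]
  extra$doc_id <- "PMID9999"
  extra$sentence <- "Cortactin deacetylation by HDAC6 controls cell motility."
  net <- build_network(dplyr::bind_rows(sheet, extra), bait = "HDAC6")
  cttn <- net$nodes[net$nodes$partner == "CTTN", ]
  expect_equal(nrow(cttn), 1)
  expect_equal(nrow(cttn$evidence[[1]]), 2)
})

test_that("the packaged miniature network has the documented structure", {
  net <- mini_hdac6_network()
  g <- glance(net)
  expect_equal(g$n_partners, 12)
  expect_equal(g$n_indirect_targets, 8)
  expect_equal(g$n_binding_annotated, 6)
  expect_equal(nrow(validate_network(net)), 0)

  # partition cover: every node sits in >= 1 subnetwork and the union of
  # subnetwork sets equals the node set
  sets <- export_sets(net)
  expect_true(all(lengths(net$nodes$subnetworks) >= 1))
  expect_setequal(
    unique(unlist(sets[setdiff(names(sets), "FULL_NETWORK")])),
    net$nodes$partner)

  complexes <- unique(net$nodes$complex_id[!is.na(net$nodes$complex_id)])
  expect_equal(length(complexes), 3)
})

test_that("validation reports broken invariants by name", {
  net <- mini_hdac6_network()
  net$nodes$evidence[[1]] <- net$nodes$evidence[[1]][0, ]
  v <- validate_network(net)
  expect_true(any(grepl("empty evidence", v$message)))

  net2 <- mini_hdac6_network()
  net2$bindings$domains[[1]] <- c("DD1", "NOT_A_DOMAIN")
  v2 <- validate_network(net2)
  expect_true(any(grepl("unknown domain: NOT_A_DOMAIN", v2$message)))

  net3 <- mini_hdac6_network()
  net3$nodes$complex_id[net3$nodes$partner == "CTTN"] <- "SPURIOUS"
  expect_true(any(grepl("complex_id", validate_network(net3)$message)))
})

test_that("curated-sheet validation errors are actionable", {
  sheet <- mini_curated_sheet()
  sheet$interaction_class[3] <- ""
  expect_error(build_network(sheet), "interaction_class")

  sheet2 <- mini_curated_sheet()
  sheet2$subnetwork[sheet2$interaction_class == "direct"][1] <- ""
  expect_error(build_network(sheet2), "subnetwork")

  sheet3 <- mini_curated_sheet()
  expect_error(
    build_network(sheet3, hgnc_map = data.frame(alias = "x", symbol = "X1")),
    "Unmapped partner")
})

test_that("gene-set export gives one set per populated subnetwork plus the union", {
  net <- mini_hdac6_network()
  sets <- export_sets(net)
  expect_equal(length(sets), 6)  # five populated categories + full network
  expect_setequal(sets$FULL_NETWORK, net$nodes$partner)
  # a multi-membership node appears in each of its sets, once in the union
  expect_true("MAPT" %in% sets$DEACETYLATION)
  expect_true("MAPT" %in% sets$AGGRESOME_AUTOPHAGY)
  expect_equal(sum(sets$FULL_NETWORK == "MAPT"), 1)

  gmt <- tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  lines <- readLines(gmt)
  expect_equal(length(lines), 6)
  fields <- strsplit(lines, "\t")
  expect_setequal(vapply(fields, `[[`, character(1), 1), names(sets))

  # an empty subnetwork is omitted, not written as an empty line
  small <- build_network(mini_curated_sheet()[1:2, ], bait = "HDAC6")
  expect_false("PHOSPHORYLATION" %in% names(export_sets(small)))
})

test_that("binding summaries aggregate partners per domain", {
  net <- mini_hdac6_network()
  sb <- summarize_bindings(net)
  expect_equal(sb$domain, hdac6_domain_map()$domain)
  expect_equal(attr(sb, "n_annotated"), 6)
  dd2 <- strsplit(sb$partners[sb$domain == "DD2"], ";")[[1]]
  expect_true(all(c("MAPT", "SQSTM1", "MIIP", "STUB1") %in% dd2))
  se14 <- strsplit(sb$partners[sb$domain == "SE14"], ";")[[1]]
  expect_identical(se14, "MAPT")

  bare <- net
  bare$bindings <- bare$bindings[0, ]
  sb0 <- summarize_bindings(bare)
  expect_true(all(sb0$n_partners == 0))
  expect_equal(attr(sb0, "n_annotated"), 0)
})

test_that("indirect summaries count links, not targets, order-invariantly", {
  net <- mini_hdac6_network()
  si <- summarize_indirect(net)
  expect_equal(attr(si, "n_targets"), 8)
  expect_equal(si$increased[si$mode == "expression_mRNA_protein"], 1)
  expect_equal(si$decreased[si$mode == "expression_mRNA_protein"], 1)
  expect_equal(sum(si$total_links), nrow(net$indirect))

  # a target under two modes contributes two links but one target
  sheet <- mini_curated_sheet()
  idx <- which(sheet$partner == "BDNF")
  sheet$mode_of_action[idx] <- "expression_mRNA_protein;activity"
  net2 <- build_network(sheet, bait = "HDAC6")
  si2 <- summarize_indirect(net2)
  expect_equal(sum(si2$total_links), sum(si$total_links) + 1)
  expect_equal(attr(si2, "n_targets"), 8)

  # row order of the curated sheet does not change totals
  set.seed(1)
  net3 <- build_network(sheet[sample(nrow(sheet)), ], bait = "HDAC6")
  expect_equal(summarize_indirect(net3), si2, ignore_attr = FALSE)

  bare <- net
  bare$indirect <- bare$indirect[0, ]
  expect_true(all(summarize_indirect(bare)$total_links == 0))
})

test_that("directions default by interaction category when uncurated", {
  sheet <- mini_curated_sheet()
  sheet$direction <- ""
  net <- build_network(sheet, bait = "HDAC6")
  td <- tidy(net)
  expect_equal(td$direction[td$partner == "TUBA4A"], "bait_to_partner")
  expect_equal(td$direction[td$partner == "MAPK1"], "partner_to_bait")
  expect_equal(td$direction[td$partner == "MIIP"], "partner_to_bait")
  expect_equal(td$direction[td$partner == "VCP"], "bait_to_partner")  # aggresome cargo
})
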