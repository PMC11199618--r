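test_that("dictionary compilation maps surface forms to approved symbols", {
  d <- compile_dictionary("cortactin", toy_hgnc_map(), bait_symbol = "HDAC6")
  cttn <- d$entries[d$entries$symbol == "CTTN", ]
  expect_setequal(cttn$alias, c("CTTN", "cortactin"))

  d2 <- compile_dictionary("IIp45", toy_hgnc_map(), bait_symbol = "HDAC6")
  expect_setequal(d2$entries$alias[d2$entries$symbol == "MIIP"],
                  c("MIIP", "IIp45"))

  d3 <- compile_dictionary(c("cortactin", "frobnicin"), toy_hgnc_map(),
                           bait_symbol = "HDAC6")
  expect_identical(d3$unmapped, "frobnicin")
  expect_false("frobnicin" %in% d3$entries$alias)

  clash <- rbind(toy_hgnc_map(),
                 data.frame(alias = "cortactin", symbol = "OTHER1"))
  expect_error(compile_dictionary("cortactin", clash, bait_symbol = "HDAC6"),
               "multiple symbols")
})

test_that("sentence splitting is abbreviation-safe with faithful offsets", {
  s <- split_sentences("A. B. took tubulin. HDAC6 binds it.")
  expect_equal(nrow(s), 2)
  expect_equal(s$text, c("A. B. took tubulin.", "HDAC6 binds it."))

  expect_equal(nrow(split_sentences("no terminator here at all")), 1)
  expect_equal(nrow(split_sentences("   \n  ")), 0)
  expect_equal(nrow(split_sentences("See Fig. 2 for details, e.g. panel B.")), 1)

  # offsets reconstruct the source
  texts <- c(
    "One sentence. Another one! A third? Trailing tail without end",
    "Dr. Smith et al. report binding. i.e. a complex forms.",
    "Single."
  )
  for (txt in texts) {
    s <- split_sentences(txt)
    for (i in seq_len(nrow(s))) {
      expect_identical(substr(txt, s$start[i], s$end[i]), s$text[i])
    }
    # slices plus gaps reconstruct the input
    rebuilt <- ""
    cursor <- 1L
    for (i in seq_len(nrow(s))) {
      rebuilt <- paste0(rebuilt, substr(txt, cursor, s$start[i] - 1L), s$text[i])
      cursor <- s$end[i] + 1L
    }
    rebuilt <- paste0(rebuilt, substr(txt, cursor, nchar(txt)))
    expect_identical(rebuilt, txt)
  }
})

test_that("mention matching follows the boundary, case and length policies", {
  d <- toy_dictionary()
  m <- find_mentions("HDAC6 deacetylates cortactin", d)
  expect_setequal(m$symbol, c("HDAC6", "CTTN"))

  # short aliases are case-sensitive: lower-case 'tat' must not hit TAT
  dtat <- compile_dictionary(
    "TAT", data.frame(alias = "TAT", symbol = "TAT"), bait_symbol = "HDAC6")
  expect_equal(nrow(find_mentions("the tat protein", dtat)), 0)
  expect_equal(find_mentions("the TAT protein", dtat)$symbol, "TAT")

  # punctuation flanks count as boundaries; hyphen/Greek normalisation applies
  m2 <- find_mentions("the α-tubulin/HDAC6 complex", d)
  expect_true("HDAC6" %in% m2$symbol)
  expect_true("TUBA4A" %in% m2$symbol)
  m3 <- find_mentions("HDAC-6 binds tau.", d)
  expect_true("HDAC6" %in% m3$symbol)
  expect_true("MAPT" %in% m3$symbol)

  # no hits inside longer words
  expect_false("MAPT" %in% find_mentions("metataulike", d)$symbol)

  # offsets are faithful under the matching policy
  sent <- "HDAC-6 deacetylates cortactin near α-tubulin."
  for (i in seq_len(nrow(find_mentions(sent, d)))) {
    mm <- find_mentions(sent, d)[i, ]
    slice <- substr(sent, mm$start, mm$end)
    norm_slice <- tolower(litminer:::normalize_text_map(slice)$norm)
    norm_alias <- tolower(litminer:::normalize_alias(mm$alias))
    expect_identical(norm_slice, norm_alias)
  }
})

test_that("longest alias wins and mentions never overlap", {
  map <- data.frame(alias = c("ERK", "ERK kinase"), symbol = c("MAPK1", "MAPK1"))
  d <- compile_dictionary(c("ERK", "ERK kinase"), map, bait_symbol = "HDAC6")
  m <- find_mentions("the ERK kinase binds HDAC6", d)
  expect_equal(m$alias[m$symbol == "MAPK1"], "ERK kinase")
  ends <- m[order(m$start), ]
  if (nrow(ends) > 1) {
    expect_true(all(ends$start[-1] > ends$end[-nrow(ends)]))
  }
})

test_that("co-mention extraction needs the bait plus a distinct partner", {
  d <- toy_dictionary()
  doc <- paste(
    "Cells were cultured for five days.",
    "The buffer contained protease inhibitors.",
    "HDAC6 deacetylates cortactin in neurons.",
    "Sections were imaged at high magnification.",
    "Samples were processed in triplicate.",
    "Controls behaved as expected.",
    "Lysates were frozen at minus eighty.",
    "Data were analysed blind to genotype.",
    "Mice were genotyped at weaning.",
    "The gel was transferred overnight.")
  cm <- extract_comentions(doc, "D1", d)
  expect_equal(nrow(cm), 1)
  expect_equal(cm$partners[[1]]$symbol, "CTTN")

  expect_equal(nrow(extract_comentions("HDAC6 and HDAC-6 again.", "D2", d)), 0)
  expect_equal(nrow(extract_comentions("cortactin binds tau.", "D3", d)), 0)

  cm2 <- extract_comentions("HDAC6 binds cortactin and tau.", "D4", d)
  expect_equal(nrow(cm2), 1)
  expect_setequal(cm2$partners[[1]]$symbol, c("CTTN", "MAPT"))
})

test_that("curation sheets fan out, deduplicate and serialise deterministically", {
  d <- toy_dictionary()
  cm <- extract_comentions("HDAC6 binds cortactin and tau.", "D4", d)
  sheet <- export_curation_sheet(cm)
  expect_equal(nrow(sheet), 2)
  expect_equal(sheet$partner, sort(sheet$partner))
  expect_true(all(sheet$interaction_class == ""))

  # the same sentence retrieved twice collapses to one row
  sheet2 <- export_curation_sheet(dplyr::bind_rows(cm, cm))
  expect_equal(nrow(sheet2), 2)

  empty <- export_curation_sheet(cm[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("partner", "doc_id", "sentence", "interaction_class")
                  %in% names(empty)))

  f1 <- tempfile(); f2 <- tempfile()
  write_curation_sheet(sheet, f1)
  write_curation_sheet(export_curation_sheet(cm), f2)
  expect_identical(readLines(f1), readLines(f2))
  rt <- read_curation_sheet(f1)
  expect_equal(rt$partner, sheet$partner)
  expect_equal(rt$sentence, sheet$sentence)
})
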