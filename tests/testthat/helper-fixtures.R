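# Shared in-code fixtures for the test suite.

toy_hgnc_map <- function() {
  data.frame(
    alias = c("cortactin", "tau", "IIp45", "alpha-tubulin", "Ku70",
              "p62", "Parkin"),
    symbol = c("CTTN", "MAPT", "MIIP", "TUBA4A", "XRCC6", "SQSTM1", "PRKN"),
    stringsAsFactors = FALSE
  )
}

toy_dictionary <- function() {
  compile_dictionary(
    c("cortactin", "tau", "IIp45", "alpha-tubulin", "Ku70"),
    toy_hgnc_map(), bait_symbol = "HDAC6"
  )
}

toy_manifest <- function() {
  tibble::tibble(
    article_id = c("A1", "A2", "A3", "A4", "A5", "A6"),
    pmid = c("100", "101", "100", "102", "103", "104"),
    pmcid = c("PMC1", "PMC2", "PMC3", "PMC4", "PMC5", "PMC6"),
    title = c("t1", "t2", "t1 dup", "t4", "t5", "t6"),
    language = c("en", "fr", "en", "en", "en", NA),
    open_access = TRUE,
    fulltext_ref = NA_character_,
    abstract = c("text", "texte", "text", "", "text", "text")
  )
}

toy_annotation_payload <- function() {
  list(
    list(
      pmcid = "PMC1",
      annotations = list(
        list(exact = "HDAC6", type = "Gene_Proteins", section = "Results",
             prefix = "the ", postfix = " enzyme",
             tags = list(list(name = "HDAC6",
                              uri = "https://purl.uniprot.org/uniprot/Q9UBN7"))),
        list(exact = "Mus musculus", type = "Organisms", section = "Methods",
             prefix = "", postfix = "",
             tags = list(list(name = "Mus musculus",
                              uri = "http://purl.obolibrary.org/obo/NCBITaxon_10090"))),
        list(exact = "cortactin", type = "Gene Disease Relationship",
             section = "Discussion", prefix = "", postfix = "",
             tags = list(list(name = "cortactin",
                              uri = "https://purl.uniprot.org/uniprot/Q14247")))
      )
    )
  )
}

# randomized p of the one-sided exact test: exactly Uniform(0,1) under the
# hypergeometric null (standard uniformization of a discrete p value)
randomized_p <- function(a, b, c_, d) {
  p <- fisher_exact(a, b, c_, d, "greater")
  pm <- hypergeom_pmf(a + b + c_ + d, a + b, a + c_)
  p - stats::runif(1) * pm$prob[pm$a == a]
}
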