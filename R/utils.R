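# Shared internal helpers.

#' The five interaction subnetwork categories
#'
#' Closed vocabulary for the curated interaction categories used throughout
#' the package: deacetylation substrates/partners, kinases acting on the bait,
#' multi-protein complexes containing the bait, regulators of bait expression
#' or activity, and aggresome/autophagy machinery.
#'
#' @return Character vector of the five category labels.
#' @export
subnetwork_levels <- function() {
  c("DEACETYLATION", "PHOSPHORYLATION", "PROTEIN_COMPLEX",
    "REGULATORY", "AGGRESOME_AUTOPHAGY")
}

#' Modes of action for indirect (inhibition-response) targets
#'
#' Closed vocabulary for effects observed upon bait knockdown or chemical
#' inhibition rather than through a physical interaction.
#'
#' @return Character vector of the seven mode labels.
#' @export
indirect_modes <- function() {
  c("expression_mRNA_protein", "phosphorylation", "acetylation",
    "activity", "degradation", "transport_localization", "other")
}

# Modes that may carry an increased/decreased direction.
directed_modes <- function() c("expression_mRNA_protein", "phosphorylation")

#' Default brain regions for expression filtering
#'
#' The seven brain regions used when restricting database-derived interactors
#' to those detectably expressed in brain tissue.
#'
#' @return Character vector of region labels (Human Protein Atlas tissue names).
#' @export
brain_regions <- function() {
  c("caudate", "cerebellum", "cerebral cortex", "dorsal raphe",
    "hippocampus", "hypothalamus", "substantia nigra")
}

# split a "A;B;C" field into a character vector, dropping empties
split_multi <- function(x, sep = ";") {
  out <- strsplit(as.character(x), sep, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_multi <- function(x, sep = ";") {
  vapply(x, function(v) paste(v, collapse = sep), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number strictly between 0 and 1.", name))
  }
  invisible(x)
}
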