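# Surface-form normalisation shared by the dictionary and the text matcher.
# Greek letters are spelled out and internal hyphens between alphanumerics
# are dropped, so that "HDAC-6", "Hdac6" and "HDAC6" collapse to one key and
# "α-tubulin" matches "alpha-tubulin".

greek_table <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta", "θ" = "theta", "κ" = "kappa",
  "λ" = "lambda", "μ" = "mu", "ρ" = "rho",
  "σ" = "sigma", "τ" = "tau", "φ" = "phi",
  "χ" = "chi", "ψ" = "psi", "ω" = "omega"
)

is_alnum_chr <- function(ch) grepl("[[:alnum:]]", ch)

# Normalise text while keeping a map from each normalised character back to
# its 1-based position in the original string. Greek letters expand to their
# spelled-out names (every produced character maps to the source letter);
# hyphens flanked by alphanumerics are dropped.
normalize_text_map <- function(text) {
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  n <- length(chars)
  out <- character(0)
  map <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (!is.na(greek_table[ch])) {
      word <- greek_table[[ch]]
      out <- c(out, strsplit(word, "")[[1]])
      map <- c(map, rep(i, nchar(word)))
    } else if (ch == "-" &&
               i > 1L && i < n &&
               is_alnum_chr(chars[i - 1L]) && is_alnum_chr(chars[i + 1L])) {
      # drop internal hyphen
    } else {
      out <- c(out, ch)
      map <- c(map, i)
    }
  }
  list(norm = paste(out, collapse = ""), map = map)
}

# Normalise a dictionary alias: Greek spelled out; internal hyphens removed
# when the de-hyphenated alias is at least 4 characters (short aliases keep
# their hyphen to avoid over-merging 2-3-letter symbols).
normalize_alias <- function(alias) {
  for (g in names(greek_table)) {
    alias <- gsub(g, greek_table[[g]], alias, fixed = TRUE)
  }
  dehyph <- gsub("(?<=[[:alnum:]])-(?=[[:alnum:]])", "", alias, perl = TRUE)
  if (nchar(dehyph) >= 4L) dehyph else alias
}
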