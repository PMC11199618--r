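---
title: "Mining, modelling and testing a bait-centric interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, modelling and testing a bait-centric interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litminer)
```

`litminer` implements a semi-automated workflow for collecting the
protein–protein interactions of one bait protein from the literature and
analysing them in a tissue context. This vignette is the package's own
account of the method: the procedure and its assumptions, the parameters
that matter, what the synthetic generators emulate, the numerical choices,
and the limitations.

## The procedure

The pipeline has five stages, with one deliberate human step in the middle.

1. **Screen.** An article manifest (one row per retrieved record) passes
   through PRISMA-style screening: records sharing a PMID/PMCID with an
   earlier record are duplicates; non-English records and records with
   neither full text nor abstract are excluded; identifiers on an
   externally supplied off-topic list are excluded. The ledger
   (`screen_articles()`, `glance()`) is conservative by construction:
   every record lands in exactly one bucket, and re-screening a ledger is
   idempotent. Off-topic verdicts are *inputs* — the tool records the
   curator's full-text screening, it does not make relevance decisions.

2. **Mine.** Named-entity annotations (Europe PMC response shape) are
   parsed and filtered to gene/protein annotations, or gene–disease
   relationships backed by a UniProt identifier (`parse_annotations()`,
   `filter_annotations()`; the provider category strings are configurable
   constants because annotation vocabularies drift between releases).
   The resulting shortlist is normalised to approved gene symbols
   (`compile_dictionary()`; genes and their protein products are one
   entity), and every sentence naming the bait plus at least one other
   dictionary entity becomes a co-mention (`split_sentences()`,
   `extract_comentions()`). This two-step design — shortlist from open
   annotation content, then full-text dictionary search — finds evidence
   in closed-access text for any entity named in any open text.

3. **Curate (external).** `export_curation_sheet()` writes one row per
   (document, sentence, partner) with empty curator columns:
   `interaction_class` (direct / indirect / reject), `subnetwork`,
   `direction`, `mode_of_action`, `binding_domains`. The handoff is an
   explicit file boundary; interaction truth is a curator judgement, not
   an algorithmic one, and the package does not pretend otherwise.
   Sentence hits without explicit interaction wording are deliberately
   left on the sheet: triage is part of curation.

4. **Build.** `build_network()` merges direct rows per partner (union of
   subnetworks and evidence), populates binding-domain annotations and the
   indirect catalog, and `write_gpml()` serialises the result as a GPML
   2013a pathway (hub node, partner DataNodes with HGNC Xrefs, complexes
   as `Group` elements, typed directed edges, evidence in node comments
   and dynamic properties). `read_gpml()` inverts it exactly.

5. **Compare and enrich.** The network is compared against reference
   database edge sets unified by Entrez id (`merge_references()`,
   `compare_network()`), database-only interactors are filtered by brain
   expression (`filter_brain_expressed()`), and differential-expression
   tables are tested for subnetwork overrepresentation
   (`subnetwork_enrichment()`).

## The network model

Partners occupy one or more of five closed subnetwork categories:
deacetylation substrates/partners, kinases acting on the bait, protein
complexes containing the bait, regulators of the bait's expression or
activity, and aggresome–autophagy machinery. Multi-membership is real —
chaperones act in both deacetylation and aggresome contexts — so nodes
store a subnetwork *set* plus a primary category used only for labelling
and figure-style layout. Binding annotations reference the bait's ordered
domain map (NLS, NES1, DD1, DMB, DD2, SE14, NES2, ZnF-UBP); amino-acid
coordinates are optional and comparisons are by domain name, because
published domain diagrams give order reliably but boundaries
inconsistently. Indirect targets — effects seen on bait knockdown or
inhibition — are kept separate from direct partners and categorised into
seven modes of action; a direction (increased/decreased) attaches only to
the expression and phosphorylation modes, matching how such effects are
reported.

When the curator leaves `direction` blank, edges default by category:
kinases and regulators point at the bait; deacetylation substrates and
aggresome cargo are pointed at by the bait; complexes are undirected.

## Matching policy

Dictionary matching hides most of the method's false-positive risk, so
the policy is explicit:

* word-boundary anchored — the characters flanking a hit must be
  non-alphanumeric;
* longest alias wins at each position, and accepted mentions never
  overlap;
* aliases of ≤ 3 characters match case-sensitively, longer aliases
  case-insensitively. Short gene symbols (`TAT`, `CA2`) are common
  English letter sequences; case sensitivity suppresses hits inside
  ordinary words while leaving long aliases robust to casing;
* Greek letters are spelled out and internal hyphens dropped on both the
  alias and text sides (aliases shorter than four characters keep their
  hyphen), so `HDAC-6`, `Hdac6` and `α-tubulin` match their canonical
  forms. Offsets always index the *original* sentence.

Co-mention scope is a single sentence; cross-sentence coreference is out
of scope, and interaction-verb classification is curator work.

## The exact overrepresentation test

DEGs are called at strict nominal *p* < α (default 0.05) after collapsing
probes to genes by minimum *p* (ties break on the smaller probe
identifier, making the collapse deterministic). For each subnetwork and
for the full network, the 2×2 table of DEG membership against set
membership is tested with the hypergeometric tail, computed from
log-binomial coefficients with log-sum-exp accumulation — no normal
approximation, stable down to the smallest representable tails. The
two-sided variant sums all outcomes whose point probability is within a
relative 1e-7 of not exceeding the observed one (the standard small-*p*
convention). One-sided "greater" is the default: the scientific question
is overrepresentation.

The background universe is the set of genes surviving preprocessing in
the DE table — overrepresentation among *testable* genes is the
defensible null; a whole-genome background would manufacture enrichment
from platform coverage alone. Genes in several subnetworks count once per
subnetwork table and once in the full-network table. Raw p values are
primary; Benjamini–Hochberg adjustment across the five subnetworks is
always reported alongside. Odds ratios use the sample estimate
(a·d)/(b·c), reported as `Inf` when only the denominator product is zero
and `NA` when both products vanish; no continuity correction is applied
because inference comes from the exact test, not the odds ratio.

## Identifier handling

Reference edges arrive as offline TSV snapshots (pinned snapshots keep
tests hermetic and counts reproducible per snapshot). UniProt accessions
with several Entrez candidates resolve to the numerically smallest Entrez
id — the earliest-assigned gene — which makes the merge deterministic.
Unmappable identifiers are routed to unmapped reports, never silently
dropped and never fatal. Expression filtering follows the Human Protein
Atlas normal-tissue dialect: records with reliability `uncertain` are
removed *before* the level test, and a candidate is retained if any
record in a selected brain region (default: caudate, cerebellum, cerebral
cortex, dorsal raphe, hippocampus, hypothalamus, substantia nigra) has
level medium or high. The filter is monotone in both the region and the
level sets.

## Synthetic generators and what they show

Every input dialect has a seeded generator with ground truth attached
(`gen_corpus()`, `gen_reference_sets()`, `gen_expression_table()`,
`gen_de_experiment()`), plus a frozen 12-partner miniature network
(`mini_hdac6_network()`) spanning all five subnetworks, three complexes,
six binding annotations and eight indirect targets. Generators are pure
functions of their arguments including the seed, and they restore the
global RNG state.

`gen_corpus()` plants bait–partner sentences using exact dictionary
aliases inside entity-free distractor text. Passing the 100%-recall /
zero-false-pair check therefore shows that the matcher and sentence
splitter are correct *under the matching policy*; it does not show recall
on real prose, where authors use unlisted synonyms, and it cannot measure
curation precision. `gen_de_experiment()` draws DEG membership as
independent Bernoulli trials whose probabilities are solved (by
`uniroot`) so the planted subnetwork's *expected* odds ratio equals the
request and the expected DEG total equals `n_deg`; the realised table is
recorded as truth. Real DE data violate the independence assumption
(co-expression), so the calibration and recovery results characterise the
test statistic, not any particular disease dataset.

Reference study conditions, chosen once: recovery simulations use a
network of five disjoint 20-gene subnetworks in a background of 5,000
genes with 500 expected DEGs and a planted odds ratio of 4, 200
simulations; null calibration uses the same sizes with odds ratio 1.
These sizes mirror a typical single-platform DE experiment mapped onto a
curated pathway.

## Numerical choices

* **Discrete-test calibration.** The one-sided exact p of a 2×2 table is
  discrete and super-uniform under the null (point masses of order 0.1 at
  the reference sizes), so its raw distribution cannot be uniform and a
  literal Kolmogorov–Smirnov test against Uniform(0,1) would reject for
  any correct implementation. Calibration therefore tests the
  *uniformized* p value, p − U·P(X = a) with U ~ Uniform(0,1), which is
  exactly uniform under the null, and separately asserts conservative
  type-I control of the raw p at the 0.05 level.
* **Tolerances.** Exact-test agreement with brute-force enumeration is
  required to 1e-10 over every margin with N ≤ 60; hypergeometric point
  masses must sum to 1 within 1e-12; the two-sided small-*p* comparison
  uses relative tolerance 1e-7.
* **Degenerate inputs.** Empty tables give p = 1; empty DEG sets give
  p = 1 and proportion 0 for every set; empty subnetworks are evaluated
  (set size 0) rather than skipped; sentence splitting of empty text
  yields zero sentences; screening of an empty manifest yields an empty
  ledger.
* **Tie-breaks.** Probe collapse ties break on probe id; mention
  candidates at the same position break on length then symbol; duplicate
  screening keeps the first-seen record (retained identifier sets are
  order-invariant even though the kept copy is not).

## Limitations

The tool records curation, it does not replace it; co-mention evidence is
sentence-bounded; dictionary recall is bounded by the shortlist, so an
entity never named in any open-access text is invisible; database
snapshot counts are reproducible only per snapshot; and expression-based
filtering inherits the antibody-based categorical resolution of the
normal-tissue data, which is why `uncertain` records are excluded rather
than down-weighted. Mapping transcript-level differential expression onto
a protein-interaction network assumes transcript changes are a proxy for
protein availability; post-transcriptional regulation and protein
compartmentalisation warrant caution when interpreting subnetwork
enrichments.
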