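# Differential-expression integration: probe collapse, DEG calling, the
# exact overrepresentation test, and per-subnetwork enrichment.

#' Collapse probe-level statistics to gene level
#'
#' When several probes are annotated to the same gene, the probe with the
#' lowest differential-expression p value represents the gene; ties break
#' deterministically on the smaller probe identifier string. Probes with no
#' gene annotation are dropped and reported via the `dropped_probes`
#' attribute.
#'
#' @param probe_table Data frame with columns `probe`, `gene`, `log2fc`,
#'   `p`.
#' @return A tibble with one row per gene: `gene`, `log2fc`, `p`, `probe`
#'   (the representative probe).
#' @export
collapse_probes <- function(probe_table) {
  df <- tibble::as_tibble(probe_table)
  stopifnot(all(c("probe", "gene", "log2fc", "p") %in% names(df)))
  if (any(is.na(df$p)) || any(df$p < 0 | df$p > 1)) {
    abort("p values must lie in [0, 1] and be non-missing.")
  }
  dropped <- df$probe[is.na(df$gene) | !nzchar(as.character(df$gene))]
  df <- df[!is.na(df$gene) & nzchar(as.character(df$gene)), , drop = FALSE]
  out <- df |>
    dplyr::arrange(.data$gene, .data$p, .data$probe) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE) |>
    dplyr::select("gene", "log2fc", "p", "probe")
  attr(out, "dropped_probes") <- dropped
  out
}

#' Call differentially expressed genes
#'
#' Strict nominal threshold: a gene is a DEG when `p < alpha`. The
#' direction of change is recorded from the sign of the log2 fold change.
#'
#' @param stats Gene-level tibble with `gene`, `log2fc`, `p`.
#' @param alpha Nominal significance cutoff, default 0.05.
#' @return `stats` with added `is_deg` (logical) and `deg_direction`
#'   (`"up"`/`"down"`/`NA`).
#' @export
call_degs <- function(stats, alpha = 0.05) {
  stopifnot_scalar_prob(alpha, "alpha")
  stats <- tibble::as_tibble(stats)
  stats$is_deg <- stats$p < alpha
  stats$deg_direction <- ifelse(stats$is_deg,
                                ifelse(stats$log2fc >= 0, "up", "down"),
                                NA_character_)
  stats
}

# log P(X = a) over the hypergeometric support for margins (N, K, n)
hyper_log_pmf <- function(N, K, n) {
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  a <- lo:hi
  list(a = a,
       logp = lchoose(K, a) + lchoose(N - K, n - a) - lchoose(N, n))
}

log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Hypergeometric point probabilities for fixed 2x2 margins
#'
#' The exact null distribution of the top-left cell of a 2x2 table with
#' fixed margins: `P(X = a) = C(K,a) C(N-K, n-a) / C(N,n)` over the
#' feasible support.
#'
#' @param N Total count; `K` row-one margin (set size); `n` column-one
#'   margin (number of successes drawn).
#' @return A tibble `a`, `prob` over the support; probabilities sum to 1.
#' @export
hypergeom_pmf <- function(N, K, n) {
  stopifnot(N >= 0, K >= 0, n >= 0, K <= N, n <= N)
  lp <- hyper_log_pmf(N, K, n)
  tibble::tibble(a = lp$a, prob = exp(lp$logp))
}

#' Exact test of a 2x2 contingency table
#'
#' Computes the exact tail probability of the observed table under the
#' hypergeometric null with fixed margins, in log space with no normal
#' approximation. `alternative = "greater"` sums `P(X >= a)`
#' (overrepresentation); `"two_sided"` sums all outcomes whose point
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7, the standard small-p-method convention).
#'
#' @param a DEGs (successes) inside the set; `b` non-successes inside;
#'   `c` successes outside; `d` non-successes outside. Non-negative
#'   integers.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return The exact p value (a number in (0, 1]).
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("All four cells must be non-negative integers.")
  }
  N <- a + b + c + d
  K <- a + b
  n <- a + c
  if (N == 0L) return(1)
  lp <- hyper_log_pmf(N, K, n)
  if (!a %in% lp$a) abort("Inconsistent margins: observed cell outside support.")
  if (alternative == "greater") {
    p <- exp(log_sum_exp(lp$logp[lp$a >= a]))
  } else {
    log_obs <- lp$logp[lp$a == a]
    keep <- lp$logp <= log_obs + log1p(1e-7)
    p <- exp(log_sum_exp(lp$logp[keep]))
  }
  min(p, 1)
}

odds_ratio_2x2 <- function(a, b, c, d) {
  ad <- a * d
  bc <- b * c
  if (bc == 0 && ad > 0) return(Inf)
  if (bc == 0 && ad == 0) return(NA_real_)
  ad / bc
}

#' Per-subnetwork overrepresentation of differentially expressed genes
#'
#' For each of the five subnetworks and for the full network, builds the
#' 2x2 table of DEG membership against set membership over the background
#' gene universe (all genes surviving preprocessing in the
#' differential-expression table — overrepresentation among testable genes
#' is the defensible null) and computes the exact tail probability with
#' [fisher_exact()]. A gene in several subnetworks counts once in each
#' subnetwork's table and once in the full-network table. Raw p values are
#' primary; Benjamini-Hochberg-adjusted values across the five subnetworks
#' are reported alongside.
#'
#' @param net A `ppi_network`.
#' @param stats Gene-level statistics (`gene`, `log2fc`, `p`), e.g. from
#'   [collapse_probes()].
#' @param background Character vector of background gene ids; defaults to
#'   the genes in `stats`. Must cover every tested gene and be non-empty.
#' @param alpha Nominal DEG cutoff (strict `p < alpha`), default 0.05.
#' @param alternative Sidedness of the exact test; default `"greater"`
#'   (overrepresentation).
#' @param id_map Optional data frame with columns `symbol`, `gene` linking
#'   network symbols to the identifier space of `stats`; by default network
#'   symbols are matched to `stats$gene` directly.
#' @return An `enrichment_result` tibble with one row per set: `set_name`,
#'   `set_size`, `deg_in_set`, `nondeg_in_set`, `deg_out`, `nondeg_out`,
#'   `proportion_deg`, `odds_ratio`, `p`, `p_adj`, `alternative`. Network
#'   genes absent from the background are attached as the
#'   `excluded_symbols` attribute.
#' @export
subnetwork_enrichment <- function(net, stats, background = NULL,
                                  alpha = 0.05,
                                  alternative = c("greater", "two_sided"),
                                  id_map = NULL) {
  alternative <- match.arg(alternative)
  stopifnot_scalar_prob(alpha, "alpha")
  stats <- tibble::as_tibble(stats)
  stopifnot(all(c("gene", "p") %in% names(stats)))
  if (is.null(background)) background <- unique(stats$gene)
  background <- unique(as.character(background))
  if (length(background) == 0L) abort("The background gene universe is empty.")
  if (!all(stats$gene %in% background)) {
    abort("`background` must contain every tested gene.")
  }

  deg <- unique(stats$gene[stats$p < alpha])
  to_gene <- function(symbols) {
    if (is.null(id_map)) return(symbols)
    m <- tibble::as_tibble(id_map)
    out <- m$gene[match(symbols, m$symbol)]
    out[!is.na(out)]
  }

  sets <- export_sets(net)
  # evaluate all five categories even when empty, plus the full network
  all_names <- c(subnetwork_levels(), "FULL_NETWORK")
  excluded <- character()
  rows <- lapply(all_names, function(nm) {
    members <- to_gene(sets[[nm]] %||% character())
    excluded <<- union(excluded, setdiff(members, background))
    members <- intersect(members, background)
    a <- length(intersect(members, deg))
    b <- length(members) - a
    c_ <- length(deg) - a
    d <- length(background) - a - b - c_
    tibble::tibble(
      set_name = nm, set_size = length(members),
      deg_in_set = a, nondeg_in_set = b, deg_out = c_, nondeg_out = d,
      proportion_deg = if (a + b > 0) a / (a + b) else 0,
      odds_ratio = odds_ratio_2x2(a, b, c_, d),
      p = fisher_exact(a, b, c_, d, alternative)
    )
  })
  out <- dplyr::bind_rows(rows)
  sub <- out$set_name != "FULL_NETWORK"
  out$p_adj <- NA_real_
  out$p_adj[sub] <- p.adjust(out$p[sub], method = "BH")
  out$alternative <- alternative
  attr(out, "alpha") <- alpha
  attr(out, "n_background") <- length(background)
  attr(out, "n_deg") <- length(deg)
  attr(out, "excluded_symbols") <- excluded
  class(out) <- c("enrichment_result", class(out))
  out
}

#' One-row summary of an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble: background size, DEG total, DEG count in the
#'   full network, full-network p, the top-ranked subnetwork and its p.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  full <- x[x$set_name == "FULL_NETWORK", ]
  sub <- x[x$set_name != "FULL_NETWORK", ]
  top <- sub[which.min(sub$p), ]
  tibble::tibble(
    n_background = attr(x, "n_background"),
    n_deg = attr(x, "n_deg"),
    deg_in_network = full$deg_in_set,
    p_full_network = full$p,
    top_subnetwork = top$set_name,
    p_top_subnetwork = top$p
  )
}

#' Plot per-subnetwork DEG proportions
#'
#' Dot plot of the proportion of differentially expressed genes per
#' subnetwork, point colour and size encoding the exact-test significance
#' (-log10 p), with a dashed line at the full-network proportion.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  sub <- object[object$set_name != "FULL_NETWORK", ]
  full_prop <- object$proportion_deg[object$set_name == "FULL_NETWORK"]
  sub$neglog10p <- -log10(pmax(sub$p, .Machine$double.xmin))
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$proportion_deg,
                                    y = .data$set_name)) +
    ggplot2::geom_vline(xintercept = full_prop, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$neglog10p,
                                     colour = .data$neglog10p)) +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10] ~ p)) +
    ggplot2::scale_size_continuous(name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = "Proportion of DEGs in subnetwork", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-gene network overlay of differential expression
#'
#' Joins gene-level statistics onto the network nodes, suitable for
#' pathway-painting tools.
#'
#' @param net A `ppi_network`.
#' @param stats Gene-level statistics with `gene`, `log2fc`, `p`.
#' @param alpha DEG cutoff.
#' @param id_map Optional `symbol`/`gene` map as in
#'   [subnetwork_enrichment()].
#' @return A tibble `symbol`, `subnetworks`, `log2fc`, `p`, `is_deg`.
#' @export
network_overlay <- function(net, stats, alpha = 0.05, id_map = NULL) {
  stats <- tibble::as_tibble(stats)
  gene_of <- function(symbol) {
    if (is.null(id_map)) return(symbol)
    m <- tibble::as_tibble(id_map)
    out <- m$gene[match(symbol, m$symbol)]
    ifelse(is.na(out), symbol, out)
  }
  genes <- gene_of(net$nodes$partner)
  idx <- match(genes, stats$gene)
  tibble::tibble(
    symbol = net$nodes$partner,
    subnetworks = join_multi(net$nodes$subnetworks),
    log2fc = stats$log2fc[idx],
    p = stats$p[idx],
    is_deg = !is.na(stats$p[idx]) & stats$p[idx] < alpha
  )
}
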