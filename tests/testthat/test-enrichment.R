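test_that("probe collapse keeps the minimum-p probe per gene", {
  tbl <- data.frame(
    probe = c("pA", "pB", "pC", "pD", "pE"),
    gene = c("G1", "G1", "G2", "G3", "G3"),
    log2fc = c(1.0, -0.5, 0.2, 0.8, 0.9),
    p = c(0.20, 0.04, 0.50, 0.01, 0.01))
  out <- collapse_probes(tbl)
  expect_equal(nrow(out), 3)
  expect_equal(out$p[out$gene == "G1"], 0.04)
  expect_equal(out$probe[out$gene == "G1"], "pB")
  # tie on p breaks to the smaller probe identifier
  expect_equal(out$probe[out$gene == "G3"], "pD")
  # single-probe genes pass through unchanged
  expect_equal(out$log2fc[out$gene == "G2"], 0.2)

  bad <- tbl; bad$p[1] <- 1.5
  expect_error(collapse_probes(bad), "p values")

  anno <- tbl; anno$gene[3] <- NA
  out2 <- collapse_probes(anno)
  expect_equal(attr(out2, "dropped_probes"), "pC")
})

test_that("DEG calling uses a strict nominal threshold with direction", {
  stats <- data.frame(gene = c("A", "B", "C"),
                      log2fc = c(2, -1.2, 1.0),
                      p = c(0.05, 0.049, 0.013))
  out <- call_degs(stats)
  expect_equal(out$is_deg, c(FALSE, TRUE, TRUE))
  expect_equal(out$deg_direction, c(NA, "down", "up"))
})

test_that("the exact test matches hand-enumerated tail probabilities", {
  # N=4, K=2, n=2: all C(4,2)=6 draws equally likely; P(a=2) = 1/6
  expect_equal(fisher_exact(2, 0, 0, 2, "greater"), 1 / 6, tolerance = 1e-12)
  # (3,1,1,3): [C(4,3)C(4,1) + C(4,4)C(4,0)] / C(8,4) = 17/70
  expect_equal(fisher_exact(3, 1, 1, 3, "greater"), 17 / 70, tolerance = 1e-12)
  # a = 0 always has tail probability one
  expect_equal(fisher_exact(0, 5, 3, 7, "greater"), 1)
  expect_equal(fisher_exact(0, 0, 0, 0, "greater"), 1)
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
})

test_that("the exact test agrees with the independent reference implementation", {
  set.seed(7)
  for (i in 1:50) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:8, 1); d <- sample(0:8, 1)
    if (a + b + c_ + d == 0) next
    m <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expect_equal(fisher_exact(a, b, c_, d, "greater"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_exact(a, b, c_, d, "two_sided"),
                 stats::fisher.test(m, alternative = "two.sided")$p.value,
                 tolerance = 1e-7)
  }
})

test_that("hypergeometric point masses normalise and the tail is monotone", {
  set.seed(3)
  for (i in 1:30) {
    N <- sample(2:80, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    pm <- hypergeom_pmf(N, K, n)
    expect_lt(abs(sum(pm$prob) - 1), 1e-12)
    if (nrow(pm) > 1) {
      tails <- vapply(pm$a, function(a) {
        fisher_exact(a, K - a, n - a, N - K - n + a, "greater")
      }, numeric(1))
      expect_true(all(diff(tails) < 0))  # strictly decreasing in a
    }
  }
})

test_that("subnetwork enrichment builds consistent tables over the background", {
  net <- synthetic_network(10)
  fx <- gen_de_experiment(net, background_size = 1000, n_deg = 100,
                          planted_subnetwork = "REGULATORY",
                          planted_odds_ratio = 8, seed = 42)
  res <- subnetwork_enrichment(net, fx$stats, fx$background)
  expect_s3_class(res, "enrichment_result")
  expect_equal(nrow(res), 6)
  # margins: every table sums to the background size
  expect_true(all(res$deg_in_set + res$nondeg_in_set + res$deg_out +
                    res$nondeg_out == 1000))
  # the realised truth table matches the planted set's row
  row <- res[res$set_name == "REGULATORY", ]
  expect_equal(row$deg_in_set, fx$truth$a)
  expect_equal(row$nondeg_in_set, fx$truth$b)
  expect_equal(row$odds_ratio, fx$truth$realized_odds_ratio)
  # BH adjustment spans the five subnetworks
  sub <- res[res$set_name != "FULL_NETWORK", ]
  expect_equal(sub$p_adj, stats::p.adjust(sub$p, "BH"))

  expect_error(subnetwork_enrichment(net, fx$stats, background = character()),
               "background|empty")
  expect_error(subnetwork_enrichment(net, fx$stats, background = "justone"),
               "every tested gene")
})

test_that("an empty DEG set yields unit p values and zero proportions", {
  net <- synthetic_network(5)
  fx <- gen_de_experiment(net, background_size = 200, n_deg = 0,
                          planted_subnetwork = "DEACETYLATION",
                          planted_odds_ratio = 2, seed = 8)
  expect_true(all(fx$stats$p >= 0.05))
  res <- subnetwork_enrichment(net, fx$stats, fx$background)
  expect_true(all(res$p == 1))
  expect_true(all(res$proportion_deg == 0))
})

test_that("odds ratios follow the zero-cell convention", {
  expect_equal(litminer:::odds_ratio_2x2(1, 2, 3, 4), 2 / 3)
  expect_identical(litminer:::odds_ratio_2x2(2, 0, 4, 6), Inf)
  expect_true(is.na(litminer:::odds_ratio_2x2(0, 0, 4, 0)))
})

test_that("a strongly planted subnetwork ranks first in the enrichment", {
  net <- synthetic_network(20)
  fx <- gen_de_experiment(net, background_size = 2000, n_deg = 200,
                          planted_subnetwork = "PHOSPHORYLATION",
                          planted_odds_ratio = 8, seed = 7)
  # by construction the planted set has the largest realised DEG proportion
  res <- subnetwork_enrichment(net, fx$stats, fx$background)
  sub <- res[res$set_name != "FULL_NETWORK", ]
  expect_equal(sub$set_name[which.max(sub$proportion_deg)], "PHOSPHORYLATION")
  expect_equal(sub$set_name[which.min(sub$p)], "PHOSPHORYLATION")
  g <- glance(res)
  expect_equal(g$top_subnetwork, "PHOSPHORYLATION")
})

test_that("the network overlay joins statistics onto nodes", {
  net <- mini_hdac6_network()
  stats <- data.frame(gene = c("CTTN", "MAPT"), log2fc = c(-1, 0.4),
                      p = c(0.01, 0.2))
  ov <- network_overlay(net, stats)
  expect_equal(nrow(ov), nrow(net$nodes))
  expect_true(ov$is_deg[ov$symbol == "CTTN"])
  expect_false(ov$is_deg[ov$symbol == "MAPT"])
  expect_true(all(is.na(ov$p[!ov$symbol %in% stats$gene])))
})

test_that("enrichment plots render without error", {
  net <- synthetic_network(5)
  fx <- gen_de_experiment(net, 500, 50, "REGULATORY", 4, seed = 2)
  p <- autoplot(subnetwork_enrichment(net, fx$stats, fx$background))
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gte(length(built$data), 2)
})
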