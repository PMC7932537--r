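# Information-theoretic specificity statistics: probabilities, entropy, RP,
# K-L divergence, the selectome threshold, selectome comparison and the
# kinetic completeness arithmetic.

test_that("cluster probabilities normalize within the table's own mode", {
  ct <- cluster_selection(c("PANQAG", "LPANQA"))
  p1 <- cluster_probabilities(ct)
  expect_equal(p1$p, 1)  # one cluster -> P = 1

  sizes <- c(AAAA = 3L, CCCC = 1L)
  pt <- make_prob_table(sizes)
  expect_equal(pt$p, c(0.75, 0.25))

  hex <- unique(random_hexamers(100L, seed = 5))
  for (ct in list(cluster_naive(hex), cluster_selection(hex))) {
    expect_equal(sum(cluster_probabilities(ct)$p), 1)
  }
})

test_that("Shannon entropy: uniform, point-mass and small cases", {
  expect_equal(shannon_entropy(rep(1 / 160000, 160000)), 17.288,
               tolerance = 1e-4)
  expect_equal(shannon_entropy(c(1, rep(0, 9))), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  # log20 convention: a fully non-specific pocket scores 1
  expect_equal(shannon_entropy(rep(1 / 20, 20), base = 20), 1)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("relative probability hits the non-specific and maximal extremes", {
  uniform <- make_prob_table(stats::setNames(rep(1L, 160000), all_tetramers()),
                             mode = "naive")
  # perfectly non-specific: P_S = P_NL -> RP = 1 everywhere
  rp <- relative_probability(uniform, uniform)
  expect_true(all(abs(rp$rp - 1) < 1e-12))
  expect_equal(sum(rp$kl_contrib), 0)

  # maximally specific: single substrate vs uniform -> RP = 160,000
  point <- make_prob_table(c(AAAA = 1L))
  rp2 <- relative_probability(point, uniform)
  expect_equal(rp2$rp[rp2$tetramer == "AAAA"], 160000)
  expect_equal(sum(rp2$kl_contrib), 17.288, tolerance = 1e-4)

  # simple ratio
  sel <- make_prob_table(c(AAAA = 1L, CCCC = 1L))
  naive <- make_prob_table(c(AAAA = 1L, CCCC = 3L), mode = "naive")
  rp3 <- relative_probability(sel, naive)
  expect_equal(rp3$rp[rp3$tetramer == "AAAA"], 2)  # 0.5 / 0.25

  # selection-only cluster: pseudocounted and flagged
  sel4 <- make_prob_table(c(AAAA = 1L, DDDD = 1L))
  rp4 <- relative_probability(sel4, naive)
  expect_true(rp4$pseudo[rp4$tetramer == "DDDD"])
  expect_equal(attr(rp4, "n_pseudo"), 1L)
  expect_equal(rp4$p_naive[rp4$tetramer == "DDDD"], 1 / 4)
  expect_error(relative_probability(sel4, naive, pseudocount = FALSE),
               "selection only")

  # absent from selection -> RP = 0, zero contribution
  expect_equal(rp3$rp[rp3$tetramer == "CCCC"], 2 / 3)
  sel5 <- make_prob_table(c(AAAA = 1L))
  rp5 <- relative_probability(sel5, naive)
  expect_equal(rp5$rp[rp5$tetramer == "CCCC"], 0)
  expect_equal(rp5$kl_contrib[rp5$tetramer == "CCCC"], 0)
})

test_that("K-L divergence: frozen two-term value, Gibbs inequality, errors", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75))$bits,
               0.5 * log2(2) + 0.5 * log2(2 / 3))
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75))$bits, 0.2075,
               tolerance = 1e-4)
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7))$bits, 0)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "undefined")

  # Gibbs: D >= 0 on random distribution pairs, 0 iff equal
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:50, 1L)
    p <- stats::rgamma(k, 1); p <- p / sum(p)
    q <- stats::rgamma(k, 1); q <- q / sum(q)
    expect_gte(kl_divergence(p, q)$bits, 0)
    expect_equal(kl_divergence(p, p)$bits, 0)
  }
})

test_that("normalization duality: sum of P_NL * RP is 1 without pseudocounts", {
  hex <- unique(random_hexamers(400L, seed = 13))
  naive_ct <- cluster_naive(hex)
  sel_ct <- cluster_selection(sample(hex, 150L))  # subset: no pseudocounts
  rp <- relative_probability(cluster_probabilities(sel_ct),
                             cluster_probabilities(naive_ct))
  expect_equal(attr(rp, "n_pseudo"), 0L)
  expect_equal(sum(rp$p_naive * rp$rp), 1)
})

test_that("selectome threshold sits at the cumulative zero crossing", {
  # hand-run running sum: -0.4, -0.3, 0.0, 1.0 -> crossing at RP 5
  tab <- fake_rp_table(c("AAAA", "CCCC", "DDDD", "EEEE"),
                       rp = c(0.5, 2, 5, 9),
                       kl_contrib = c(-0.4, 0.1, 0.3, 1.0))
  expect_equal(selectome_threshold(tab), 5)

  # all clusters at RP <= 1: no positive mass
  flat <- fake_rp_table(c("AAAA", "CCCC"), rp = c(0.5, 1))
  expect_warning(thr <- selectome_threshold(flat), "no definable specificity")
  expect_true(is.na(thr))

  # two-cluster table via the full probability path: contributions
  # -0.424 then +1.161, crossing at the RP-5 cluster
  sel <- make_prob_table(c(AAAA = 1L, CCCC = 1L))
  naive <- make_prob_table(c(AAAA = 9L, CCCC = 1L), mode = "naive")
  rp <- relative_probability(sel, naive)
  expect_equal(sort(rp$kl_contrib), c(0.5 * log2(5 / 9), 0.5 * log2(5)),
               tolerance = 1e-12)
  expect_equal(selectome_threshold(rp), 5)

  # threshold consistency: cumulative contribution over RP <= RP* is <= 0
  # and within one cluster's contribution of 0
  asc <- tab[order(tab$rp), ]
  below <- cumsum(asc$kl_contrib)[max(which(asc$rp < 5))]
  expect_lte(below, 0)
  expect_lte(abs(below), max(abs(asc$kl_contrib)))
})

test_that("extract_selectome uses strict RP > threshold", {
  tab <- fake_rp_table(c("AAAA", "CCCC", "DDDD", "EEEE"),
                       rp = c(0.5, 2, 5, 9),
                       p_sel = c(0.4, 0.3, 0.2, 0.1))
  tab$n_sel <- c(4L, 3L, 2L, 1L)
  tab$n_naive <- rep(1L, 4L)
  tab$p_naive <- rep(0.25, 4)
  res <- extract_selectome(tab, 5)
  expect_equal(res$selectome, "EEEE")  # the threshold cluster is excluded
  expect_equal(res$n_selectome, 1L)
  expect_equal(res$hexamers_in, 1L)
  expect_equal(res$hexamers_out, 9L)
  expect_warning(res_na <- extract_selectome(tab, NA_real_), "empty")
  expect_length(res_na$selectome, 0L)
})

test_that("a table with P_S equal to P_NL has no definable specificity", {
  # analytic null: identical distributions give RP = 1 on every cluster, so
  # there is no positive divergence mass and no threshold
  sizes <- stats::setNames(sample(1:50, 30L, replace = TRUE),
                           all_tetramers()[1:30])
  rp <- relative_probability(make_prob_table(sizes),
                             make_prob_table(sizes, mode = "naive"))
  expect_warning(thr <- selectome_threshold(rp), "no definable specificity")
  expect_true(is.na(thr))
})

test_that("fold specificity reproduces the printed comparisons", {
  expect_equal(fold_specificity(13.93, 17.288), 10.25, tolerance = 5e-3)
  expect_equal(fold_specificity(13.67, 17.288), 12.28, tolerance = 5e-3)
  expect_equal(fold_specificity(7.386, 8, base = 20), 6.29, tolerance = 5e-3)
  expect_equal(fold_specificity(7.078, 8, base = 20), 15.83, tolerance = 5e-3)
  expect_equal(fold_specificity(3.2, 3.2), 1)
  expect_error(fold_specificity(-1, 2), "negative")
  expect_error(fold_specificity(3, 2), "h_reference")
})

test_that("selectome comparison partitions the combined set", {
  a <- c("AAAA", "CCCC", "DDDD")
  b <- c("CCCC", "EEEE")
  cmpr <- compare_selectomes(a, b)
  expect_equal(cmpr$shared, "CCCC")
  expect_equal(sort(cmpr$unique_a), c("AAAA", "DDDD"))
  expect_equal(cmpr$unique_b, "EEEE")
  expect_equal(cmpr$n_combined, 4L)
  expect_equal(sum(cmpr$fractions), 100)

  expect_length(compare_selectomes(a, "EEEE")$shared, 0L)
  same <- compare_selectomes(a, a)
  expect_length(same$unique_a, 0L)
  expect_length(same$unique_b, 0L)

  # the published overlap arithmetic: 3,902 shared of 10,110 combined
  ta <- all_tetramers()[1:(3902 + 4019)]
  tb <- c(ta[1:3902], all_tetramers()[(3902 + 4019 + 1):(3902 + 4019 + 2189)])
  big <- compare_selectomes(ta, tb)
  expect_equal(big$n_combined, 10110L)
  expect_equal(unname(big$fractions["shared"]), 38.6, tolerance = 1e-2)
})

test_that("pseudo-first-order completeness matches the stated conditions", {
  expect_equal(selection_completeness(3289, 200e-9, 7200), 0.991,
               tolerance = 5e-4)
  expect_equal(selection_completeness(0, 1, 1), 0)
  expect_equal(selection_completeness(1000, 200e-9, 3600), 1 - exp(-0.72))
  expect_error(selection_completeness(-1, 1, 1), ">= 0")
})

test_that("stats TSV carries cumulative divergence in ascending-RP order", {
  sel <- make_prob_table(c(AAAA = 2L, CCCC = 1L, DDDD = 1L))
  naive <- make_prob_table(c(AAAA = 2L, CCCC = 5L, DDDD = 1L, EEEE = 4L),
                           mode = "naive")
  rp <- relative_probability(sel, naive)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(rp, path)
  df <- read.table(path, sep = "\t", header = TRUE)
  asc <- df[order(df$rp), ]
  expect_equal(asc$kl_cumulative, cumsum(asc$kl_contrib))
  expect_equal(max(df$kl_cumulative), sum(df$kl_contrib))
  expect_equal(df$rank, rank(-df$rp, ties.method = "min"))
})
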