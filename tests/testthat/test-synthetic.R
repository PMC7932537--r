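# The selection simulator: landscape construction, naive library sampling,
# selection rounds, kinetics emission.

test_that("landscapes are reproducible and special shapes behave", {
  l1 <- make_landscape(seed = 5)
  l2 <- make_landscape(seed = 5)
  expect_identical(l1, l2)
  expect_length(l1, 160000L)
  expect_true(all(is.finite(l1) & l1 >= 0))

  peak <- make_landscape(single_peak = "LANQ", peak_rate = 9999)
  expect_equal(sum(peak > 0), 1L)
  expect_equal(unname(peak["LANQ"]), 9999)

  flat <- make_landscape(flat_rate = 42)
  expect_true(all(flat == 42))

  # zero weights, zero noise: every tetramer at the scale rate
  w0 <- matrix(0, 4L, 20L, dimnames = list(NULL, aa_alphabet()))
  const <- make_landscape(seed = 1, weights = w0, scale = 100, noise_sd = 0)
  expect_true(all(abs(const - 100) < 1e-9))
})

test_that("naive library sampling is uniform, deterministic and depth-bound", {
  n1 <- simulate_naive_library(5e4, 2e5, seed = 9)
  n2 <- simulate_naive_library(5e4, 2e5, seed = 9)
  expect_identical(n1$counts, n2$counts)
  expect_equal(sum(n1$counts), 2e5)
  expect_true(all(nchar(names(n1$counts)) == 6L))
  expect_true(all(is_standard_peptide(names(n1$counts))))
  expect_lte(length(n1), 5e4)

  # a single distinct hexamer occupies 1-3 clusters after naive clustering
  one <- simulate_naive_library(1, 10, seed = 2)
  expect_length(one, 1L)
  expect_true(length(cluster_naive(one)$sizes) %in% 1:3)
})

test_that("selection is seed-deterministic and reports round summaries", {
  land <- make_landscape(seed = 61)
  e1 <- small_experiment(land, seed = 62)
  e2 <- small_experiment(land, seed = 62)
  expect_identical(e1$selection$counts, e2$selection$counts)
  rs <- attr(e1$selection, "round_summary")
  expect_equal(nrow(rs), 2L)
  expect_true(all(rs$cleaved_fraction >= 0 & rs$cleaved_fraction <= 1))
  expect_equal(sum(e1$selection$counts), 6e4)
})

test_that("without enzyme nothing is cleaved; without pressure divergence shrinks", {
  land <- make_landscape(seed = 71)
  naive <- simulate_naive_library(2e5, 6e5, seed = 72)
  cfg <- selection_config(sequencing_depth = 6e4, seed = 73)
  ctrl <- simulate_control(naive, land, cfg)
  expect_equal(ctrl$sample_label, "control")
  rs <- attr(ctrl, "round_summary")
  expect_true(all(rs$cleaved_fraction == 0))
  # only immunodepletion escapees survive: a subset of the input library
  expect_true(all(names(ctrl$counts) %in% names(naive$counts)))

  # no enzyme AND no depletion: a plain resample of the library, which
  # stays far closer to the naive reference than a real selection does
  sel <- simulate_selection(naive, land, cfg)
  an_sel <- selectome_analysis(sel, naive)
  neutral <- simulate_selection(
    naive, land,
    selection_config(enzyme_conc = 0, immunodepletion_efficiency = 0,
                     sequencing_depth = 6e5, seed = 74))
  an_neu <- suppressWarnings(selectome_analysis(neutral, naive))
  expect_lt(an_neu$result$d_kl, an_sel$result$d_kl)
  expect_lt(an_neu$result$h_naive - an_neu$result$h_selection,
            an_sel$result$h_naive - an_sel$result$h_selection)
})

test_that("perfect immunodepletion with no enzyme empties the pool", {
  land <- make_landscape(flat_rate = 0)
  naive <- simulate_naive_library(1e3, 1e4, seed = 81)
  cfg <- selection_config(enzyme_conc = 0, immunodepletion_efficiency = 1,
                          sequencing_depth = 1e3, seed = 82)
  expect_error(simulate_selection(naive, land, cfg), "no phage survived")
})

test_that("cleavage probability is monotone in rate, enzyme and time", {
  # the closed form the simulator applies per hexamer and round
  p <- function(k, E = 2e-7, t = 7200) selection_completeness(k, E, t)
  ks <- c(0, 10, 100, 1000, 10000)
  expect_true(all(diff(p(ks)) > 0))
  expect_true(all(diff(vapply(c(1e-8, 1e-7, 1e-6),
                              function(E) p(1000, E = E), 1)) > 0))
  expect_true(all(diff(vapply(c(600, 3600, 7200),
                              function(t) p(1000, t = t), 1)) > 0))
  expect_equal(round(p(3289), 2), 0.99)
})

test_that("a single hot tetramer dominates the selection outcome", {
  land <- make_landscape(single_peak = "LANQ", peak_rate = 25000)
  e <- small_experiment(land, seed = 91)
  an <- suppressWarnings(selectome_analysis(e$selection, e$naive))
  expect_true("LANQ" %in% an$result$selectome)
  # the hot cluster retains every library hexamer that carries it
  naive_ct <- cluster_naive(e$naive)
  expect_equal(unname(an$selection_clusters$sizes["LANQ"]),
               unname(naive_ct$sizes["LANQ"]))
  # hot-containing hexamers are massively enriched in read mass
  hot_mass <- function(hs) {
    hx <- names(hs$counts)
    hit <- substr(hx, 1, 4) == "LANQ" | substr(hx, 2, 5) == "LANQ" |
      substr(hx, 3, 6) == "LANQ"
    sum(hs$counts[hit]) / sum(hs$counts)
  }
  expect_gt(hot_mass(e$selection), 100 * hot_mass(e$naive))
})

test_that("kinetics tables censor at the ceiling and preserve zero rates", {
  land <- make_landscape(single_peak = "LANQ", peak_rate = 5e4,
                         context_sd = 0)
  hx <- c("KLANQA", "AAAAAA")
  kin <- emit_kinetics_table(land, hx, noise_sd = 0, ceiling = 12792,
                             seed = 3)
  expect_equal(kin$constant, c(12792, 0))  # censored; zero stays zero
  expect_equal(kin$cleavage_index, c(5L, 4L))  # P1' of the best candidate

  # noise-free emission returns exact landscape rates below the ceiling
  land2 <- make_landscape(single_peak = "LANQ", peak_rate = 777,
                          context_sd = 0)
  kin2 <- emit_kinetics_table(land2, "KLANQA", noise_sd = 0, seed = 3)
  expect_equal(kin2$constant, 777)
})

test_that("planted proteomes round-trip and write valid FASTA/TSV", {
  land <- make_landscape(seed = 55)
  pcs <- plant_cleavage_sites(land, n_proteins = 10L, protein_length = 120L,
                              n_sites = 25L, seed = 56)
  expect_length(pcs$proteome, 10L)
  expect_equal(nrow(pcs$sites), 25L)
  for (i in seq_len(25L)) {
    expect_equal(project_tetramer(pcs$proteome[[pcs$sites$protein_id[i]]],
                                  pcs$sites$p1prime_index[i]),
                 pcs$sites$tetramer[i])
  }
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(pcs$proteome, fa)
  back <- Biostrings::readAAStringSet(fa)
  expect_equal(as.character(back), pcs$proteome)
})

test_that("selectome recovery strengthens with sequencing depth", {
  land <- make_landscape(seed = 201)
  naive <- simulate_naive_library(4e5, 1.2e6, seed = 202)
  sp_at_depth <- function(depth) {
    sel <- simulate_selection(naive, land,
                              selection_config(sequencing_depth = depth,
                                               seed = 203))
    an <- selectome_analysis(sel, naive)
    st <- an$rp_table[an$rp_table$tetramer %in% an$result$selectome, ]
    stats::cor(st$rp, log(pmax(land[st$tetramer], 1e-12)),
               method = "spearman")
  }
  lo <- sp_at_depth(3e4)
  hi <- sp_at_depth(3e5)
  expect_gt(hi, 0)      # positive recovery over selectome tetramers
  expect_gt(hi, lo)     # and it sharpens with depth
})
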