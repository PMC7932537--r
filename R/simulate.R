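# synthetic_sim: generate everything the pipeline consumes with the
# statistical structure the analysis assumes — a tetramer-level specificity
# landscape, a naive hexamer library, selection rounds under
# pseudo-first-order cleavage kinetics with immunodepletion and
# sequencing-depth resampling, kinetic validation tables, and toy proteomes
# with planted cleavage sites.

#' Tetramer specificity landscape
#'
#' Assigns a catalytic efficiency (kcat/K_M, M^-1 s^-1) to every one of the
#' 160,000 tetramers from an additive position-weight energy model over
#' P3-P1' plus log-normal noise:
#' `k(t) = scale * exp(sum_position w[position, residue] + eps)`.
#' Special shapes: `single_peak` puts all activity on one tetramer (rest
#' exactly 0); `flat_rate` gives every tetramer the same rate.
#' `context_sd` rides along as an attribute: the log-scale dispersion
#' applied per hexamer during selection to emulate the unpredictable
#' contribution of the P5-P4 and P2'-P3' context residues.
#'
#' @param seed Integer seed; the landscape is reproducible from
#'   `(seed, parameters)`.
#' @param weights Optional 4 x 20 numeric matrix (positions x residues,
#'   columns named by [aa_alphabet()]); random `N(0, weight_sd)` weights are
#'   drawn when omitted.
#' @param scale Rate scale, M^-1 s^-1 (geometric median of the landscape).
#' @param noise_sd SD of the per-tetramer log-normal noise `eps`.
#' @param weight_sd SD of random position weights when `weights` is `NULL`.
#' @param context_sd Per-hexamer log-normal context dispersion used by
#'   [simulate_selection()] and [emit_kinetics_table()].
#' @param single_peak Optional tetramer: all rate mass on this motif.
#' @param peak_rate Rate of the `single_peak` tetramer.
#' @param flat_rate Optional scalar: uniform landscape at this rate.
#' @return A `specificity_landscape`: named numeric vector over all 160,000
#'   tetramers with attributes `context_sd` and `params`.
#' @export
make_landscape <- function(seed = 1L, weights = NULL, scale = 20,
                           noise_sd = 0.5, weight_sd = 1.6, context_sd = 0.6,
                           single_peak = NULL, peak_rate = 25000,
                           flat_rate = NULL) {
  tets <- all_tetramers()
  if (!is.null(single_peak)) {
    stopifnot(single_peak %in% tets)
    k <- stats::setNames(numeric(length(tets)), tets)
    k[single_peak] <- peak_rate
  } else if (!is.null(flat_rate)) {
    stopifnot(flat_rate >= 0)
    k <- stats::setNames(rep(flat_rate, length(tets)), tets)
  } else {
    set.seed(seed)
    aa <- aa_alphabet()
    if (is.null(weights)) {
      weights <- matrix(stats::rnorm(80L, sd = weight_sd), nrow = 4L,
                        dimnames = list(NULL, aa))
    }
    stopifnot(is.matrix(weights), nrow(weights) == 4L, ncol(weights) == 20L)
    if (is.null(colnames(weights))) colnames(weights) <- aa
    logk <- log(scale)
    for (p in 1:4) {
      logk <- logk + weights[p, substr(tets, p, p)]
    }
    eps <- if (noise_sd > 0) stats::rnorm(length(tets), sd = noise_sd) else 0
    k <- stats::setNames(exp(logk + eps), tets)
  }
  structure(k, context_sd = context_sd,
            params = list(seed = seed, scale = scale, noise_sd = noise_sd,
                          weight_sd = weight_sd, single_peak = single_peak,
                          peak_rate = peak_rate, flat_rate = flat_rate),
            class = "specificity_landscape")
}

# Per-hexamer effective rate: best (or summed) candidate-tetramer rate.
hexamer_rates <- function(hexamers, landscape, rate_mode = c("max", "sum")) {
  rate_mode <- match.arg(rate_mode)
  m <- vapply(0:2, function(off) {
    unname(landscape[substring(hexamers, off + 1L, off + 4L)])
  }, numeric(length(hexamers)))
  m <- matrix(m, ncol = 3L)
  if (rate_mode == "max") {
    pmax(m[, 1L], m[, 2L], m[, 3L])
  } else {
    rowSums(m)
  }
}

#' Simulate a naive hexamer library
#'
#' Distinct hexamers are drawn uniformly without replacement from the
#' 64,000,000 possible sequences; read counts follow a multinomial at the
#' requested sequencing depth (hexamers that draw zero reads are dropped).
#' With a large library the tetramer-cluster distribution is close to
#' uniform, which is the property the naive reference needs.
#'
#' @param n_distinct Number of distinct hexamers (<= 20^6).
#' @param depth Sequencing depth (total reads).
#' @param seed Integer seed.
#' @return A [hexamer_set()] with `sample_label = "naive"`.
#' @export
simulate_naive_library <- function(n_distinct = 3e6, depth = 9e6, seed = 1L) {
  stopifnot(n_distinct >= 1, n_distinct <= 20^6, depth >= n_distinct / 10)
  set.seed(seed)
  idx <- sample.int(20^6, n_distinct)
  hex <- index_to_kmer(idx, 6L)
  counts <- as.numeric(stats::rmultinom(1L, size = depth,
                                        prob = rep(1, n_distinct)))
  keep <- counts > 0
  hexamer_set(stats::setNames(counts[keep], hex[keep]),
              sample_label = "naive", n_reads_total = depth)
}

#' Selection experiment configuration
#'
#' Defaults mirror the selection conditions of the profiled experiment:
#' 200 nM active enzyme for 2 h (7,200 s) over two rounds, with the naive
#' library sequenced about ten times deeper than the selections.
#'
#' @param enzyme_conc Active enzyme concentration, M (default 200 nM).
#' @param time Incubation time per round, s (default 7,200).
#' @param n_rounds Number of selection rounds (default 2).
#' @param sequencing_depth Reads drawn from the surviving pool each round
#'   (the last round is the sequenced sample).
#' @param immunodepletion_efficiency Probability that an uncleaved phage is
#'   removed by tag immunodepletion (default 0.99).
#' @param seed Integer seed for all selection randomness.
#' @return A `selection_config` list.
#' @export
selection_config <- function(enzyme_conc = 2e-7, time = 7200, n_rounds = 2L,
                             sequencing_depth = 1e6,
                             immunodepletion_efficiency = 0.99, seed = 1L) {
  stopifnot(enzyme_conc >= 0, time >= 0, n_rounds >= 1,
            sequencing_depth >= 1,
            immunodepletion_efficiency >= 0,
            immunodepletion_efficiency <= 1)
  structure(list(enzyme_conc = enzyme_conc, time = time,
                 n_rounds = as.integer(n_rounds),
                 sequencing_depth = sequencing_depth,
                 immunodepletion_efficiency = immunodepletion_efficiency,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Simulate substrate phage selection rounds
#'
#' Each hexamer's effective rate is the best of its three candidate-tetramer
#' rates (a substrate is cleaved at its best site) times a per-hexamer
#' log-normal context factor with SD `context_sd` from the landscape. Per
#' round: cleavage probability `p = 1 - exp(-rate * E * t)`; cleaved phage
#' counts are binomial; uncleaved phage escape immunodepletion with
#' probability `1 - immunodepletion_efficiency`; the surviving pool is
#' renormalized and resampled to the sequencing depth (propagation +
#' sequencing). The final round's sample is returned.
#'
#' @param naive A naive [hexamer_set()] (the round-0 pool).
#' @param landscape A [make_landscape()] object.
#' @param config A [selection_config()].
#' @param protease_label Label carried on the output set.
#' @param rate_mode `"max"` (default: best scissile site dominates) or
#'   `"sum"` of candidate rates.
#' @return A [hexamer_set()] with `sample_label = "selection"` (or
#'   `"control"` when `enzyme_conc = 0`) and attribute `round_summary`.
#' @export
simulate_selection <- function(naive, landscape, config,
                               protease_label = "sim",
                               rate_mode = c("max", "sum")) {
  stopifnot(inherits(naive, "hexamer_set"),
            inherits(landscape, "specificity_landscape"),
            inherits(config, "selection_config"))
  rate_mode <- match.arg(rate_mode)
  set.seed(config$seed)
  hex <- names(naive$counts)
  counts <- round(naive$counts)
  context_sd <- attr(landscape, "context_sd")
  context <- if (context_sd > 0) {
    exp(stats::rnorm(length(hex), sd = context_sd))
  } else {
    rep(1, length(hex))
  }
  k_eff <- hexamer_rates(hex, landscape, rate_mode) * context
  p <- 1 - exp(-k_eff * config$enzyme_conc * config$time)
  leak <- 1 - config$immunodepletion_efficiency
  summary_rows <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    pool_size <- sum(counts)
    cleaved <- stats::rbinom(length(counts), counts, p)
    escaped <- stats::rbinom(length(counts), counts - cleaved, leak)
    surviving <- cleaved + escaped
    total <- sum(surviving)
    if (total == 0) {
      stop("no phage survived the selection round; ",
           "lower immunodepletion_efficiency or raise rates/depth")
    }
    counts <- as.numeric(stats::rmultinom(1L, size = config$sequencing_depth,
                                          prob = surviving))
    summary_rows[[r]] <- data.frame(
      round = r,
      cleaved_fraction = sum(cleaved) / max(pool_size, 1),
      surviving = total,
      distinct = sum(counts > 0))
  }
  keep <- counts > 0
  out <- hexamer_set(
    stats::setNames(counts[keep], hex[keep]),
    sample_label = if (config$enzyme_conc == 0) "control" else "selection",
    protease_label = protease_label,
    n_reads_total = config$sequencing_depth)
  attr(out, "round_summary") <- do.call(rbind, summary_rows)
  out
}

#' Simulate the untreated control sample
#'
#' The control undergoes the same immunodepletion and sequencing as a
#' selection but sees no enzyme, so only tag-escape background survives.
#'
#' @inheritParams simulate_selection
#' @return A [hexamer_set()] with `sample_label = "control"`.
#' @export
simulate_control <- function(naive, landscape, config) {
  config$enzyme_conc <- 0
  simulate_selection(naive, landscape, config, protease_label = "")
}

#' Emit a synthetic kinetics validation table
#'
#' Per-hexamer measured constant: the context-factored landscape rate with
#' multiplicative log-normal measurement noise, censored at the assay
#' ceiling (phage-based K_obs saturates by experimental design). The
#' cleavage index marks the P1' of the best candidate tetramer.
#'
#' @param landscape A [make_landscape()] object.
#' @param hexamers Character vector of hexamer peptides to "measure".
#' @param noise_sd SD of the log-normal measurement noise.
#' @param ceiling Censoring ceiling, M^-1 s^-1 (default 12,792).
#' @param seed Integer seed.
#' @return `data.frame` with columns `peptide`, `cleavage_index`,
#'   `constant`, `true_rate`.
#' @export
emit_kinetics_table <- function(landscape, hexamers, noise_sd = 0.3,
                                ceiling = 12792, seed = 1L) {
  stopifnot(inherits(landscape, "specificity_landscape"), ceiling > 0,
            all(nchar(hexamers) == 6L))
  set.seed(seed)
  m <- vapply(0:2, function(off) {
    unname(landscape[substring(hexamers, off + 1L, off + 4L)])
  }, numeric(length(hexamers)))
  m <- matrix(m, ncol = 3L)
  best <- max.col(m, ties.method = "first")
  true_rate <- m[cbind(seq_along(hexamers), best)]
  context_sd <- attr(landscape, "context_sd")
  total_sd <- sqrt(context_sd^2 + noise_sd^2)
  noise <- if (total_sd > 0) {
    exp(stats::rnorm(length(hexamers), sd = total_sd))
  } else {
    1
  }
  constant <- pmin(true_rate * noise, ceiling)
  data.frame(peptide = hexamers,
             cleavage_index = best - 1L + 4L,
             constant = constant,
             true_rate = true_rate)
}

#' Plant cleavage sites in a synthetic proteome
#'
#' Generates random protein sequences and embeds chosen tetramers at
#' recorded positions: half the sites are drawn rate-weighted from the
#' landscape (hot sites), half uniformly from all tetramers. Isotopic
#' enrichment is sampled high for sites at or above the hot-rate cut and
#' near zero otherwise, in two replicate channels.
#'
#' @param landscape A [make_landscape()] object.
#' @param n_proteins,protein_length Proteome size.
#' @param n_sites Number of planted sites (>= 1).
#' @param seed Integer seed.
#' @param hot_quantile Quantile of the positive landscape rates above which
#'   a site counts as hot (default 0.9).
#' @param ie_high Mean log2 enrichment of hot sites (default 3).
#' @param ie_sd Replicate noise SD on the log2 scale (default 0.5).
#' @return List with `proteome` (named character vector) and `sites`
#'   (`data.frame`: `protein_id`, `p1prime_index`, `tetramer`, `true_rate`,
#'   `hot`, `ie_rep1`, `ie_rep2`).
#' @export
plant_cleavage_sites <- function(landscape, n_proteins = 30L,
                                 protein_length = 300L, n_sites = 60L,
                                 seed = 1L, hot_quantile = 0.9,
                                 ie_high = 3, ie_sd = 0.5) {
  stopifnot(inherits(landscape, "specificity_landscape"), n_sites >= 1)
  set.seed(seed)
  aa <- aa_alphabet()
  proteome <- vapply(seq_len(n_proteins), function(i) {
    paste0(sample(aa, protein_length, replace = TRUE), collapse = "")
  }, character(1L))
  names(proteome) <- sprintf("SYNPROT%03d", seq_len(n_proteins))

  tets <- names(landscape)
  pos_rates <- landscape[landscape > 0]
  if (length(pos_rates) == 0L) stop("landscape has no positive rates")
  hot_cut <- stats::quantile(pos_rates, hot_quantile)
  n_hot <- ceiling(n_sites / 2)
  hot_pool <- names(pos_rates)
  site_tet <- c(sample(hot_pool, n_hot, replace = TRUE,
                       prob = as.numeric(pos_rates)),
                sample(tets, n_sites - n_hot, replace = TRUE))
  prot <- sample(names(proteome), n_sites, replace = TRUE)
  p1i <- sample(5:(protein_length - 4L), n_sites, replace = TRUE)
  for (i in seq_len(n_sites)) {
    s <- proteome[[prot[i]]]
    substr(s, p1i[i] - 3L, p1i[i]) <- site_tet[i]
    proteome[[prot[i]]] <- s
  }
  # re-read the planted tetramer: a later site may overwrite an earlier one
  site_tet <- vapply(seq_len(n_sites), function(i) {
    substr(proteome[[prot[i]]], p1i[i] - 3L, p1i[i])
  }, character(1L))
  true_rate <- unname(landscape[site_tet])
  hot <- true_rate >= hot_cut
  mu <- ifelse(hot, ie_high, 0)
  sites <- data.frame(protein_id = prot,
                      p1prime_index = p1i,
                      tetramer = site_tet,
                      true_rate = true_rate,
                      hot = hot,
                      ie_rep1 = stats::rnorm(n_sites, mu, ie_sd),
                      ie_rep2 = stats::rnorm(n_sites, mu, ie_sd))
  list(proteome = proteome, sites = sites)
}

#' Write synthetic amplicon reads as FASTQ
#'
#' Reverse-translates `left_flank + hexamer + right_flank` for every read of
#' every hexamer (deterministic codons), pads with constant DNA, and writes
#' 4-line FASTQ records with uniform qualities. Intended for small
#' demonstration sets exercising the extraction path.
#'
#' @param set A [hexamer_set()].
#' @param spec A [flank_spec()].
#' @param path Output FASTQ path.
#' @param prefix_dna,suffix_dna Constant pads around the coding region.
#' @param max_reads Cap on emitted reads (hexamers are emitted in descending
#'   count order until the cap).
#' @export
write_amplicon_fastq <- function(set, spec, path,
                                 prefix_dna = "ACGGCT",
                                 suffix_dna = "GGTACG",
                                 max_reads = 1e5) {
  stopifnot(inherits(set, "hexamer_set"), inherits(spec, "flank_spec"))
  ord <- order(-set$counts, names(set$counts), method = "radix")
  counts <- round(set$counts[ord])
  counts <- counts[cumsum(counts) <= max_reads]
  if (length(counts) == 0L) stop("max_reads too small for even one hexamer")
  coding <- reverse_translate(paste0(spec$left_flank, names(counts),
                                     spec$right_flank))
  dna <- paste0(prefix_dna, coding, suffix_dna)
  reads <- rep(dna, counts)
  qual <- vapply(nchar(reads), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1L))
  lines <- as.vector(rbind(paste0("@read", seq_along(reads)),
                           reads, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write a proteome FASTA
#'
#' @param proteome Named character vector of protein sequences.
#' @param path Output FASTA path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(proteome), path)
  invisible(path)
}
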