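# cleavage_annotation: project P3-P1' tetramers onto cleavage sites in
# proteins (N-terminomics neo-N-termini or P4-P4' octamer records), classify
# sites against a selectome, apply isotopic-enrichment statistics, and
# compute cross-protease selectivity correlations.

#' Project the P3-P1' tetramer of a cleavage site
#'
#' Given the 1-based index of the P1' residue (the first residue after the
#' scissile bond) on a protein sequence, returns residues
#' `p1prime_index - 3 .. p1prime_index`, i.e. P3-P2-P1-P1'. Sites too close
#' to the N-terminus (index < 4) or beyond the sequence cannot be projected
#' and yield `NA`.
#'
#' @param protein_sequence Protein sequence (character scalar).
#' @param p1prime_index 1-based P1' residue index (vectorized).
#' @return Character vector of 4-mers (`NA` where unprojectable).
#' @export
project_tetramer <- function(protein_sequence, p1prime_index) {
  stopifnot(length(protein_sequence) == 1L, is.character(protein_sequence))
  len <- nchar(protein_sequence)
  ok <- !is.na(p1prime_index) & p1prime_index >= 4L & p1prime_index <= len
  out <- rep(NA_character_, length(p1prime_index))
  out[ok] <- substr(rep(protein_sequence, sum(ok)),
                    p1prime_index[ok] - 3L, p1prime_index[ok])
  out
}

#' Extract the P3-P1' tetramer from a P4-P4' octamer
#'
#' Database cleavage records report the eight residues flanking the scissile
#' bond (P4..P4'); the P3-P1' tetramer is characters 2-5. Records of the
#' wrong length or with non-standard residues yield `NA` (to be skipped and
#' counted by the caller).
#'
#' @param octamer Character vector of 8-mers.
#' @return Character vector of 4-mers (`NA` for invalid records).
#' @export
parse_octamer <- function(octamer) {
  ok <- !is.na(octamer) & nchar(octamer) == 8L & is_standard_peptide(octamer)
  ifelse(ok, substr(octamer, 2L, 5L), NA_character_)
}

#' Isotopic-enrichment population statistics
#'
#' N-terminomics reports the log2 reporter-ion ratio (treated over control)
#' of each labeled N-terminus; sites are judged by their distance from the
#' population mean in units of the population standard deviation. Replicate
#' channels are averaged on the log2 scale before statistics; the standard
#' deviation uses the n-1 (sample) denominator.
#'
#' @param ie Numeric vector of log2 enrichment values, or a matrix with one
#'   replicate per column (rows are sites).
#' @return List with `mean`, `sd`, and `z` (per-site standardized
#'   enrichment, same order as the input rows).
#' @export
enrichment_stats <- function(ie) {
  if (is.matrix(ie) || is.data.frame(ie)) ie <- rowMeans(as.matrix(ie))
  ie <- as.numeric(ie)
  if (length(ie) < 2L || anyNA(ie) || any(!is.finite(ie))) {
    stop("need >= 2 sites with finite enrichment values")
  }
  m <- mean(ie)
  s <- stats::sd(ie)
  if (s == 0) stop("zero enrichment dispersion: z undefined")
  list(mean = m, sd = s, z = (ie - m) / s)
}

#' Classify cleavage sites against a selectome
#'
#' Each projected site falls into one of three categories: `selectome`
#' (RP strictly above the threshold), `sub_threshold` (0 < RP <= threshold:
#' a recognized but poor P3-P1' sequence), or `absent` (RP = 0: not found in
#' the phage-display substrate set at all). Category fractions are reported
#' over projectable sites.
#'
#' @param sites `data.frame` with a `tetramer` column (`NA` =
#'   unprojectable).
#' @param rp An `rp_table`.
#' @param rp_threshold Selectome threshold RP.
#' @return List with `sites` (input plus `rp`, `rank`, `category`) and
#'   `fractions` (named proportions over projectable sites).
#' @export
classify_sites <- function(sites, rp, rp_threshold) {
  stopifnot(is.data.frame(sites), "tetramer" %in% names(sites))
  i <- match(sites$tetramer, rp$tetramer)
  rp_val <- rp$rp[i]
  rp_val[is.na(rp_val)] <- 0
  rp_val[is.na(sites$tetramer)] <- NA_real_
  rank_val <- rp$rank[i]
  thr <- if (is.na(rp_threshold)) Inf else rp_threshold
  category <- rep(NA_character_, nrow(sites))
  proj <- !is.na(rp_val)
  category[proj & rp_val > thr] <- "selectome"
  category[proj & rp_val > 0 & rp_val <= thr] <- "sub_threshold"
  category[proj & rp_val == 0] <- "absent"
  out <- sites
  out$rp <- rp_val
  out$rank <- rank_val
  out$category <- category
  lev <- c("selectome", "sub_threshold", "absent")
  fr <- table(factor(category[proj], levels = lev)) / max(sum(proj), 1L)
  list(sites = out, fractions = as.numeric(fr) |> stats::setNames(lev))
}

#' Map neo-N-terminal peptides onto a proteome
#'
#' An N-terminally labeled peptide starts at the P1' residue of its cleavage
#' site, so its first match inside the parent protein gives the
#' `p1prime_index` directly. Exact substring matching; when a peptide
#' matches more than once, the first position is used and a warning is
#' raised.
#'
#' @param proteome Named character vector or `AAStringSet` of protein
#'   sequences.
#' @param protein_id Protein identifier per peptide.
#' @param peptide Peptide sequences.
#' @return Integer vector of 1-based P1' indices (`NA` when no match).
#' @export
locate_peptides <- function(proteome, protein_id, peptide) {
  if (methods::is(proteome, "AAStringSet")) {
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  }
  n_multi <- 0L
  out <- mapply(function(id, pep) {
    seqs <- proteome[[id]]
    if (is.null(seqs)) return(NA_integer_)
    hits <- gregexpr(pep, seqs, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(NA_integer_)
    if (length(hits) > 1L) n_multi <<- n_multi + 1L
    as.integer(hits[1L])
  }, protein_id, peptide, USE.NAMES = FALSE)
  if (n_multi > 0L) {
    warning(sprintf("%d peptides matched more than once; first match used",
                    n_multi))
  }
  out
}

#' Annotate cleavage sites end to end
#'
#' Accepts sites specified by P4-P4' octamer, by (protein, P1' index), or by
#' neo-N-terminal peptide (mapped by exact substring match), projects the
#' P3-P1' tetramer, classifies each site against the selectome, and — when
#' isotopic-enrichment columns are present — standardizes enrichment against
#' the population.
#'
#' @param sites `data.frame` with either an `octamer` column, or
#'   `protein_id` + `p1prime_index` columns, or `protein_id` + `peptide`
#'   columns; optional enrichment columns named `ie*` (replicates averaged
#'   on the log2 scale).
#' @param rp An `rp_table`.
#' @param rp_threshold Selectome threshold.
#' @param proteome Named character vector or `AAStringSet` (required unless
#'   sites carry octamers).
#' @return List with `sites` (annotated `data.frame`: `tetramer`, `rp`,
#'   `rank`, `category`, and `ie_log2` + `z` when enrichment was given),
#'   `fractions`, `n_unprojectable`, and `enrichment` (population stats or
#'   `NULL`).
#' @export
annotate_sites <- function(sites, rp, rp_threshold, proteome = NULL) {
  stopifnot(is.data.frame(sites), nrow(sites) > 0L)
  if (!is.null(sites$octamer)) {
    sites$tetramer <- parse_octamer(sites$octamer)
  } else {
    if (is.null(proteome)) stop("a proteome is required without octamers")
    if (methods::is(proteome, "AAStringSet")) {
      proteome <- stats::setNames(as.character(proteome), names(proteome))
    }
    if (is.null(sites$p1prime_index) && !is.null(sites$peptide)) {
      sites$p1prime_index <- locate_peptides(proteome, sites$protein_id,
                                             sites$peptide)
    }
    stopifnot(!is.null(sites$protein_id), !is.null(sites$p1prime_index))
    sites$tetramer <- vapply(seq_len(nrow(sites)), function(i) {
      seqs <- proteome[[sites$protein_id[i]]]
      if (is.null(seqs)) return(NA_character_)
      project_tetramer(seqs, sites$p1prime_index[i])
    }, character(1L))
  }
  ie_cols <- grep("^ie", names(sites), value = TRUE)
  enr <- NULL
  if (length(ie_cols) > 0L) {
    ie <- rowMeans(as.matrix(sites[, ie_cols, drop = FALSE]))
    enr <- enrichment_stats(ie)
    sites$ie_log2 <- ie
    sites$z <- enr$z
  }
  cls <- classify_sites(sites, rp, rp_threshold)
  list(sites = cls$sites,
       fractions = cls$fractions,
       n_unprojectable = sum(is.na(cls$sites$tetramer)),
       enrichment = enr[c("mean", "sd")])
}

#' Cross-protease selectivity correlation
#'
#' Within a group of cleavage sites (shared between two proteases or unique
#' to one, by the isotopic-enrichment criterion `z > 1` or by RP), regresses
#' the scaled fitness RP/RP_max under protease B on that under protease A.
#' Shared substrates track the identity line (slope near 1); substrates
#' unique to one enzyme collapse toward slope 0.
#'
#' @param rp_a,rp_b RP values of the sites under proteases A and B.
#' @param rp_max_a,rp_max_b Scaling maxima (default: observed maxima).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
selectivity_correlation <- function(rp_a, rp_b,
                                    rp_max_a = max(rp_a),
                                    rp_max_b = max(rp_b)) {
  stopifnot(length(rp_a) == length(rp_b))
  if (length(rp_a) < 3L) stop("group of size < 3")
  if (rp_max_a <= 0 || rp_max_b <= 0) stop("RP_max must be > 0")
  x <- rp_a / rp_max_a
  y <- rp_b / rp_max_b
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n = length(x))
}

#' Group sites by dual-protease enrichment
#'
#' Uses the strict `z > cut` convention for calling a site a substrate of
#' each enzyme.
#'
#' @param z_a,z_b Standardized enrichment under proteases A and B.
#' @param cut Positivity cut in standard deviations (default 1).
#' @return Factor with levels `shared`, `unique_a`, `unique_b`, `neither`.
#' @export
group_sites_by_ie <- function(z_a, z_b, cut = 1) {
  stopifnot(length(z_a) == length(z_b))
  a <- z_a > cut
  b <- z_b > cut
  out <- rep("neither", length(z_a))
  out[a & b] <- "shared"
  out[a & !b] <- "unique_a"
  out[!a & b] <- "unique_b"
  factor(out, levels = c("shared", "unique_a", "unique_b", "neither"))
}
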