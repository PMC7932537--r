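# profiles: align cluster members on the P5-P3' window, build positional
# frequency matrices / information content, and stratify substrates into
# RP/RP_max decile groups.

window_positions <- function() {
  c("P5", "P4", "P3", "P2", "P1", "P1'", "P2'", "P3'")
}

#' Align cluster members on the P5-P3' window
#'
#' Hexamers in a tetramer cluster share the P3-P1' core but carry it at
#' different offsets, so the six residues of each member occupy different
#' stretches of the eight-position P5-P3' window: offset 0 maps to P3..P3',
#' offset 1 to P4..P2', offset 2 to P5..P1'. Positions a member does not
#' reach are `NA`.
#'
#' @param x A `cluster_table` (with `tetramer` naming the cluster) or a
#'   `data.frame` of members with columns `hexamer`, `offset`.
#' @param tetramer Cluster to align when `x` is a `cluster_table`; also used
#'   to check offset consistency when supplied.
#' @return Character matrix, one row per member, 8 columns P5..P3'.
#' @export
align_members <- function(x, tetramer = NULL) {
  if (inherits(x, "cluster_table")) {
    stopifnot(!is.null(tetramer))
    m <- cluster_members(x, tetramer)
  } else {
    m <- x
    stopifnot(is.data.frame(m), all(c("hexamer", "offset") %in% names(m)))
  }
  if (!is.null(tetramer)) {
    at <- substring(m$hexamer, m$offset + 1L, m$offset + 4L)
    if (any(at != tetramer)) {
      stop("inconsistent offset: member does not carry the tetramer at its stated offset")
    }
  }
  if (!all(m$offset %in% 0:2)) stop("offsets must be 0, 1 or 2")
  w <- matrix(NA_character_, nrow = nrow(m), ncol = 8L,
              dimnames = list(m$hexamer, window_positions()))
  for (off in 0:2) {
    idx <- which(m$offset == off)
    if (length(idx) == 0L) next
    start_col <- 3L - off
    for (p in 1:6) {
      w[idx, start_col + p - 1L] <- substr(m$hexamer[idx], p, p)
    }
  }
  w
}

#' Positional frequency matrix from aligned windows
#'
#' Counts each distinct hexamer once (read counts are not weights), per
#' position and residue. Frequencies are normalized by that position's
#' coverage (the number of members that occupy it), and per-position
#' information content is `log2(20) - H(position)` in bits.
#'
#' @param windows Character matrix from [align_members()] (rows may come
#'   from several clusters; `rbind` them first).
#' @return A `pfm` object: list with `counts` (20 x 8), `freq` (20 x 8,
#'   `NA` columns where coverage is 0), `coverage` (length 8),
#'   `info` (length 8, bits, `NA` where coverage is 0).
#' @export
build_pfm <- function(windows) {
  stopifnot(is.matrix(windows), ncol(windows) == 8L, nrow(windows) > 0L)
  aa <- aa_alphabet()
  counts <- vapply(seq_len(8L), function(j) {
    tabulate(factor(windows[, j], levels = aa), nbins = 20L)
  }, integer(20L))
  dimnames(counts) <- list(aa, window_positions())
  coverage <- colSums(counts)
  freq <- sweep(counts, 2L, coverage, "/")
  freq[, coverage == 0L] <- NA_real_
  info <- vapply(seq_len(8L), function(j) {
    if (coverage[j] == 0L) return(NA_real_)
    f <- freq[, j]
    f <- f[f > 0]
    log2(20) + sum(f * log2(f))
  }, numeric(1L))
  names(info) <- window_positions()
  structure(list(counts = counts, freq = freq,
                 coverage = coverage, info = info),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm: positional frequency matrix, coverage per position:\n")
  print(x$coverage)
  cat("information content (bits):\n")
  print(round(x$info, 3))
  invisible(x)
}

#' Aggregate profile of a set of clusters
#'
#' Aligns the members of every listed cluster on the P5-P3' window and
#' builds one pooled frequency matrix — the aggregate specificity profile
#' of, e.g., a selectome.
#'
#' @param ct A `cluster_table`.
#' @param tetramers Character vector of clusters to pool.
#' @return A `pfm`.
#' @export
selectome_pfm <- function(ct, tetramers) {
  stopifnot(inherits(ct, "cluster_table"), length(tetramers) > 0L)
  a <- ct$assignments[ct$assignments$tetramer %in% tetramers, , drop = FALSE]
  if (nrow(a) == 0L) stop("none of the requested clusters are in the table")
  build_pfm(align_members(a[, c("hexamer", "offset")]))
}

#' RP/RP_max decile groups
#'
#' Stratifies clusters into 10 groups by their RP relative to the maximum:
#' group k holds clusters with RP/RP_max in ((k-1)/10, k/10] (right-closed
#' bins; an exact 0 joins group 1). Substrate composition changes across
#' these fitness strata, which is what the per-group profiles reveal.
#'
#' @param rp Named numeric vector of RP values (names are tetramers),
#'   typically the selectome clusters.
#' @param rp_max Maximum RP used for scaling; defaults to `max(rp)`.
#' @return Named integer vector of group indices 1..10.
#' @export
rp_decile_groups <- function(rp, rp_max = max(rp)) {
  if (length(rp) == 0L) stop("empty cluster set")
  if (rp_max <= 0) stop("RP_max must be > 0")
  ratio <- rp / rp_max
  if (any(ratio < 0 | ratio > 1)) stop("RP values must lie in [0, RP_max]")
  grp <- as.integer(ceiling(ratio * 10))
  grp[ratio == 0] <- 1L
  names(grp) <- names(rp)
  grp
}

#' Per-decile frequency profiles
#'
#' @param ct A `cluster_table` holding the clusters' members.
#' @param rp Named numeric RP vector over the clusters to stratify.
#' @param rp_max Maximum RP for scaling (defaults to `max(rp)`).
#' @return List of 10 `pfm` objects (`NULL` for empty groups), named
#'   `"1"`..`"10"` from lowest to highest RP/RP_max.
#' @export
decile_pfms <- function(ct, rp, rp_max = max(rp)) {
  grp <- rp_decile_groups(rp, rp_max)
  out <- vector("list", 10L)
  names(out) <- as.character(1:10)
  for (k in 1:10) {
    tets <- names(grp)[grp == k]
    if (length(tets) > 0L) out[[k]] <- selectome_pfm(ct, tets)
  }
  out
}

#' Write a frequency matrix to TSV
#'
#' Rows are the 20 residues, columns the window positions P5..P3'.
#'
#' @param pfm A `pfm`.
#' @param path Output path.
#' @param what `"freq"` (default) or `"counts"`.
#' @export
write_pfm_tsv <- function(pfm, path, what = c("freq", "counts")) {
  stopifnot(inherits(pfm, "pfm"))
  what <- match.arg(what)
  m <- pfm[[what]]
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
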