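# tetramer_clustering: group hexamers into P3-P1' tetramer clusters.
# Naive mode keeps multi-membership (no selective pressure to resolve);
# selection mode assigns each hexamer to a single cluster by eliminating
# redundancy from the least abundant clusters upward.

#' Candidate tetramers of a hexamer
#'
#' A hexamer contains a four-residue window at offsets 0, 1 and 2; each is a
#' candidate P3-P1' recognition motif. Duplicate tetramers (e.g. in
#' `"AAAAAA"`) are retained with their distinct offsets.
#'
#' @param hexamer A single 6-mer peptide (standard alphabet).
#' @return `data.frame` with columns `tetramer`, `offset` (0, 1, 2).
#' @export
candidate_tetramers <- function(hexamer) {
  if (length(hexamer) != 1L || !is_standard_peptide(hexamer) ||
      nchar(hexamer) != 6L) {
    stop("'hexamer' must be a single 6-mer over the standard alphabet")
  }
  data.frame(tetramer = substring(hexamer, 1:3, 4:6), offset = 0:2)
}

# Multi-membership assignment table for a vector of distinct hexamers.
# One row per (hexamer, distinct tetramer); when a tetramer occurs at more
# than one offset of the same hexamer, the smallest offset is kept.
tetramer_assignments <- function(hexamers) {
  n <- length(hexamers)
  idx <- rep(seq_len(n), each = 3L)
  off <- rep(0:2, times = n)
  tet <- substring(hexamers[idx], off + 1L, off + 4L)
  dup <- duplicated(paste0(idx, ".", tet))
  data.frame(hexamer = hexamers[idx][!dup],
             tetramer = tet[!dup],
             offset = off[!dup])
}

new_cluster_table <- function(assignments, mode) {
  tab <- table(assignments$tetramer)
  sizes <- as.integer(tab)
  names(sizes) <- names(tab)
  structure(
    list(assignments = assignments,
         sizes = sizes,
         mode = mode,
         n_hexamers = length(unique(assignments$hexamer)),
         total_assignments = nrow(assignments)),
    class = "cluster_table"
  )
}

as_hexamer_vector <- function(x) {
  if (inherits(x, "hexamer_set")) return(names(x$counts))
  stopifnot(is.character(x), length(x) > 0L)
  x
}

#' Cluster hexamers without redundancy elimination (naive mode)
#'
#' Every distinct hexamer is inserted into all of its candidate tetramer
#' clusters (up to 3; once per distinct tetramer). This is the appropriate
#' treatment for the naive library, where no selective pressure singles out
#' one tetramer per hexamer.
#'
#' @param x A [hexamer_set()] or character vector of distinct hexamers.
#' @return A `cluster_table` with `mode = "naive"`: assignment table
#'   (`hexamer`, `tetramer`, `offset`), per-cluster sizes (distinct-hexamer
#'   counts, the n_t of the probability model) and the total number of
#'   assignments (the probability denominator).
#' @export
cluster_naive <- function(x) {
  hex <- as_hexamer_vector(x)
  new_cluster_table(tetramer_assignments(hex), mode = "naive")
}

#' Cluster hexamers with redundancy elimination (selection mode)
#'
#' Each selected hexamer is assigned to the single most abundant tetramer
#' cluster it can be found in, so that co-occurring windows and positions
#' outside the true P3-P1' motif do not inflate other clusters. The
#' procedure: (1) build the multi-membership table and record each cluster's
#' initial distinct-hexamer count; (2) visit clusters in ascending order of
#' that initial count (ties broken lexicographically) and remove each still
#' multiply-assigned hexamer from the visited cluster unless it is the
#' hexamer's most abundant candidate (a hexamer's own ties broken by
#' smallest offset, then lexicographic tetramer); (3) drop empty clusters.
#' The result is a partition of the distinct hexamers. Abundance is the
#' static initial count throughout; read counts are metadata only.
#'
#' @param x A [hexamer_set()] or character vector of distinct hexamers.
#' @return A `cluster_table` with `mode = "selection"`; every distinct
#'   hexamer appears in exactly one cluster.
#' @export
cluster_selection <- function(x) {
  hex <- as_hexamer_vector(x)
  a <- tetramer_assignments(hex)
  n0 <- unname(table(a$tetramer)[a$tetramer])
  # The staged elimination keeps, for every hexamer, exactly its maximally
  # abundant candidate (static counts): clusters are visited from least
  # abundant upward and a hexamer is only removed while another, larger
  # candidate still holds it, so the best candidate can never be removed.
  ord <- order(a$hexamer, -as.integer(n0), a$offset, a$tetramer,
               method = "radix")
  keep <- !duplicated(a$hexamer[ord])
  b <- a[ord, , drop = FALSE][keep, , drop = FALSE]
  rownames(b) <- NULL
  new_cluster_table(b, mode = "selection")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("cluster_table [%s]: %d clusters, %d hexamers, %d assignments\n",
              x$mode, length(x$sizes), x$n_hexamers, x$total_assignments))
  invisible(x)
}

#' Members of one tetramer cluster
#'
#' @param ct A `cluster_table`.
#' @param tetramer A 4-mer present in the table.
#' @return `data.frame` with columns `hexamer`, `offset`.
#' @export
cluster_members <- function(ct, tetramer) {
  stopifnot(inherits(ct, "cluster_table"))
  m <- ct$assignments[ct$assignments$tetramer == tetramer,
                      c("hexamer", "offset")]
  if (nrow(m) == 0L) stop(sprintf("no cluster '%s' in table", tetramer))
  rownames(m) <- NULL
  m
}

#' Number of distinct hexamers that can contain a tetramer
#'
#' The capacity of a tetramer cluster: how many distinct hexamers contain
#' the tetramer at one or more of the three offsets. For a tetramer with no
#' self-overlap this is 3 x 20^2 = 1,200; self-overlapping tetramers
#' (e.g. `"AAAA"`) have a smaller capacity because some placements coincide.
#' Computed by inclusion-exclusion over the three placement sets.
#'
#' @param tetramer A 4-mer peptide.
#' @return Integer count (<= 1,200).
#' @export
max_hexamers_containing <- function(tetramer) {
  if (length(tetramer) != 1L || !is_standard_peptide(tetramer) ||
      nchar(tetramer) != 4L) {
    stop("'tetramer' must be a single 4-mer over the standard alphabet")
  }
  # shift-by-1 overlap (offsets 0&1 and 1&2): t[1..3] == t[2..4];
  # shift-by-2 overlap (offsets 0&2): t[1..2] == t[3..4].
  ov1 <- substr(tetramer, 1L, 3L) == substr(tetramer, 2L, 4L)
  ov2 <- substr(tetramer, 1L, 2L) == substr(tetramer, 3L, 4L)
  singles <- 3L * 400L
  pairs <- (if (ov1) 2L * 20L else 0L) + (if (ov2) 1L else 0L)
  # t at all three offsets forces all four residues equal (shift-1 overlap),
  # leaving the single all-identical hexamer.
  triple <- if (ov1) 1L else 0L
  singles - pairs + triple
}

#' Write a cluster table to TSV
#'
#' One row per cluster: `tetramer`, `n_hexamers`, `members`
#' (semicolon-joined `hexamer:offset`).
#'
#' @param ct A `cluster_table`.
#' @param path Output path.
#' @export
write_cluster_tsv <- function(ct, path) {
  stopifnot(inherits(ct, "cluster_table"))
  a <- ct$assignments
  member_str <- paste0(a$hexamer, ":", a$offset)
  members <- tapply(member_str, a$tetramer, paste, collapse = ";")
  tet <- names(members)
  df <- data.frame(tetramer = tet,
                   n_hexamers = as.integer(ct$sizes[tet]),
                   members = unname(members))
  df <- df[order(-df$n_hexamers, df$tetramer, method = "radix"), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample clustering summary
#'
#' Mirrors the bookkeeping reported for each sequenced sample: distinct
#' hexamers, occupied tetramer clusters, total cluster assignments.
#'
#' @param ct A `cluster_table`.
#' @return One-row `data.frame`.
#' @export
cluster_summary <- function(ct) {
  stopifnot(inherits(ct, "cluster_table"))
  data.frame(mode = ct$mode,
             n_hexamers = ct$n_hexamers,
             n_clusters = length(ct$sizes),
             total_assignments = ct$total_assignments,
             max_cluster_size = max(ct$sizes))
}
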