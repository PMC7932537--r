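# Independent oracles used to freeze expected values: deliberately naive
# implementations, kept separate from the package's code paths.

# Random hexamers over the standard alphabet.
random_hexamers <- function(n, seed) {
  set.seed(seed)
  replicate(n, paste0(sample(aa_alphabet(), 6L, replace = TRUE),
                      collapse = ""))
}

# Enumerate every distinct hexamer containing `tetramer` at >= 1 offset, by
# explicit construction of the three placement sets.
enumerate_hexamers_containing <- function(tetramer) {
  aa <- aa_alphabet()
  pairs <- as.matrix(expand.grid(aa, aa, stringsAsFactors = FALSE))
  unique(c(paste0(tetramer, pairs[, 1L], pairs[, 2L]),
           paste0(pairs[, 1L], tetramer, pairs[, 2L]),
           paste0(pairs[, 1L], pairs[, 2L], tetramer)))
}

# Literal staged greedy redundancy elimination, as an independent oracle for
# cluster_selection(): build the multi-membership table, then visit clusters
# in ascending order of their initial size (ties lexicographic) and delete
# each still multiply-assigned hexamer from the visited cluster unless the
# visited cluster is that hexamer's maximally abundant candidate (hexamer
# ties: smallest offset, then lexicographic tetramer). O(n^2)-ish; use on
# small sets only.
brute_force_selection_clustering <- function(hexamers) {
  cand <- lapply(hexamers, function(h) {
    tet <- substring(h, 1:3, 4:6)
    keep <- !duplicated(tet)
    data.frame(hexamer = h, tetramer = tet[keep], offset = (0:2)[keep])
  })
  a <- do.call(rbind, cand)
  initial <- table(a$tetramer)
  best_for <- function(h) {
    rows <- a[a$hexamer == h, ]
    n0 <- as.integer(initial[rows$tetramer])
    rows <- rows[order(-n0, rows$offset, rows$tetramer), ]
    rows$tetramer[1L]
  }
  best <- vapply(hexamers, best_for, character(1L))
  names(best) <- hexamers

  alive <- rep(TRUE, nrow(a))
  visit <- names(sort(initial))  # ascending size; ties lexicographic (names sorted)
  visit <- visit[order(as.integer(initial[visit]))]
  for (tet in visit) {
    rows <- which(alive & a$tetramer == tet)
    for (r in rows) {
      h <- a$hexamer[r]
      still <- sum(alive & a$hexamer == h)
      if (still > 1L && best[[h]] != tet) alive[r] <- FALSE
    }
  }
  out <- a[alive, ]
  # partition check: exactly one assignment per hexamer must remain
  stopifnot(!anyDuplicated(out$hexamer), nrow(out) == length(hexamers))
  split(out$hexamer, out$tetramer)
}
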