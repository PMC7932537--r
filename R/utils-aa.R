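# Shared amino-acid alphabet helpers. All counting in this package is over
# the 20 standard residues; '*' (stop) and 'X' (ambiguous) never enter a
# hexamer set.

.pkg_cache <- new.env(parent = emptyenv())

#' The 20 standard amino-acid one-letter codes
#'
#' @return Character vector of length 20, alphabetical.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Test peptides for the standard 20-letter alphabet
#'
#' @param x Character vector of peptide sequences.
#' @return Logical vector: `TRUE` where `x` is non-empty and contains only
#'   the 20 standard residues (no stop `*`, no `X`, no gaps).
#' @export
is_standard_peptide <- function(x) {
  !is.na(x) & nchar(x) > 0L &
    !grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), x)
}

#' All 160,000 tetramer sequences
#'
#' The P3-P1' recognition space of a protease reading a four-residue motif:
#' 20^4 = 160,000 tetramers. Computed once and cached.
#'
#' @return Character vector of length 160,000, lexicographically sorted.
#' @export
all_tetramers <- function() {
  if (is.null(.pkg_cache$tetramers)) {
    aa <- aa_alphabet()
    g <- expand.grid(aa, aa, aa, aa, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    # expand.grid varies the first factor fastest; reverse for lexicographic
    .pkg_cache$tetramers <- paste0(g[[4L]], g[[3L]], g[[2L]], g[[1L]])
  }
  .pkg_cache$tetramers
}

# Map 1-based indices in 1..20^k to k-mer peptides (base-20 digits).
index_to_kmer <- function(idx, k) {
  aa <- aa_alphabet()
  i <- as.double(idx) - 1
  out <- rep("", length(i))
  for (p in seq_len(k)) {
    out <- paste0(aa[i %% 20 + 1], out)
    i <- i %/% 20
  }
  out
}

codon_map <- function() {
  if (is.null(.pkg_cache$codon_map)) {
    gc <- Biostrings::GENETIC_CODE
    first <- tapply(names(gc), gc, function(v) sort(v)[1L])
    .pkg_cache$codon_map <- first
  }
  .pkg_cache$codon_map
}

#' Reverse-translate peptides to DNA
#'
#' Uses one fixed codon per residue (the alphabetically first codon of the
#' standard genetic code), so the mapping is deterministic and
#' `translate(reverse_translate(p)) == p`. Used to construct synthetic
#' amplicon reads.
#'
#' @param peptides Character vector of peptide sequences (standard alphabet).
#' @return Character vector of DNA sequences, 3x the peptide length.
#' @export
reverse_translate <- function(peptides) {
  stopifnot(all(is_standard_peptide(peptides)))
  map <- codon_map()
  vapply(strsplit(peptides, ""), function(ch) {
    paste0(map[ch], collapse = "")
  }, character(1L))
}
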