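# amplicon_extract: raw amplicon reads -> clean hexamer count sets.
# Six-frame translation, flank-anchored variable-region extraction, and
# control subtraction (subtract_control lives with the hexamer_set class).

#' Flank specification for insert extraction
#'
#' The variable region of the displayed peptide sits between two constant
#' amino-acid tags. An insert is accepted only when it lies strictly between
#' the left and right flank in a translated frame, has exactly
#' `insert_length` residues and contains no stop or ambiguous symbols.
#' The flank sequences are mandatory configuration: they are a property of
#' the display vector, not of this method, so no universal default can be
#' assumed — the defaults here are the ones used by the package's own
#' synthetic read generator.
#'
#' @param left_flank,right_flank Constant amino-acid tags (>= 3 residues,
#'   standard alphabet) immediately before/after the insert.
#' @param insert_length Length of the randomized insert (default 6).
#' @return An object of class `flank_spec`.
#' @export
flank_spec <- function(left_flank = "DLA", right_flank = "GAE",
                       insert_length = 6L) {
  if (!is_standard_peptide(left_flank) || nchar(left_flank) < 3L ||
      !is_standard_peptide(right_flank) || nchar(right_flank) < 3L) {
    stop("flanks must be peptides of >= 3 standard residues")
  }
  insert_length <- as.integer(insert_length)
  if (is.na(insert_length) || insert_length < 1L) {
    stop("insert_length must be >= 1")
  }
  structure(list(left_flank = left_flank, right_flank = right_flank,
                 insert_length = insert_length),
            class = "flank_spec")
}

#' Translate a DNA sequence in all six frames
#'
#' Forward frames 0, 1, 2 then reverse-complement frames 0, 1, 2, translated
#' with the standard genetic code. Trailing partial codons are dropped, stop
#' codons are rendered `*`, and any codon containing an ambiguity symbol
#' (e.g. N) is rendered `X`.
#'
#' @param dna A DNA string (A/C/G/T/N), at least 3 nt.
#' @return Named character vector of 6 peptides
#'   (`F0`, `F1`, `F2`, `R0`, `R1`, `R2`).
#' @export
translate_six_frames <- function(dna) {
  if (length(dna) != 1L || is.na(dna) || nchar(dna) < 3L) {
    stop("'dna' must be a single sequence of at least 3 nt")
  }
  d <- Biostrings::DNAString(dna)
  rc <- Biostrings::reverseComplement(d)
  tr1 <- function(s, off) {
    w <- ((length(s) - off) %/% 3L) * 3L
    if (w < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1L, width = w),
      if.fuzzy.codon = "X"))
  }
  c(F0 = tr1(d, 0L), F1 = tr1(d, 1L), F2 = tr1(d, 2L),
    R0 = tr1(rc, 0L), R1 = tr1(rc, 1L), R2 = tr1(rc, 2L))
}

# Vectorized frame translation over a DNAStringSet (width >= 3 assumed).
# Returns a list of 6 character vectors in frame order F0,F1,F2,R0,R1,R2.
translate_frames_batch <- function(dss) {
  rc <- Biostrings::reverseComplement(dss)
  one <- function(x, off) {
    w <- pmax(((Biostrings::width(x) - off) %/% 3L) * 3L, 0L)
    as.character(Biostrings::translate(
      Biostrings::subseq(x, start = off + 1L, width = w),
      if.fuzzy.codon = "X"))
  }
  list(F0 = one(dss, 0L), F1 = one(dss, 1L), F2 = one(dss, 2L),
       R0 = one(rc, 0L), R1 = one(rc, 1L), R2 = one(rc, 2L))
}

#' Extract the variable insert from a translated frame
#'
#' Returns the substring strictly between the first occurrence of the left
#' flank and the next occurrence of the right flank, if and only if it has
#' exactly `spec$insert_length` residues and contains only the 20 standard
#' residues. Stops or X inside the insert disqualify the insert (not the
#' read's other frames). Non-matching frames yield `NA`.
#'
#' @param frame Peptide string(s) from [translate_six_frames()] (vectorized).
#' @param spec A [flank_spec()].
#' @return Character vector: the insert, or `NA` where no valid insert.
#' @export
extract_insert <- function(frame, spec) {
  stopifnot(inherits(spec, "flank_spec"))
  li <- regexpr(spec$left_flank, frame, fixed = TRUE)
  start <- as.integer(li) + nchar(spec$left_flank)
  rest <- substr(frame, start, nchar(frame))
  ri <- regexpr(spec$right_flank, rest, fixed = TRUE)
  ins <- substr(rest, 1L, as.integer(ri) - 1L)
  ok <- !is.na(frame) & li > 0L & ri > 0L &
    nchar(ins) == spec$insert_length & is_standard_peptide(ins)
  ifelse(ok, ins, NA_character_)
}

#' Build a hexamer set from amplicon reads
#'
#' Each read is translated in six frames and contributes at most one insert:
#' the first frame (forward 0, 1, 2 then reverse 0, 1, 2) that yields a
#' valid flank-anchored insert wins. Reads where more than one frame matched
#' are counted in the diagnostics (vanishingly rare on real amplicons).
#' Base qualities are not used.
#'
#' @param reads A `DNAStringSet`, or a character vector of DNA sequences
#'   (optionally named with read identifiers).
#' @param spec A [flank_spec()].
#' @param sample_label,protease_label Sample metadata, see [hexamer_set()].
#' @return A [hexamer_set()] with attribute `extraction_stats`: reads in,
#'   reads too short, reads without a valid insert, reads with multi-frame
#'   hits, distinct hexamers out.
#' @export
build_hexamer_set <- function(reads, spec,
                              sample_label = "selection",
                              protease_label = "") {
  stopifnot(inherits(spec, "flank_spec"))
  if (!methods::is(reads, "DNAStringSet")) {
    reads <- Biostrings::DNAStringSet(reads)
  }
  if (length(reads) == 0L) stop("read batch is empty")
  long_enough <- Biostrings::width(reads) >= 3L
  dss <- reads[long_enough]
  n_in <- length(reads)
  n_short <- sum(!long_enough)

  inserts <- rep(NA_character_, length(dss))
  n_hits <- integer(length(dss))
  if (length(dss) > 0L) {
    frames <- translate_frames_batch(dss)
    for (f in frames) {
      ins_f <- extract_insert(f, spec)
      hit <- !is.na(ins_f)
      n_hits <- n_hits + hit
      take <- is.na(inserts) & hit
      inserts[take] <- ins_f[take]
    }
  }
  extracted <- inserts[!is.na(inserts)]
  if (length(extracted) == 0L) {
    stop(sprintf(
      "no hexamer inserts extracted: check the flank specification (left '%s', right '%s', insert length %d)",
      spec$left_flank, spec$right_flank, spec$insert_length))
  }
  tab <- table(extracted)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  stats <- list(reads_in = n_in,
                reads_too_short = n_short,
                reads_with_insert = length(extracted),
                reads_no_insert = n_in - n_short - length(extracted),
                reads_multiframe = sum(n_hits > 1L),
                hexamers_out = length(counts))
  message(sprintf("extracted %d inserts (%d distinct) from %d reads (%d rejected)",
                  stats$reads_with_insert, stats$hexamers_out, n_in,
                  stats$reads_too_short + stats$reads_no_insert))
  out <- hexamer_set(counts, sample_label = sample_label,
                     protease_label = protease_label,
                     n_reads_total = n_in)
  attr(out, "extraction_stats") <- stats
  out
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' @param path Path to a FASTQ/FASTQ.gz file (4-line records) or a FASTA
#'   file of pre-assembled amplicons.
#' @param format `"auto"` (guess from the extension), `"fastq"` or
#'   `"fasta"`.
#' @return A `DNAStringSet`.
#' @export
read_amplicon_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2)$", "", path)
    format <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  Biostrings::readDNAStringSet(path, format = format)
}
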