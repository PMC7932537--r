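# HexamerSet: the unit of selection output. A multiset of distinct insert
# peptides (hexamers by default) with read counts and sample metadata.

#' Construct a hexamer set
#'
#' A hexamer set is the canonical container for one sequenced sample: the
#' distinct variable-region peptides observed, their read counts, and where
#' they came from (naive library, untreated control, or a protease
#' selection).
#'
#' @param counts Named numeric vector: names are insert peptides (all the
#'   same length, standard 20-letter alphabet), values are positive read
#'   counts.
#' @param sample_label One of `"naive"`, `"control"`, `"selection"`.
#' @param protease_label Free-text enzyme label (e.g. `"MMP-2"`).
#' @param n_reads_total Total reads that produced the set; defaults to
#'   `sum(counts)`.
#' @return An object of class `hexamer_set`: a list with elements `counts`,
#'   `sample_label`, `protease_label`, `n_reads_total`, `insert_length`.
#' @export
hexamer_set <- function(counts,
                        sample_label = c("selection", "naive", "control"),
                        protease_label = "",
                        n_reads_total = sum(counts)) {
  sample_label <- match.arg(sample_label)
  if (length(counts) == 0L) {
    stop("a hexamer set must contain at least one peptide")
  }
  hx <- names(counts)
  if (is.null(hx) || anyNA(hx)) {
    stop("'counts' must be a named vector (names are insert peptides)")
  }
  len <- unique(nchar(hx))
  if (length(len) != 1L) {
    stop("all insert peptides must have the same length")
  }
  if (!all(is_standard_peptide(hx))) {
    stop("insert peptides must use only the 20 standard one-letter codes")
  }
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (anyDuplicated(hx)) stop("insert peptides must be distinct")
  structure(
    list(counts = counts,
         sample_label = sample_label,
         protease_label = protease_label,
         n_reads_total = n_reads_total,
         insert_length = len),
    class = "hexamer_set"
  )
}

#' @export
print.hexamer_set <- function(x, ...) {
  cat(sprintf(
    "hexamer_set [%s%s]: %d distinct %d-mers, %s reads (%s total in sample)\n",
    x$sample_label,
    if (nzchar(x$protease_label)) paste0(", ", x$protease_label) else "",
    length(x$counts), x$insert_length,
    format(sum(x$counts), big.mark = ","),
    format(x$n_reads_total, big.mark = ",")))
  invisible(x)
}

#' @export
length.hexamer_set <- function(x) length(x$counts)

#' Remove control-set peptides from a selection set
#'
#' Peptides found in the untreated control are removed from the selection by
#' sequence identity, regardless of counts: anything that survives
#' immunodepletion without being cleaved is background, not substrate
#' evidence. The operation is idempotent and never increases a count.
#'
#' @param selection,control `hexamer_set` objects built with the same flank
#'   specification (same insert length).
#' @return The `selection` set restricted to peptides absent from `control`,
#'   with attribute `removed_fraction` (fraction of distinct peptides
#'   removed). Warns and errors informatively if nothing survives.
#' @export
subtract_control <- function(selection, control) {
  stopifnot(inherits(selection, "hexamer_set"), inherits(control, "hexamer_set"))
  if (selection$insert_length != control$insert_length) {
    stop("selection and control sets have different insert lengths; ",
         "they must come from the same flank specification")
  }
  keep <- !(names(selection$counts) %in% names(control$counts))
  removed_fraction <- 1 - mean(keep)
  if (!any(keep)) {
    warning("all selection peptides were found in the control; ",
            "the subtracted set is empty")
    out <- selection
    out$counts <- selection$counts[0L]
    attr(out, "removed_fraction") <- removed_fraction
    return(out)
  }
  out <- selection
  out$counts <- selection$counts[keep]
  attr(out, "removed_fraction") <- removed_fraction
  out
}

#' Write / read a hexamer count table
#'
#' Plain TSV with header `hexamer<TAB>count`, one row per distinct peptide,
#' sorted by descending count then lexicographically.
#'
#' @param x A `hexamer_set`.
#' @param path Output file path.
#' @return `write_hexamer_tsv` returns `path` invisibly; `read_hexamer_tsv`
#'   returns a `hexamer_set`.
#' @export
write_hexamer_tsv <- function(x, path) {
  stopifnot(inherits(x, "hexamer_set"))
  ord <- order(-x$counts, names(x$counts), method = "radix")
  df <- data.frame(hexamer = names(x$counts)[ord],
                   count = unname(x$counts[ord]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hexamer_tsv
#' @param sample_label,protease_label Metadata for the set read from disk.
#' @export
read_hexamer_tsv <- function(path, sample_label = "selection",
                             protease_label = "") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
  counts <- df$count
  names(counts) <- df$hexamer
  hexamer_set(counts, sample_label = sample_label,
              protease_label = protease_label)
}
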