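# validation: binned RP-vs-catalytic-constant correlation and RP-threshold
# binary classification against measured kinetics.

#' Match kinetic measurements to tetramer clusters
#'
#' Joins each measured peptide to the RP of its P3-P1' tetramer. Peptides
#' with a known scissile position are projected directly (P1' at
#' `cleavage_index`, tetramer = residues `cleavage_index - 3` ..
#' `cleavage_index`). Hexamers without a known scissile bond are resolved by
#' cluster lookup: of the three candidate tetramers, the one with the
#' highest RP in the table (ties: smallest offset). Peptides whose tetramer
#' is absent from the table get RP = 0 and count toward the unmatched
#' fraction.
#'
#' @param kinetics `data.frame` with columns `peptide`, `cleavage_index`
#'   (1-based P1' position, `NA` for hexamers to be resolved by lookup) and
#'   `constant` (K_obs or kcat/K_M, M^-1 s^-1, >= 0).
#' @param rp An `rp_table` from [relative_probability()].
#' @return List with `records` (`data.frame`: `peptide`, `tetramer`, `rp`,
#'   `constant`), `n_unmatched` and `unmatched_fraction`.
#' @export
match_kinetics <- function(kinetics, rp) {
  stopifnot(is.data.frame(kinetics),
            all(c("peptide", "constant") %in% names(kinetics)))
  if (is.null(kinetics$cleavage_index)) kinetics$cleavage_index <- NA_integer_
  if (any(kinetics$constant < 0, na.rm = TRUE)) stop("constants must be >= 0")
  pep <- kinetics$peptide
  ci <- kinetics$cleavage_index
  tet <- rep(NA_character_, length(pep))

  idx <- !is.na(ci)
  if (any(idx)) {
    bad <- ci[idx] < 4L | ci[idx] > nchar(pep[idx])
    if (any(bad)) {
      stop("peptide too short to define the P3-P1' tetramer at its cleavage index")
    }
    tet[idx] <- substr(pep[idx], ci[idx] - 3L, ci[idx])
  }
  if (any(!idx)) {
    if (any(nchar(pep[!idx]) != 6L)) {
      stop("peptides without a cleavage index must be hexamers (cluster lookup)")
    }
    hx <- pep[!idx]
    cand <- vapply(0:2, function(off) substring(hx, off + 1L, off + 4L),
                   character(length(hx)))
    cand <- matrix(cand, ncol = 3L)
    rps <- matrix(rp$rp[match(cand, rp$tetramer)], ncol = 3L)
    rps[is.na(rps)] <- -1  # absent from table: never preferred
    best <- max.col(rps, ties.method = "first")  # smallest offset on ties
    tet[!idx] <- cand[cbind(seq_len(nrow(cand)), best)]
  }
  rp_val <- rp$rp[match(tet, rp$tetramer)]
  unmatched <- is.na(rp_val) | rp_val == 0
  rp_val[is.na(rp_val)] <- 0
  records <- data.frame(peptide = pep, tetramer = tet, rp = rp_val,
                        constant = kinetics$constant)
  list(records = records,
       n_unmatched = sum(unmatched),
       unmatched_fraction = mean(unmatched))
}

#' Binned correlation between RP and catalytic constants
#'
#' The raw per-substrate correlation between RP and the measured constant is
#' diluted by the unpredictable contribution of the P5-P4 and P2'-P3'
#' context residues. Binning neighboring substrates along the ascending RP
#' axis and correlating bin means averages that context noise out, so the
#' binned correlation approaches the underlying RP-fitness relationship.
#' Bins hold an equal number of substrates (contiguous in RP order) by
#' default; equal-width RP bins are available.
#'
#' @param records `data.frame` with columns `rp` and `constant` (from
#'   [match_kinetics()]).
#' @param n_per_bin Substrates per bin (contiguous along ascending RP).
#' @param n_bins Alternative: number of bins (default 10 when neither is
#'   given).
#' @param equal_width If `TRUE`, use equal-width RP bins instead of
#'   equal-count bins.
#' @return List with `r_raw` (Pearson R, unbinned), `bins` (per-bin
#'   `data.frame`: `n`, `mean_rp`, `mean_constant`, `sem_constant`),
#'   `r_binned`, and the OLS fit of mean constant on mean RP: `slope`,
#'   `intercept`, `r_squared`.
#' @export
binned_correlation <- function(records, n_per_bin = NULL, n_bins = NULL,
                               equal_width = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("rp", "constant") %in% names(records)))
  x <- records$rp
  y <- records$constant
  if (length(x) < 3L) stop("need at least 3 records")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(y) == 0) stop("all constants identical: correlation undefined")
  r_raw <- stats::cor(x, y)

  ord <- order(x, method = "radix")
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (is.null(n_per_bin) && is.null(n_bins)) n_bins <- 10L
  if (equal_width) {
    if (is.null(n_bins)) n_bins <- max(ceiling(n / n_per_bin), 1L)
    grp <- as.integer(cut(x, breaks = n_bins, include.lowest = TRUE))
  } else if (!is.null(n_per_bin)) {
    grp <- ceiling(seq_len(n) / n_per_bin)
  } else {
    grp <- ceiling(seq_len(n) * n_bins / n)
  }
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  bins <- data.frame(
    n = as.integer(tapply(y, grp, length)),
    mean_rp = as.numeric(tapply(x, grp, mean)),
    mean_constant = as.numeric(tapply(y, grp, mean)),
    sem_constant = as.numeric(tapply(y, grp, sem)))
  rownames(bins) <- NULL
  if (nrow(bins) < 2L) stop("binning produced fewer than 2 bins")
  fit <- stats::lm(mean_constant ~ mean_rp, data = bins)
  list(r_raw = r_raw,
       bins = bins,
       r_binned = stats::cor(bins$mean_rp, bins$mean_constant),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Binary classification of substrates by an RP threshold
#'
#' Treats "RP above threshold" as the prediction and "non-zero measured
#' constant" as the truth: TP where RP > threshold and K > 0, TN where
#' RP <= threshold and K = 0, FP where RP > threshold and K = 0, FN where
#' RP <= threshold and K > 0. Reports sensitivity, specificity, accuracy,
#' FP rate, precision and the Matthews correlation coefficient.
#'
#' @param records `data.frame` with columns `rp` and `constant`; rows may
#'   alternatively carry a logical `positive` truth column (used e.g. for
#'   isotopic-enrichment calls), which takes precedence over `constant`.
#' @param rp_threshold Threshold RP (strict `>` for a positive call).
#' @return A `classification_metrics` list: `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `fp_rate`, `precision`,
#'   `mcc`, `mcc_undefined` (TRUE when the MCC denominator is 0 and MCC is
#'   reported as 0).
#' @export
binary_classification <- function(records, rp_threshold) {
  stopifnot(is.data.frame(records), "rp" %in% names(records))
  if (nrow(records) == 0L) stop("empty input")
  truth <- if (!is.null(records$positive)) {
    as.logical(records$positive)
  } else {
    records$constant > 0
  }
  pred <- records$rp > rp_threshold
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc_undefined <- denom == 0
  mcc <- if (mcc_undefined) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         sensitivity = div(tp, tp + fn),
         specificity = div(tn, tn + fp),
         accuracy = (tp + tn) / nrow(records),
         fp_rate = div(fp, fp + tn),
         precision = div(tp, tp + fp),
         mcc = mcc,
         mcc_undefined = mcc_undefined),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("classification: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  FP rate %.3f, precision %.3f, MCC %.3f%s\n",
              x$fp_rate, x$precision, x$mcc,
              if (x$mcc_undefined) " (undefined, reported as 0)" else ""))
  invisible(x)
}

#' Read a kinetics table
#'
#' TSV with columns `peptide`, `cleavage_index` (blank/NA when unknown),
#' `constant`, and optionally `sd`.
#'
#' @param path Input TSV path.
#' @return `data.frame` suitable for [match_kinetics()].
#' @export
read_kinetics_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "constant") %in% names(df)))
  df
}
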