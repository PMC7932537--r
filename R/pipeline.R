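# High-level pipeline: hexamer sets in, selectome out.

#' Run the full specificity analysis
#'
#' Optionally subtracts the untreated control, clusters the selection with
#' redundancy elimination and the naive library without, computes
#' probabilities, RP and divergence contributions, derives the selectome
#' threshold at the cumulative-divergence zero crossing, and extracts the
#' selectome.
#'
#' @param selection A selection [hexamer_set()].
#' @param naive The naive-library [hexamer_set()].
#' @param control Optional untreated-control [hexamer_set()]; its peptides
#'   are removed from the selection before clustering.
#' @param rp_threshold Optional threshold override; by default the
#'   cumulative-divergence zero crossing is used.
#' @return A `selectome_analysis` list: `selection_clusters`,
#'   `naive_clusters` (cluster tables), `rp_table`, and `result`
#'   (a `selectome_result`).
#' @export
selectome_analysis <- function(selection, naive, control = NULL,
                               rp_threshold = NULL) {
  if (!is.null(control)) selection <- subtract_control(selection, control)
  sel_ct <- cluster_selection(selection)
  nl_ct <- cluster_naive(naive)
  rp <- relative_probability(cluster_probabilities(sel_ct),
                             cluster_probabilities(nl_ct))
  thr <- if (is.null(rp_threshold)) selectome_threshold(rp) else rp_threshold
  res <- extract_selectome(rp, thr)
  structure(list(selection_clusters = sel_ct,
                 naive_clusters = nl_ct,
                 rp_table = rp,
                 result = res),
            class = "selectome_analysis")
}

#' @export
print.selectome_analysis <- function(x, ...) {
  print(x$selection_clusters)
  print(x$naive_clusters)
  print(x$result)
  invisible(x)
}

#' Write the analysis summary as JSON
#'
#' @param analysis A `selectome_analysis` (or `selectome_result`).
#' @param path Output JSON path.
#' @export
write_summary_json <- function(analysis, path) {
  res <- if (inherits(analysis, "selectome_analysis")) {
    analysis$result
  } else {
    analysis
  }
  stopifnot(inherits(res, "selectome_result"))
  jsonlite::write_json(
    list(rp_threshold = res$rp_threshold,
         n_clusters = res$n_clusters,
         n_selectome = res$n_selectome,
         hexamers_in = res$hexamers_in,
         hexamers_out = res$hexamers_out,
         h_selection = res$h_selection,
         h_naive = res$h_naive,
         d_kl = res$d_kl,
         rp_max = res$rp_max),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
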