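#' Accelerated-aging signature of a model
#'
#' The concordant shared genes between a model's DEG list and an aged
#' reference: genes up in both or down in both (the shaded Venn region fed
#' to cell-type contribution scoring). Directions and effect sizes are
#' retained by returning the subset of the model's records, so the
#' signature can itself be ranked and compared.
#'
#' @param model,aged_reference filtered [deg_list()] objects.
#' @param n_universe universe size (default [harmonize_universe()]).
#' @param scan a [scan_config()].
#' @return A [deg_list()] restricted to the concordant shared genes, with
#'   dataset id `<model>_aging_signature`. Zero concordant genes yields an
#'   empty signature with a warning.
#' @export
aging_signature <- function(model, aged_reference, n_universe = NULL,
                            scan = scan_config()) {
  so <- compare_datasets(model, aged_reference, n_universe = n_universe,
                         scan = scan)
  conc <- extract_concordant_genes(so)
  genes <- c(conc$up_shared, conc$down_shared)
  if (!length(genes)) {
    warning(sprintf("empty aging signature for '%s' vs '%s'",
                    model$dataset_id, aged_reference$dataset_id))
  }
  sig <- model
  sig$dataset_id <- paste0(model$dataset_id, "_aging_signature")
  sig$records <- model$records[model$records$gene_id %in% genes, , drop = FALSE]
  rownames(sig$records) <- NULL
  sig
}

#' Score per-cell-type contributions to an aging signature
#'
#' Compares the signature against each cell type's filtered DEG list with
#' the directional overlap test. A cell type's contribution is
#' `-log10(overall p)` when the overlap is concordant (sign +1) and floored
#' at 0 when discordant, so the score is a contribution magnitude;
#' `percent_common` is 100 x shared genes / signature size (the bubble size
#' of the contribution plot).
#'
#' @param signature a [deg_list()] from [aging_signature()].
#' @param atlas named list of per-cell-type [deg_list()] objects (old vs
#'   young DEGs, one list per cell type).
#' @param n_universe universe size shared by the comparisons.
#' @param scan a [scan_config()].
#' @param crit [filter_criteria()] applied to each cell type's list.
#' @return data.frame with `celltype`, `neg_log_p`, `percent_common`,
#'   `n_shared`, `sign`, sorted by decreasing `neg_log_p`.
#' @export
score_contributions <- function(signature, atlas, n_universe = 20000L,
                                scan = scan_config(),
                                crit = filter_criteria()) {
  stopifnot(inherits(signature, "deg_list"), length(atlas) > 0,
            !is.null(names(atlas)))
  n_sig <- nrow(signature$records)
  if (!n_sig) {
    return(data.frame(celltype = names(atlas), neg_log_p = 0,
                      percent_common = 0, n_shared = 0L, sign = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(atlas), function(ct) {
    filtered <- apply_filter(atlas[[ct]], crit)
    if (!nrow(filtered$records)) {
      return(data.frame(celltype = ct, neg_log_p = 0, percent_common = 0,
                        n_shared = 0L, sign = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    so <- compare_datasets(signature, filtered, n_universe = n_universe,
                           scan = scan)
    shared <- length(unique(unlist(lapply(so$quadrants, `[[`, "shared_genes"))))
    data.frame(
      celltype = ct,
      neg_log_p = if (so$sign > 0) -so$overall_log10_p else 0,
      percent_common = 100 * shared / n_sig,
      n_shared = as.integer(shared),
      sign = so$sign,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$neg_log_p, out$celltype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
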