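#' Screen candidate datasets for hyper-maturity
#'
#' Reproduces the database screening logic: candidates are retained when
#' their region label contains the keyword (case-insensitive substring),
#' their life-stage label is not excluded (embryo / infant / cultured by
#' default, since the screen targets adult brain tissue), and their
#' directional overlap against at least one developmental reference is
#' concordant (sign +1) with overall p below the threshold (default
#' 1e-10). Matches are returned in ascending order of their best overlap
#' p-value.
#'
#' @param candidates named list of filtered [deg_list()] objects carrying
#'   `region` and `life_stage` metadata.
#' @param references named list of filtered developmental reference
#'   [deg_list()] objects (nonempty).
#' @param region_keyword substring the region label must contain (default
#'   `"hippocampus"`, matched case-insensitively).
#' @param exclusion_labels life-stage labels to exclude.
#' @param overlap_p_threshold screening threshold on the overall overlap p.
#' @param n_universe universe size for the comparisons.
#' @param scan a [scan_config()].
#' @return data.frame with `dataset_id`, `best_reference`, `overall_p`,
#'   `log10_p`, `sign`, `index`, sorted by ascending `overall_p`; zero rows
#'   if nothing passes.
#' @export
screen_candidates <- function(candidates, references,
                              region_keyword = "hippocampus",
                              exclusion_labels = c("embryo", "infant",
                                                   "cultured"),
                              overlap_p_threshold = 1e-10,
                              n_universe = NULL,
                              scan = scan_config()) {
  if (!length(references)) stop("empty reference panel", call. = FALSE)
  if (overlap_p_threshold <= 0 || overlap_p_threshold >= 1) {
    stop("overlap_p_threshold must lie in (0, 1)", call. = FALSE)
  }
  rows <- list()
  for (cand in candidates) {
    stopifnot(inherits(cand, "deg_list"))
    if (!grepl(region_keyword, cand$region %||% "", ignore.case = TRUE)) next
    if (tolower(cand$life_stage %||% "") %in% tolower(exclusion_labels)) next
    best <- NULL
    for (rn in names(references)) {
      so <- compare_datasets(cand, references[[rn]], n_universe = n_universe,
                             scan = scan)
      if (so$sign > 0 &&
          (is.null(best) || so$overall_log10_p < best$log10_p)) {
        best <- list(ref = rn, p = so$overall_p, log10_p = so$overall_log10_p,
                     sign = so$sign)
      }
    }
    if (!is.null(best) && best$log10_p < log10(overlap_p_threshold)) {
      rows[[cand$dataset_id]] <- data.frame(
        dataset_id = cand$dataset_id, best_reference = best$ref,
        overall_p = best$p, log10_p = best$log10_p, sign = best$sign,
        index = -best$log10_p, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(dataset_id = character(), best_reference = character(),
                      overall_p = numeric(), log10_p = numeric(),
                      sign = integer(), index = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$log10_p, out$dataset_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-study analysis pipeline
#'
#' Simulates a cohort, filters every DEG list, computes the model-by-
#' reference signed index table, summarizes maturity (development family)
#' and aging (aging family) per model, computes behavioral anxiety indices
#' and their Pearson correlation with maturity, classifies the models by
#' PCA + 2-means, runs the enrichment meta-analysis over the concordant
#' feature-gene sets, scores cell-type contributions for the model with the
#' strongest aging index, and screens the cohort against the developmental
#' panel. All stage outputs are written as TSV under `outdir` together with
#' a `report.yaml`; the run is fully determined by the configuration seed.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory; when NULL nothing is written.
#' @param crit [filter_criteria()] applied to every DEG list.
#' @param scan [scan_config()] used for every comparison.
#' @param n_enrichment_models number of top-maturity models whose
#'   concordant gene sets enter the enrichment meta-analysis (default 5).
#' @return An object of class `maturity_report`: list with `index_table`,
#'   `summary` (per-model maturity/aging/anxiety data.frame), `correlation`
#'   (r, p, slope, intercept), `groups` ([classify_models()] result),
#'   `enrichment`, `contributions`, `screen`, and `config`.
#' @export
run_all <- function(config = sim_config(), outdir = NULL,
                    crit = filter_criteria(), scan = scan_config(),
                    n_enrichment_models = 5L) {
  cohort <- simulate_cohort(config)
  n_universe <- config$n_genes_universe
  refs <- lapply(cohort$panel$references, apply_filter, crit = crit)
  models <- lapply(cohort$models, apply_filter, crit = crit)

  idx <- compute_index_table(models, refs, n_universe = n_universe,
                             scan = scan)
  dev_cols <- grep("^dev_", colnames(idx), value = TRUE)
  aging_cols <- grep("^aging_", colnames(idx), value = TRUE)
  maturity <- model_maturity_summary(idx, dev_cols)
  aging <- model_maturity_summary(idx, aging_cols)

  eff <- anxiety_effect_sizes(cohort$behavior)
  anx <- stats::setNames(eff$models$anxiety_index, eff$models$model)
  summary_df <- data.frame(
    model = names(models),
    planted_f = config$concordance_grid,
    maturity_index = as.numeric(maturity[names(models)]),
    aging_index = as.numeric(aging[names(models)]),
    anxiety_index = as.numeric(anx[names(models)]),
    stringsAsFactors = FALSE
  )
  corr <- correlate_indices(summary_df$maturity_index,
                            summary_df$anxiety_index)
  groups <- classify_models(idx, dev_columns = dev_cols)

  # enrichment over the strongest models' concordant feature genes
  top <- names(sort(abs(maturity), decreasing = TRUE))
  top <- utils::head(top[maturity[top] > 0], n_enrichment_models)
  queries <- lapply(top, function(m) {
    best_ref <- dev_cols[which.max(abs(unclass(idx)[m, dev_cols]))]
    so <- compare_datasets(models[[m]], refs[[best_ref]],
                           n_universe = n_universe, scan = scan)
    conc <- extract_concordant_genes(so)
    c(conc$up_shared, conc$down_shared)
  })
  names(queries) <- top
  queries <- queries[lengths(queries) > 0]
  enrichment <- if (length(queries) >= 2) {
    meta_enrich(queries, cohort$gene_sets, universe_n = n_universe)
  } else {
    NULL
  }

  # cell-type contributions for the model with the strongest aging index
  aging_model <- names(which.max(aging))
  best_aged <- aging_cols[which.max(abs(unclass(idx)[aging_model, aging_cols]))]
  sig <- aging_signature(models[[aging_model]], refs[[best_aged]],
                         n_universe = n_universe, scan = scan)
  contributions <- score_contributions(sig, cohort$atlas,
                                       n_universe = n_universe, scan = scan,
                                       crit = crit)
  contributions$model <- aging_model

  screen <- screen_candidates(models, refs[dev_cols],
                              n_universe = n_universe, scan = scan)

  report <- structure(
    list(index_table = idx, summary = summary_df, correlation = corr,
         groups = groups, enrichment = enrichment,
         contributions = contributions, screen = screen,
         effect_sizes = eff$measures, config = config, crit = crit),
    class = "maturity_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.maturity_report <- function(x, ...) {
  cat(sprintf("<maturity_report> %d models (seed %d)\n",
              nrow(x$summary), x$config$seed))
  cat(sprintf("  maturity vs anxiety: r = %.3f, p = %.4f (n = %d)\n",
              x$correlation$r, x$correlation$p, x$correlation$n))
  tab <- table(x$groups$groups)
  cat(sprintf("  groups: %d development_like, %d aging_like\n",
              tab[["development_like"]], tab[["aging_like"]]))
  cat(sprintf("  screened in: %d of %d models\n", nrow(x$screen),
              nrow(x$summary)))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  top enriched term: %s (meta p = %.3g)\n",
                x$enrichment$term_id[1], x$enrichment$meta_p[1]))
  }
  cat(sprintf("  top contributing cell type: %s (-log10 p = %.1f)\n",
              x$contributions$celltype[1], x$contributions$neg_log_p[1]))
  invisible(x)
}

# Write every stage output of a report as TSV plus a summary report.yaml.
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  idx_df <- data.frame(model = rownames(report$index_table),
                       unclass(report$index_table), check.names = FALSE)
  wt(idx_df, "index_table.tsv")
  wt(report$summary, "summary_indices.tsv")
  wt(report$summary[c("model", "maturity_index", "anxiety_index")],
     "scatter.tsv")
  wt(data.frame(model = names(report$groups$groups),
                group = as.character(report$groups$groups),
                pc1 = report$groups$pc_scores[, 1],
                pc2 = report$groups$pc_scores[, 2]),
     "groups.tsv")
  if (!is.null(report$enrichment)) {
    wt(as.data.frame(report$enrichment), "enrichment.tsv")
  }
  wt(report$contributions, "celltype_contributions.tsv")
  wt(report$screen, "screen.tsv")
  wt(report$effect_sizes, "effect_sizes.tsv")
  yaml::write_yaml(list(
    seed = report$config$seed,
    n_models = report$config$n_models,
    filter = list(min_abs_fold_change = report$crit$min_abs_fold_change,
                  max_pvalue = report$crit$max_pvalue),
    correlation = report$correlation[c("r", "p", "n", "slope", "intercept")],
    explained_variance_pc12 =
      sum(report$groups$explained_variance_fractions[1:2]),
    n_screened = nrow(report$screen),
    groups = as.list(table(report$groups$groups))
  ), file.path(outdir, "report.yaml"))
  invisible(outdir)
}
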