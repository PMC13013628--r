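#' Rank-scan configuration for the directional overlap test
#'
#' The overlap statistic scans nested top fractions of the two fold-change
#' ranked gene lists and takes the best (smallest) hypergeometric tail
#' probability over the grid, Bonferroni-corrected for the number of grid
#' pairs evaluated. `cutoff_fractions = 1` with `correction = "none"`
#' degenerates to a plain one-shot Fisher/hypergeometric overlap test.
#'
#' @param cutoff_fractions strictly increasing fractions in (0, 1]; the last
#'   must be 1 so the full lists are always evaluated. Default deciles.
#' @param correction `"bonferroni_scan"` (default; multiply the minimum
#'   p-value by the number of grid pairs, capped at 1) or `"none"`.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(cutoff_fractions = seq(0.1, 1, by = 0.1),
                        correction = c("bonferroni_scan", "none")) {
  correction <- match.arg(correction)
  f <- as.numeric(cutoff_fractions)
  if (!length(f) || any(!is.finite(f)) || any(f <= 0) || any(f > 1)) {
    stop("cutoff_fractions must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(f, strictly = TRUE)) {
    stop("cutoff_fractions must be strictly increasing", call. = FALSE)
  }
  if (f[length(f)] != 1) stop("last cutoff fraction must be 1.0", call. = FALSE)
  structure(list(cutoff_fractions = f, correction = correction),
            class = "scan_config")
}

#' Split a DEG list into fold-change ranked up and down gene lists
#'
#' Genes are split by the sign of `log2fc`; each half is ordered by
#' decreasing |log2fc|, ties broken by ascending p-value, then
#' lexicographically by gene id. Records with exactly zero log2fc carry no
#' direction and are dropped with a warning.
#'
#' @param deg a (typically filtered) [deg_list()].
#' @return list with character vectors `up` and `down`.
#' @export
rank_by_effect <- function(deg) {
  stopifnot(inherits(deg, "deg_list"))
  r <- deg$records
  if (nrow(r) && any(r$log2fc == 0)) {
    warning(sprintf("excluding %d record(s) with zero log2fc from ranking",
                    sum(r$log2fc == 0)))
    r <- r[r$log2fc != 0, , drop = FALSE]
  }
  ord <- order(-abs(r$log2fc), r$pvalue, r$gene_id)
  r <- r[ord, , drop = FALSE]
  list(up = r$gene_id[r$log2fc > 0], down = r$gene_id[r$log2fc < 0])
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `overlap` shared genes when a set of
#' size `k_a` and an independent draw of size `k_b` are taken from a
#' universe of `n_universe` genes.
#'
#' @param k_a,k_b sizes of the two gene sets.
#' @param overlap observed number of shared genes.
#' @param n_universe universe size.
#' @param log_p return the natural log of the tail probability.
#' @return `P[X >= overlap]` for X ~ Hypergeometric(n_universe, k_a, k_b).
#' @export
hypergeom_overlap_p <- function(k_a, k_b, overlap, n_universe, log_p = FALSE) {
  for (v in list(k_a = k_a, k_b = k_b, overlap = overlap, n_universe = n_universe)) {
    if (any(!is.finite(v) | v < 0 | v != floor(v))) {
      stop("arguments must be nonnegative integers", call. = FALSE)
    }
  }
  if (any(overlap > pmin(k_a, k_b)) || any(pmax(k_a, k_b) > n_universe)) {
    stop("domain error: need overlap <= min(k_a, k_b) <= n_universe", call. = FALSE)
  }
  p <- stats::phyper(overlap - 1, k_a, n_universe - k_a, k_b,
                     lower.tail = FALSE, log.p = log_p)
  if (!log_p) p <- pmin(p, 1)
  p
}

#' Combine two p-values by Fisher's method
#'
#' Survival probability of a chi-squared variable with 4 degrees of freedom
#' at -2(ln p1 + ln p2). Used to aggregate the two concordant (or the two
#' discordant) direction-pair overlap p-values of [compare_datasets()].
#'
#' @param p1,p2 p-values in (0, 1] (natural-log scale if `log_p`).
#' @param log_p treat inputs and return value on the natural-log scale;
#'   this keeps extremely small overlap p-values exact.
#' @return the combined p-value (or its natural log).
#' @export
fisher_combine <- function(p1, p2, log_p = FALSE) {
  if (!log_p) {
    if (any(c(p1, p2) <= 0 | c(p1, p2) > 1)) {
      stop("p-values must lie in (0, 1]", call. = FALSE)
    }
    lp <- log(p1) + log(p2)
  } else {
    if (any(c(p1, p2) > 0)) stop("log p-values must be <= 0", call. = FALSE)
    lp <- p1 + p2
  }
  stats::pchisq(-2 * lp, df = 4, lower.tail = FALSE, log.p = log_p)
}

# Fisher's method over k p-values on the natural-log scale (2k df).
fisher_method_log <- function(log_ps) {
  stats::pchisq(-2 * sum(log_ps), df = 2 * length(log_ps),
                lower.tail = FALSE, log.p = TRUE)
}

#' Rank-scan overlap p-value between two ordered gene lists
#'
#' For every pair of cutoffs (ceiling(f_i |A|), ceiling(f_j |B|)) over the
#' scan grid, computes the upper-tail hypergeometric probability of the
#' overlap between the two top-ranked prefixes, and returns the minimum,
#' multiplied by the number of grid pairs when `correction =
#' "bonferroni_scan"` (capped at 1). The p-value is carried on the
#' natural-log scale internally so deep overlaps do not underflow.
#'
#' @param list_a,list_b character vectors of genes, ranked by decreasing
#'   effect size (see [rank_by_effect()]); each must be duplicate-free.
#' @param n_universe universe size (must hold all distinct genes involved).
#' @param scan a [scan_config()].
#' @return list with `pvalue`, `log10_pvalue`, `best_cut_a`, `best_cut_b`,
#'   `n_grid` and `shared_at_full` (the full-list intersection, sorted).
#' @export
running_overlap_p <- function(list_a, list_b, n_universe,
                              scan = scan_config()) {
  stopifnot(inherits(scan, "scan_config"))
  list_a <- as.character(list_a); list_b <- as.character(list_b)
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    stop("ranked lists must be duplicate-free", call. = FALSE)
  }
  if (!length(list_a) || !length(list_b)) {
    return(list(pvalue = 1, log10_pvalue = 0, best_cut_a = 0L, best_cut_b = 0L,
                n_grid = 0L, shared_at_full = character(0)))
  }
  if (n_universe < length(union(list_a, list_b))) {
    stop("n_universe smaller than the combined distinct genes", call. = FALSE)
  }
  cuts_a <- as.integer(ceiling(scan$cutoff_fractions * length(list_a)))
  cuts_b <- as.integer(ceiling(scan$cutoff_fractions * length(list_b)))
  pos_b <- match(list_a, list_b)  # rank of each A gene within B (NA if absent)

  n_grid <- length(cuts_a) * length(cuts_b)
  best <- list(logp = Inf, ca = cuts_a[1], cb = cuts_b[1])
  for (ia in seq_along(cuts_a)) {
    ca <- cuts_a[ia]
    pos <- pos_b[seq_len(ca)]
    pos <- sort(pos[!is.na(pos)])
    ov <- findInterval(cuts_b, pos)  # shared genes within each B prefix
    lp <- stats::phyper(ov - 1, ca, n_universe - ca, cuts_b,
                        lower.tail = FALSE, log.p = TRUE)
    j <- which.min(lp)
    if (lp[j] < best$logp) best <- list(logp = lp[j], ca = ca, cb = cuts_b[j])
  }
  logp <- best$logp
  if (scan$correction == "bonferroni_scan") {
    logp <- min(0, logp + log(n_grid))
  }
  list(pvalue = exp(logp),
       log10_pvalue = logp / log(10),
       best_cut_a = best$ca, best_cut_b = best$cb,
       n_grid = n_grid,
       shared_at_full = sort(intersect(list_a, list_b)))
}

#' Directional signed overlap between two DEG lists
#'
#' The core comparison: both (filtered) DEG lists are split into
#' fold-change ranked up and down lists, the four direction pairs (up/up,
#' down/down, up/down, down/up) are each scored with the rank-scan overlap
#' test, the two concordant and the two discordant pairs are aggregated with
#' Fisher's method, and the result is reported as the smaller of the two
#' aggregates together with its direction: `sign = +1` when concordant
#' overlap dominates (the two signatures change in the same direction),
#' `-1` when discordant overlap dominates.
#'
#' @param a,b filtered [deg_list()] objects.
#' @param n_universe effective universe size; defaults to
#'   [harmonize_universe()] of the two lists.
#' @param scan a [scan_config()].
#' @param combine how to aggregate the two quadrant p-values on each side:
#'   Fisher's method (default) or their minimum.
#' @return An object of class `signed_overlap` with the per-quadrant shared
#'   gene sets and p-values (taken at the full cutoffs for the gene sets, as
#'   in a Venn diagram), `concordant_p`, `discordant_p`, `overall_p`,
#'   `overall_log10_p` and `sign`.
#' @export
compare_datasets <- function(a, b, n_universe = NULL, scan = scan_config(),
                             combine = c("fisher", "min")) {
  stopifnot(inherits(a, "deg_list"), inherits(b, "deg_list"))
  combine <- match.arg(combine)
  if (is.null(n_universe)) n_universe <- harmonize_universe(a, b)

  ra <- rank_by_effect(a)
  rb <- rank_by_effect(b)
  quadrant_lists <- list(
    up_up = list(ra$up, rb$up),
    down_down = list(ra$down, rb$down),
    up_down = list(ra$up, rb$down),
    down_up = list(ra$down, rb$up)
  )
  quadrants <- lapply(quadrant_lists, function(pair) {
    res <- running_overlap_p(pair[[1]], pair[[2]], n_universe, scan)
    list(shared_genes = res$shared_at_full,
         k_a = length(pair[[1]]), k_b = length(pair[[2]]),
         overlap = length(res$shared_at_full),
         pvalue = res$pvalue, log10_pvalue = res$log10_pvalue,
         best_cut_a = res$best_cut_a, best_cut_b = res$best_cut_b)
  })

  ln <- function(q) q$log10_pvalue * log(10)  # natural-log p per quadrant
  agg <- function(q1, q2) {
    if (combine == "fisher") fisher_combine(ln(q1), ln(q2), log_p = TRUE)
    else min(ln(q1), ln(q2))
  }
  log_conc <- agg(quadrants$up_up, quadrants$down_down)
  log_disc <- agg(quadrants$up_down, quadrants$down_up)
  sign <- if (log_conc <= log_disc) 1L else -1L
  log_overall <- min(log_conc, log_disc)

  structure(
    list(dataset_a = a$dataset_id, dataset_b = b$dataset_id,
         n_universe = as.integer(n_universe),
         quadrants = quadrants,
         concordant_p = exp(log_conc), discordant_p = exp(log_disc),
         concordant_log10_p = log_conc / log(10),
         discordant_log10_p = log_disc / log(10),
         overall_p = exp(log_overall),
         overall_log10_p = log_overall / log(10),
         sign = sign,
         scan = scan, combine = combine),
    class = "signed_overlap"
  )
}

#' @export
print.signed_overlap <- function(x, ...) {
  cat(sprintf("<signed_overlap> %s vs %s (universe %d)\n", x$dataset_a,
              x$dataset_b, x$n_universe))
  cat(sprintf("  overall p = %.3g (log10 = %.2f), sign = %+d (%s)\n",
              x$overall_p, x$overall_log10_p, x$sign,
              if (x$sign > 0) "concordant" else "discordant"))
  for (q in names(x$quadrants)) {
    qq <- x$quadrants[[q]]
    cat(sprintf("  %-9s %4d/%4d shared %4d  p = %.3g\n", q, qq$k_a, qq$k_b,
                qq$overlap, qq$pvalue))
  }
  invisible(x)
}

#' Concordant shared genes of a signed overlap
#'
#' The up/up and down/down shared gene sets: genes changing in the same
#' direction in both datasets. These are the feature genes fed to the
#' enrichment meta-analysis and, against an aged reference, the
#' accelerated-aging signature used for cell-type contribution scoring.
#'
#' @param result a `signed_overlap` from [compare_datasets()].
#' @return list with character vectors `up_shared` and `down_shared`.
#' @export
extract_concordant_genes <- function(result) {
  stopifnot(inherits(result, "signed_overlap"))
  list(up_shared = result$quadrants$up_up$shared_genes,
       down_shared = result$quadrants$down_down$shared_genes)
}

#' Flip the direction of every gene in a DEG list
#'
#' Utility for sign-convention checks: negates all log2 fold changes.
#'
#' @param deg a [deg_list()].
#' @return the negated [deg_list()].
#' @export
negate_deg <- function(deg) {
  stopifnot(inherits(deg, "deg_list"))
  deg$records$log2fc <- -deg$records$log2fc
  deg
}
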