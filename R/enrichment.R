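#' Hypergeometric enrichment of a query gene set against a collection
#'
#' For each term in the collection, computes the upper-tail hypergeometric
#' probability of the observed overlap between the query and the term's gene
#' set within a universe of `universe_n` genes, and appends
#' Benjamini-Hochberg q-values across terms.
#'
#' @param query character vector of gene ids (nonempty).
#' @param collection a [gene_set_collection()].
#' @param universe_n universe size; must be at least as large as the query
#'   and every term.
#' @return data.frame with `term_id`, `term_name`, `term_size`,
#'   `query_size`, `overlap`, `pvalue`, `log10_pvalue`, `qvalue`, sorted by
#'   ascending p-value (ties broken by term id).
#' @export
enrich_one <- function(query, collection, universe_n = 20000L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(as.character(query)))
  if (!length(query)) stop("query gene set is empty", call. = FALSE)
  if (universe_n < length(query)) {
    stop("domain error: universe smaller than the query", call. = FALSE)
  }
  sizes <- lengths(collection$sets)
  if (any(sizes > universe_n)) {
    stop("domain error: a term is larger than the universe", call. = FALSE)
  }
  overlap <- vapply(collection$sets,
                    function(g) length(intersect(g, query)), integer(1))
  lp <- stats::phyper(overlap - 1, sizes, universe_n - sizes, length(query),
                      lower.tail = FALSE, log.p = TRUE)
  res <- data.frame(
    term_id = names(collection$sets),
    term_name = as.character(collection$term_names),
    term_size = as.integer(sizes),
    query_size = length(query),
    overlap = overlap,
    pvalue = pmin(exp(lp), 1),
    log10_pvalue = lp / log(10),
    stringsAsFactors = FALSE
  )
  res$qvalue <- stats::p.adjust(res$pvalue, method = "BH")
  res <- res[order(res$pvalue, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Meta-analysis of gene-set enrichment across multiple query sets
#'
#' Runs [enrich_one()] for every query set (e.g. the concordant feature
#' genes of each screened model), combines the per-term p-values across
#' query sets with Fisher's method (chi-squared with 2K degrees of freedom
#' for K sets), and ranks terms by the combined p-value. A term's
#' `n_significant_sets` counts the query sets in which its BH q-value is
#' below 0.05.
#'
#' @param queries named list of character gene-id vectors; with a single
#'   query set the ranking reduces exactly to [enrich_one()]'s.
#' @param collection a [gene_set_collection()].
#' @param universe_n universe size.
#' @return data.frame of class `meta_enrichment` with `term_id`,
#'   `term_name`, `meta_p`, `meta_log10_p`, `n_significant_sets`, `rank`,
#'   ordered by rank; the per-set p-value matrix is attached as attribute
#'   `per_set_p`.
#' @export
meta_enrich <- function(queries, collection, universe_n = 20000L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(queries) < 1) stop("need at least one query set", call. = FALSE)
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- paste0("set", seq_along(queries))
  }
  per <- lapply(queries, enrich_one, collection = collection,
                universe_n = universe_n)
  terms <- names(collection$sets)
  lp_mat <- vapply(per, function(d) {
    d$log10_pvalue[match(terms, d$term_id)] * log(10)
  }, numeric(length(terms)))
  if (is.null(dim(lp_mat))) lp_mat <- matrix(lp_mat, nrow = length(terms))
  q_mat <- vapply(per, function(d) d$qvalue[match(terms, d$term_id)],
                  numeric(length(terms)))
  if (is.null(dim(q_mat))) q_mat <- matrix(q_mat, nrow = length(terms))

  meta_lp <- apply(lp_mat, 1, fisher_method_log)
  res <- data.frame(
    term_id = terms,
    term_name = as.character(collection$term_names),
    meta_p = pmin(exp(meta_lp), 1),
    meta_log10_p = meta_lp / log(10),
    n_significant_sets = as.integer(rowSums(q_mat < 0.05)),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$meta_p, res$meta_log10_p, res$term_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  p_set <- exp(lp_mat)[match(res$term_id, terms), , drop = FALSE]
  dimnames(p_set) <- list(res$term_id, names(queries))
  attr(res, "per_set_p") <- p_set
  class(res) <- c("meta_enrichment", "data.frame")
  res
}

#' @export
print.meta_enrichment <- function(x, n = 10, ...) {
  cat(sprintf("<meta_enrichment> %d terms x %d query sets; top terms:\n",
              nrow(x), ncol(attr(x, "per_set_p"))))
  print.data.frame(utils::head(x[c("rank", "term_id", "meta_p",
                                   "n_significant_sets")], n))
  invisible(x)
}
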