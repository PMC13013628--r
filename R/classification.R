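#' Build the model-by-reference signed index matrix
#'
#' Assembles precomputed [compare_datasets()] results into the matrix of
#' signed -log10 overlap indices used for PCA grouping. Every model must
#' have been compared against every reference; missing pairs are an error.
#'
#' @param overlaps nested list: `overlaps[[model]][[reference]]` is a
#'   `signed_overlap`.
#' @return numeric matrix (models x references) of class `index_table`.
#' @export
build_index_matrix <- function(overlaps) {
  if (!length(overlaps) || is.null(names(overlaps))) {
    stop("overlaps must be a named nested list", call. = FALSE)
  }
  refs <- sort(unique(unlist(lapply(overlaps, names))))
  if (!length(refs)) stop("no reference comparisons present", call. = FALSE)
  missing <- character(0)
  for (m in names(overlaps)) {
    miss <- setdiff(refs, names(overlaps[[m]]))
    if (length(miss)) {
      missing <- c(missing, paste(m, miss, sep = " vs "))
    }
  }
  if (length(missing)) {
    stop("incomplete comparison matrix; missing pair(s): ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  idx <- matrix(NA_real_, length(overlaps), length(refs),
                dimnames = list(names(overlaps), refs))
  lp <- idx; sg <- idx
  for (m in names(overlaps)) {
    for (r in refs) {
      so <- overlaps[[m]][[r]]
      stopifnot(inherits(so, "signed_overlap"))
      idx[m, r] <- overlap_index(so)
      lp[m, r] <- so$overall_log10_p
      sg[m, r] <- so$sign
    }
  }
  structure(idx, log10_p = lp, sign = sg, class = c("index_table", "matrix"))
}

#' Classify models into development-like and aging-like groups
#'
#' Column-standardizes the signed index matrix, projects the models onto
#' their first two principal components, and splits them with 2-means
#' using a fixed, deterministic initialization (the two models with the
#' extreme first-component scores). The cluster whose members have the
#' higher mean index over the development reference columns is labeled
#' `development_like`, the other `aging_like` — so group semantics depend
#' on the development columns only, not on the aging columns' orientation.
#'
#' @param matrix an `index_table` (or plain numeric matrix), models in rows;
#'   at least 3 models and 2 references.
#' @param dev_columns columns forming the development family (names or
#'   indices); defaults to columns whose name starts with `"dev"`.
#' @return An object of class `maturity_groups`: list with `groups` (named
#'   factor with levels `development_like`, `aging_like`), `pc_scores`
#'   (models x 2), `explained_variance_fractions` (all components),
#'   `centers`, and `dev_columns`.
#' @export
classify_models <- function(matrix, dev_columns = NULL) {
  x <- unclass(matrix)
  if (!is.matrix(x) || nrow(x) < 3 || ncol(x) < 2) {
    stop("need a matrix with >= 3 models and >= 2 references", call. = FALSE)
  }
  if (is.null(dev_columns)) {
    dev_columns <- grep("^dev", colnames(x), value = TRUE)
    if (!length(dev_columns)) dev_columns <- colnames(x)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate matrix: zero-variance column(s) ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  expl <- pc$sdev^2 / sum(pc$sdev^2)

  # deterministic 2-means: seed with the two extreme PC1 models
  init <- scores[c(which.min(scores[, 1]), which.max(scores[, 1])), ,
                 drop = FALSE]
  if (any(duplicated(init))) {
    stop("degenerate scores: extreme models coincide", call. = FALSE)
  }
  km <- stats::kmeans(scores, centers = init)
  cl <- km$cluster

  dev_mean <- vapply(1:2, function(k) {
    mean(x[cl == k, dev_columns, drop = FALSE])
  }, numeric(1))
  labels <- if (dev_mean[1] >= dev_mean[2]) {
    c("development_like", "aging_like")
  } else {
    c("aging_like", "development_like")
  }
  groups <- factor(labels[cl], levels = c("development_like", "aging_like"))
  names(groups) <- rownames(x)

  structure(
    list(groups = groups, pc_scores = scores,
         explained_variance_fractions = expl,
         centers = km$centers, dev_columns = dev_columns),
    class = "maturity_groups"
  )
}

#' @export
print.maturity_groups <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("<maturity_groups> %d models: %d development_like, %d aging_like\n",
              length(x$groups), tab[["development_like"]], tab[["aging_like"]]))
  cat(sprintf("  first two components explain %.1f%% of the variance\n",
              100 * sum(x$explained_variance_fractions[1:2])))
  print(split(names(x$groups), x$groups))
  invisible(x)
}
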