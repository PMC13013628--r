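#' Signed -log10 similarity index
#'
#' Transforms an overlap p-value and its direction into the signed index
#' used for maturity, aging, excitation, suppression and corticosterone
#' scales: `sign * (-log10(p))`. Positive values mean the model's signature
#' changes in the same direction as the reference (e.g. hyper-maturity
#' against a developmental reference); negative values mean the opposite
#' (e.g. pseudo-immaturity). The p-value is floored at 1e-300 so the index
#' stays finite if a caller supplies an underflowed p; pipeline code passes
#' the exact log10 p instead (see `log10_p`).
#'
#' @param p overlap p-value in (0, 1].
#' @param sign +1 (concordant) or -1 (discordant).
#' @param log10_p optional exact log10 p-value; overrides `p` when given.
#' @return signed index (numeric scalar).
#' @export
maturity_index <- function(p, sign = 1, log10_p = NULL) {
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  if (!is.null(log10_p)) {
    if (log10_p > 0) stop("log10_p must be <= 0", call. = FALSE)
    return(sign * -log10_p)
  }
  stop_if_not_scalar_number(p, "p")
  if (p <= 0 || p > 1) stop("domain error: p must lie in (0, 1]", call. = FALSE)
  sign * -log10(max(p, 1e-300))
}

# index for a signed_overlap object, on the exact log scale
overlap_index <- function(so) {
  stopifnot(inherits(so, "signed_overlap"))
  maturity_index(so$overall_p, so$sign, log10_p = so$overall_log10_p)
}

#' Cohen's d from group summary statistics
#'
#' Effect size of a model-vs-control behavioral comparison,
#' `d = (M_model - M_control) / S_pooled` with the unweighted pooled SD
#' `S_pooled = sqrt((S_model^2 + S_control^2) / 2)`. The polarity-adjusted
#' effect `d_adjusted = polarity * d` is oriented so that positive values
#' always mean more anxiety-like behavior, whatever the raw measure's
#' direction (e.g. time in open arms has polarity -1, latency to enter the
#' light box +1).
#'
#' @param measure a list or one-row data.frame with fields `mean_model`,
#'   `sd_model`, `mean_control`, `sd_control` and optionally `polarity`
#'   (default +1). SEM-reported measures must be converted on ingestion
#'   (see [read_behavior_table()]).
#' @return list with `d_raw`, `d_adjusted` and `s_pooled`.
#' @export
cohens_d <- function(measure) {
  m <- as.list(measure)
  s1 <- m$sd_model; s2 <- m$sd_control
  if (is.null(s1) || is.null(s2) || s1 < 0 || s2 < 0) {
    stop("sd_model and sd_control must be nonnegative", call. = FALSE)
  }
  if (s1 == 0 && s2 == 0) {
    stop("undefined effect size: both group SDs are zero", call. = FALSE)
  }
  pol <- m$polarity %||% 1
  if (!pol %in% c(-1, 1)) stop("polarity must be +1 or -1", call. = FALSE)
  s_pooled <- sqrt((s1^2 + s2^2) / 2)
  d_raw <- (m$mean_model - m$mean_control) / s_pooled
  list(d_raw = d_raw, d_adjusted = pol * d_raw, s_pooled = s_pooled)
}

#' Read a behavioral summary table
#'
#' Tab-separated with header `model measure polarity mean_model sd_model
#' n_model mean_control sd_control n_control`. Dispersion may instead be
#' given as `sem_model`/`sem_control`; SEMs are converted to SDs as
#' `SD = SEM * sqrt(n)` (requires n >= 2).
#'
#' @param path TSV file path.
#' @return data.frame of validated behavioral measures (SDs only).
#' @export
read_behavior_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("model", "measure", "polarity", "mean_model", "n_model",
            "mean_control", "n_control")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("behavior table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (grp in c("model", "control")) {
    sd_col <- paste0("sd_", grp); sem_col <- paste0("sem_", grp)
    if (!sd_col %in% names(tab)) {
      if (!sem_col %in% names(tab)) {
        stop("behavior table needs ", sd_col, " or ", sem_col, call. = FALSE)
      }
      n <- tab[[paste0("n_", grp)]]
      if (any(n < 2)) stop("SEM conversion requires n >= 2", call. = FALSE)
      tab[[sd_col]] <- tab[[sem_col]] * sqrt(n)
    } else if (sem_col %in% names(tab)) {
      fill <- is.na(tab[[sd_col]]) & !is.na(tab[[sem_col]])
      tab[[sd_col]][fill] <- tab[[sem_col]][fill] * sqrt(tab[[paste0("n_", grp)]][fill])
    }
  }
  if (any(!tab$polarity %in% c(-1, 1))) {
    stop("polarity must be +1 or -1", call. = FALSE)
  }
  if (any(tab$sd_model < 0 | tab$sd_control < 0, na.rm = TRUE)) {
    stop("SDs must be nonnegative", call. = FALSE)
  }
  tab[c("model", "measure", "polarity", "mean_model", "sd_model", "n_model",
        "mean_control", "sd_control", "n_control")]
}

#' Per-measure and per-model anxiety effect sizes
#'
#' Computes polarity-adjusted Cohen's d for every row of a behavioral table
#' and aggregates to one anxiety index per model as the unweighted mean of
#' the model's adjusted effects.
#'
#' @param behavior data.frame as returned by [read_behavior_table()] (or the
#'   synthetic generator).
#' @return list with `measures` (the input plus `d_raw`, `d_adjusted`) and
#'   `models` (data.frame `model`, `anxiety_index`, `n_measures`).
#' @export
anxiety_effect_sizes <- function(behavior) {
  stopifnot(is.data.frame(behavior), nrow(behavior) > 0)
  ds <- lapply(seq_len(nrow(behavior)), function(i) cohens_d(behavior[i, ]))
  behavior$d_raw <- vapply(ds, `[[`, numeric(1), "d_raw")
  behavior$d_adjusted <- vapply(ds, `[[`, numeric(1), "d_adjusted")
  agg <- stats::aggregate(d_adjusted ~ model, data = behavior, FUN = mean)
  names(agg)[2] <- "anxiety_index"
  agg$n_measures <- as.vector(table(behavior$model)[agg$model])
  list(measures = behavior, models = agg)
}

#' Anxiety index of one model
#'
#' @param measures data.frame of one model's behavioral measures.
#' @return unweighted mean of the polarity-adjusted Cohen's d values.
#' @export
model_anxiety_index <- function(measures) {
  if (!nrow(measures)) stop("no behavioral measures supplied", call. = FALSE)
  mean(vapply(seq_len(nrow(measures)),
              function(i) cohens_d(measures[i, ])$d_adjusted, numeric(1)))
}

#' Signed index table over models and references
#'
#' Compares every model DEG list against every reference DEG list and
#' tabulates the signed -log10 overlap indices. Rows are models, columns
#' references; the exact log10 p-values and signs are kept as attributes.
#'
#' @param models,references named lists of filtered [deg_list()] objects.
#' @param n_universe universe size shared by all comparisons (default via
#'   [harmonize_universe()] per pair).
#' @param scan a [scan_config()].
#' @return numeric matrix of class `index_table` with attributes
#'   `log10_p` and `sign` (same dimensions).
#' @export
compute_index_table <- function(models, references, n_universe = NULL,
                                scan = scan_config()) {
  stopifnot(length(models) > 0, length(references) > 0,
            !is.null(names(models)), !is.null(names(references)))
  idx <- matrix(NA_real_, length(models), length(references),
                dimnames = list(names(models), names(references)))
  lp <- idx; sg <- idx
  for (i in seq_along(models)) {
    for (j in seq_along(references)) {
      so <- compare_datasets(models[[i]], references[[j]],
                             n_universe = n_universe, scan = scan)
      idx[i, j] <- overlap_index(so)
      lp[i, j] <- so$overall_log10_p
      sg[i, j] <- so$sign
    }
  }
  structure(idx, log10_p = lp, sign = sg, class = c("index_table", "matrix"))
}

#' @export
print.index_table <- function(x, ...) {
  cat(sprintf("<index_table> %d models x %d references (signed -log10 overlap p)\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Summarize a family of reference comparisons to one index per model
#'
#' The default summary takes, per model, the family index of largest
#' absolute value (the most significant comparison, sign preserved) —
#' matching a screening rule of the form "significant against at least one
#' developmental reference". Mean and single-column summaries are available.
#'
#' @param table an `index_table` from [compute_index_table()].
#' @param columns reference columns forming the family (names or indices).
#' @param method `"max_abs"` (default), `"mean"`, or `"column"`.
#' @param column the single reference used when `method = "column"`.
#' @return named numeric vector, one summary index per model.
#' @export
model_maturity_summary <- function(table, columns = colnames(table),
                                   method = c("max_abs", "mean", "column"),
                                   column = NULL) {
  method <- match.arg(method)
  sub <- unclass(table)[, columns, drop = FALSE]
  if (!ncol(sub)) stop("no comparisons available for this family", call. = FALSE)
  switch(method,
    max_abs = apply(sub, 1, function(v) v[which.max(abs(v))]),
    mean = rowMeans(sub),
    column = {
      if (is.null(column)) stop("method 'column' needs 'column'", call. = FALSE)
      sub[, column]
    })
}

#' Pearson correlation with t-based two-sided p-value
#'
#' @param x,y numeric vectors (n >= 3, finite, nonzero variance).
#' @return list with `r`, `p`, `n`, `t`, `df`, `slope`, `intercept` (least
#'   squares line of y on x).
#' @export
correlate_indices <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need two equal-length vectors with n >= 3", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  p <- pearson_p_from_r(r, n)
  slope <- r * stats::sd(y) / stats::sd(x)
  list(r = r, p = p, n = n,
       t = r * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2,
       slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Two-sided p-value of a Pearson correlation via the t transformation
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t distribution with
#' n - 2 degrees of freedom.
#'
#' @param r Pearson correlation coefficient.
#' @param n number of paired observations (>= 3).
#' @return two-sided p-value.
#' @export
pearson_p_from_r <- function(r, n) {
  stop_if_not_scalar_number(r, "r")
  if (abs(r) >= 1) return(0)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}
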