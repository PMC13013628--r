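#' Construct a signed differential-expression list
#'
#' A `deg_list` is the unit of comparison throughout the package: one
#' dataset's differentially expressed genes, each with a signed log2 fold
#' change and a raw p-value, plus optional metadata describing the dataset
#' (species, brain region, life stage) and the universe of measured genes.
#'
#' @param records data.frame with columns `gene_id` (character),
#'   `log2fc` (finite numeric) and `pvalue` (numeric in (0, 1]).
#' @param dataset_id character scalar identifying the dataset.
#' @param species,region,life_stage free-text metadata labels; `region` and
#'   `life_stage` drive the screening filters in [screen_candidates()].
#' @param universe optional character vector of all measured gene ids; when
#'   present every record must belong to it.
#' @return An object of class `deg_list`.
#' @seealso [read_deg_table()], [apply_filter()]
#' @export
deg_list <- function(records, dataset_id, species = "mouse",
                     region = "hippocampus", life_stage = "adult",
                     universe = NULL) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame", call. = FALSE)
  need <- c("gene_id", "log2fc", "pvalue")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  records <- records[need]
  records$gene_id <- as.character(records$gene_id)
  records$log2fc <- as.numeric(records$log2fc)
  records$pvalue <- as.numeric(records$pvalue)
  if (anyDuplicated(records$gene_id)) {
    stop("duplicate gene_ids in records; collapse before constructing", call. = FALSE)
  }
  if (nrow(records) && any(!is.finite(records$log2fc))) {
    stop("non-finite log2fc values", call. = FALSE)
  }
  if (nrow(records) &&
      any(!is.finite(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1)) {
    stop("pvalues must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    bad <- setdiff(records$gene_id, universe)
    if (length(bad)) {
      stop("record gene_ids outside the stated universe, e.g. ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
  }
  rownames(records) <- NULL
  structure(
    list(dataset_id = as.character(dataset_id)[1], species = species,
         region = region, life_stage = life_stage,
         records = records, universe = universe),
    class = "deg_list"
  )
}

#' @export
print.deg_list <- function(x, ...) {
  cat(sprintf("<deg_list> %s (%s, %s): %d records", x$dataset_id,
              x$species, x$region, nrow(x$records)))
  if (!is.null(x$universe)) cat(sprintf(", universe %d genes", length(x$universe)))
  cat("\n")
  if (nrow(x$records)) print(utils::head(x$records, 4))
  invisible(x)
}

#' @export
length.deg_list <- function(x) nrow(x$records)

#' Read a DEG table from a tab-separated file
#'
#' Expects a header with `gene_id`, a p-value column `pvalue`, and either a
#' `log2fc` column or a signed linear `fold_change` column (negative meaning
#' down-regulated; converted as sign(fc) * log2(|fc|)). Gene symbols are
#' uppercased so that mouse/rat/human symbol-level matching works without an
#' explicit homology map; an optional two-column ortholog map (from, to) can
#' override symbols before harmonization. Duplicate gene ids are collapsed
#' keeping the record with the smallest p-value.
#'
#' @param path file path to a TSV with the columns above.
#' @param dataset_id identifier stored on the result.
#' @param ortholog_map optional data.frame (or path to a two-column TSV)
#'   mapping input symbols to harmonized symbols.
#' @param ... further metadata passed to [deg_list()] (species, region, ...).
#' @return A validated [deg_list()].
#' @export
read_deg_table <- function(path, dataset_id, ortholog_map = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(tab) == 0L && ncol(tab) == 0L) {
    stop("format error: empty file ", path, call. = FALSE)
  }
  if (!"gene_id" %in% names(tab)) {
    stop("format error: missing column 'gene_id' in ", path, call. = FALSE)
  }
  has_log <- "log2fc" %in% names(tab)
  has_lin <- "fold_change" %in% names(tab)
  if (!has_log && !has_lin) {
    stop("format error: need a 'log2fc' or 'fold_change' column in ", path,
         call. = FALSE)
  }
  if (!"pvalue" %in% names(tab)) {
    stop("format error: missing column 'pvalue' in ", path, call. = FALSE)
  }

  num <- function(col) {
    raw <- tab[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & nzchar(trimws(as.character(raw))))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric '%s' at line %d ('%s')",
                   col, bad[1] + 1L, raw[bad[1]]), call. = FALSE)
    }
    val
  }
  if (has_log) {
    l2 <- num("log2fc")
  } else {
    fc <- num("fold_change")
    if (any(abs(fc) < 1 & fc != 0, na.rm = TRUE)) {
      stop("parse error: linear fold_change values must have |fc| >= 1 ",
           "(sign encodes direction)", call. = FALSE)
    }
    l2 <- sign(fc) * log2(abs(fc))
  }
  rec <- data.frame(gene_id = toupper(as.character(tab$gene_id)),
                    log2fc = l2, pvalue = num("pvalue"),
                    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$gene_id) & nzchar(rec$gene_id), , drop = FALSE]

  if (!is.null(ortholog_map)) {
    if (is.character(ortholog_map) && length(ortholog_map) == 1L) {
      ortholog_map <- utils::read.delim(ortholog_map, stringsAsFactors = FALSE)
    }
    if (ncol(ortholog_map) < 2L) stop("ortholog map needs two columns", call. = FALSE)
    from <- toupper(as.character(ortholog_map[[1]]))
    to <- toupper(as.character(ortholog_map[[2]]))
    hit <- match(rec$gene_id, from)
    rec$gene_id[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }

  # collapse duplicates: keep smallest p-value
  rec <- rec[order(rec$pvalue, rec$gene_id), , drop = FALSE]
  rec <- rec[!duplicated(rec$gene_id), , drop = FALSE]
  rec <- rec[order(rec$gene_id), , drop = FALSE]
  deg_list(rec, dataset_id = dataset_id, ...)
}

#' Write a DEG list as a tab-separated table
#'
#' @param deg a [deg_list()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  stopifnot(inherits(deg, "deg_list"))
  utils::write.table(deg$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Differential-expression filter criteria
#'
#' The screening filter used throughout: absolute linear fold change strictly
#' greater than `min_abs_fold_change` and raw p-value strictly below
#' `max_pvalue`. Defaults are |FC| > 1.2 and p < 0.05.
#'
#' @param min_abs_fold_change linear fold-change threshold (> 1).
#' @param max_pvalue raw p-value threshold in (0, 1].
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_abs_fold_change = 1.2, max_pvalue = 0.05) {
  stop_if_not_scalar_number(min_abs_fold_change, "min_abs_fold_change")
  stop_if_not_scalar_number(max_pvalue, "max_pvalue")
  if (min_abs_fold_change <= 1) stop("min_abs_fold_change must be > 1", call. = FALSE)
  if (max_pvalue <= 0 || max_pvalue > 1) stop("max_pvalue must be in (0, 1]", call. = FALSE)
  structure(list(min_abs_fold_change = min_abs_fold_change,
                 max_pvalue = max_pvalue),
            class = "filter_criteria")
}

#' Apply fold-change and p-value filters to a DEG list
#'
#' Retains records with `2^|log2fc| > min_abs_fold_change` and
#' `pvalue < max_pvalue` (both strict). The universe is unchanged: filtering
#' selects the differentially expressed genes, it does not shrink the set of
#' measured genes.
#'
#' @param deg a [deg_list()].
#' @param crit a [filter_criteria()].
#' @return The filtered [deg_list()].
#' @export
apply_filter <- function(deg, crit = filter_criteria()) {
  stopifnot(inherits(deg, "deg_list"), inherits(crit, "filter_criteria"))
  keep <- 2^abs(deg$records$log2fc) > crit$min_abs_fold_change &
    deg$records$pvalue < crit$max_pvalue
  deg$records <- deg$records[keep, , drop = FALSE]
  rownames(deg$records) <- NULL
  deg
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Gene ids are uppercased;
#' empty sets are dropped with a warning; a duplicated term id keeps the
#' first occurrence and warns.
#'
#' @param path GMT file path.
#' @param name collection name (defaults to the file name).
#' @return An object of class `gene_set_collection`: a list with `name`,
#'   `sets` (named list of character vectors) and `term_names`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); term_names <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("format error: line %d has %d field(s), need >= 3", i,
                   length(f)), call. = FALSE)
    }
    id <- f[1]
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning(sprintf("dropping empty gene set '%s' (line %d)", id, i))
      next
    }
    if (id %in% names(sets)) {
      warning(sprintf("duplicate term id '%s' (line %d): keeping first", id, i))
      next
    }
    sets[[id]] <- genes
    term_names[id] <- f[2]
  }
  gene_set_collection(sets, term_names = term_names, name = name)
}

#' @rdname read_gmt
#' @param sets named list of character gene vectors.
#' @param term_names optional named character vector of descriptions.
#' @export
gene_set_collection <- function(sets, term_names = NULL, name = "collection") {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a non-empty named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("term ids must be unique", call. = FALSE)
  if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed", call. = FALSE)
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(sets), names(sets))
  }
  structure(list(name = name, sets = sets,
                 term_names = term_names[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %s: %d sets, sizes %d-%d\n", x$name,
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write a gene-set collection in GMT format
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$term_names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Effective gene universe size for an overlap test
#'
#' When both DEG lists carry an explicit universe of measured genes, the
#' effective universe is the size of their intersection; otherwise the
#' configurable fallback (default 20000, the order of the mouse
#' protein-coding gene count) is used. The universe must be able to contain
#' all distinct DEGs of the two lists; anything smaller indicates
#' inconsistent inputs.
#'
#' @param a,b [deg_list()] objects.
#' @param fallback_n universe size used when either list lacks a universe.
#' @return integer universe size.
#' @export
harmonize_universe <- function(a, b, fallback_n = 20000L) {
  stopifnot(inherits(a, "deg_list"), inherits(b, "deg_list"))
  n <- if (!is.null(a$universe) && !is.null(b$universe)) {
    length(intersect(a$universe, b$universe))
  } else {
    as.integer(fallback_n)
  }
  n_deg <- length(union(a$records$gene_id, b$records$gene_id))
  if (n < n_deg) {
    stop(sprintf(paste0("inconsistent universe: %d genes cannot contain the ",
                        "%d distinct DEGs of '%s' and '%s'"),
                 n, n_deg, a$dataset_id, b$dataset_id), call. = FALSE)
  }
  as.integer(n)
}
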