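#' Configuration for the synthetic study generator
#'
#' Defines the simulated study conditions: a gene universe, a developmental
#' reference panel (seven timepoints emulating postnatal ages 8-29 days vs
#' adult) and an aging panel (three timepoints emulating 16/24/29 vs 3
#' months), a cohort of model datasets with planted direction-concordance
#' against one of the reference signatures, behavioral measures whose true
#' effect sizes are linked linearly to the planted concordance, and a
#' single-cell atlas of per-cell-type aging DEG lists with designated
#' contributor cell types.
#'
#' @param n_genes_universe number of measured genes (default 20000).
#' @param n_dev_timepoints developmental reference timepoints (default 7).
#' @param n_aging_timepoints aging reference timepoints (default 3).
#' @param signature_size genes per reference signature, half up / half down
#'   (default 800).
#' @param n_models model datasets in the cohort (default 19: 17 planted
#'   hyper-maturity plus 2 planted immaturity).
#' @param concordance_grid planted direction-concordance fraction per model,
#'   each in \[-1, 1\] (negative = planted immaturity). Default: 17 values
#'   evenly spaced from 0.9 down to 0.3, then -0.4 and -0.7.
#' @param model_family per-model reference family the concordance is planted
#'   against: `"development"` (default for all models) or `"aging"`.
#' @param effect_size_link list with `slope` and `noise_sd` linking planted
#'   concordance f to a measure's true anxiety effect size
#'   d = slope * f + Normal(0, noise_sd). Default slope 1, noise SD 0.2.
#' @param n_celltypes cell types in the atlas (default 11).
#' @param contributors named numeric vector of planted aging-signature
#'   shares per designated contributor cell type (default microglia 0.55,
#'   astrocyte 0.25); use an empty vector for a null atlas.
#' @param seed integer RNG seed; identical seeds give identical outputs.
#' @param effect_mu,effect_sd,effect_min signature-gene |log2FC| are drawn
#'   from Normal(effect_mu, effect_sd) truncated below at effect_min
#'   (defaults 1, 0.3, 0.3), so most planted genes clear the |FC| > 1.2
#'   filter while weak-timepoint genes realistically fail it.
#' @param null_fc_sd SD of null genes' log2FC around 0 (default 0.1).
#' @param obs_se standard error of the observed log2FC in the one-sample z
#'   noise model: observed = true + Normal(0, obs_se), p-value from
#'   z = observed / obs_se; null genes get p ~ Uniform(0, 1) (default 0.15).
#' @param dev_aging_overlap fraction of the aging signature shared with the
#'   development signature (partial disjointness, default 0.2).
#' @param n_background_degs true non-signature DEGs per cell-type list
#'   (default 300).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes_universe = 20000L,
                       n_dev_timepoints = 7L,
                       n_aging_timepoints = 3L,
                       signature_size = 800L,
                       n_models = 19L,
                       concordance_grid = NULL,
                       model_family = NULL,
                       effect_size_link = list(slope = 1, noise_sd = 0.2),
                       n_celltypes = 11L,
                       contributors = c(microglia = 0.55, astrocyte = 0.25),
                       seed = 1L,
                       effect_mu = 1, effect_sd = 0.3, effect_min = 0.3,
                       null_fc_sd = 0.1, obs_se = 0.15,
                       dev_aging_overlap = 0.2,
                       n_background_degs = 300L) {
  if (signature_size > n_genes_universe) {
    stop("invalid config: signature_size exceeds the gene universe",
         call. = FALSE)
  }
  if (is.null(concordance_grid)) {
    n_pos <- max(n_models - 2L, 1L)
    concordance_grid <- c(seq(0.9, 0.3, length.out = n_pos),
                          c(-0.4, -0.7)[seq_len(n_models - n_pos)])
  }
  if (length(concordance_grid) != n_models) {
    stop("invalid config: concordance_grid must have one entry per model",
         call. = FALSE)
  }
  if (any(abs(concordance_grid) > 1)) {
    stop("invalid config: concordance fractions must lie in [-1, 1]",
         call. = FALSE)
  }
  if (is.null(model_family)) model_family <- rep("development", n_models)
  if (length(model_family) == 1L) model_family <- rep(model_family, n_models)
  if (length(model_family) != n_models ||
      !all(model_family %in% c("development", "aging"))) {
    stop("invalid config: model_family must give 'development' or 'aging' ",
         "per model", call. = FALSE)
  }
  stopifnot(is.numeric(effect_size_link$slope),
            is.numeric(effect_size_link$noise_sd),
            effect_size_link$noise_sd >= 0)
  if (length(contributors) &&
      (is.null(names(contributors)) || any(contributors < 0 | contributors > 1))) {
    stop("contributors must be a named vector of shares in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(n_genes_universe = as.integer(n_genes_universe),
         n_dev_timepoints = as.integer(n_dev_timepoints),
         n_aging_timepoints = as.integer(n_aging_timepoints),
         signature_size = as.integer(signature_size),
         n_models = as.integer(n_models),
         concordance_grid = as.numeric(concordance_grid),
         model_family = model_family,
         effect_size_link = effect_size_link,
         n_celltypes = as.integer(n_celltypes),
         contributors = contributors,
         seed = as.integer(seed),
         effect_mu = effect_mu, effect_sd = effect_sd, effect_min = effect_min,
         null_fc_sd = null_fc_sd, obs_se = obs_se,
         dev_aging_overlap = dev_aging_overlap,
         n_background_degs = as.integer(n_background_degs)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d genes, %d+%d references ",
                     "(signature %d), %d models, %d cell types, seed %d\n"),
              x$n_genes_universe, x$n_dev_timepoints, x$n_aging_timepoints,
              x$signature_size, x$n_models, x$n_celltypes, x$seed))
  invisible(x)
}

# |log2FC| from Normal(mu, sd) truncated below at lo (rejection sampling)
rtrunc_abs_effect <- function(n, mu, sd, lo) {
  out <- stats::rnorm(n, mu, sd)
  bad <- which(out < lo)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mu, sd)
    bad <- bad[out[bad] < lo]
  }
  out
}

# Full-universe record table: null background everywhere, true effects for
# `genes` with signed magnitudes `effects`; p-values from the one-sample z
# model for true DEGs and Uniform(0,1) for null genes.
simulate_records <- function(universe, genes, effects, cfg) {
  n <- length(universe)
  log2fc <- stats::rnorm(n, 0, cfg$null_fc_sd)
  pvalue <- stats::runif(n)
  if (length(genes)) {
    i <- match(genes, universe)
    obs <- effects + stats::rnorm(length(genes), 0, cfg$obs_se)
    log2fc[i] <- obs
    pvalue[i] <- pmax(2 * stats::pnorm(-abs(obs) / cfg$obs_se), 1e-300)
  }
  data.frame(gene_id = universe, log2fc = log2fc, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

sim_universe <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes_universe))

# Deterministic signature assignments shared by all generators.
sim_truth <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    universe <- sim_universe(cfg)
    half <- cfg$signature_size %/% 2
    dev_genes <- sample(universe, cfg$signature_size)
    dev_dir <- rep(c(1, -1), length.out = cfg$signature_size)
    n_shared <- round(cfg$dev_aging_overlap * cfg$signature_size)
    aging_genes <- c(sample(dev_genes, n_shared),
                     sample(setdiff(universe, dev_genes),
                            cfg$signature_size - n_shared))
    aging_dir <- sample(c(1, -1), cfg$signature_size, replace = TRUE)
    # per-gene persistence controls which timepoints a gene is active in
    list(universe = universe,
         development = data.frame(gene_id = dev_genes, direction = dev_dir,
                                  persistence = stats::runif(cfg$signature_size),
                                  stringsAsFactors = FALSE),
         aging = data.frame(gene_id = aging_genes, direction = aging_dir,
                            persistence = stats::runif(cfg$signature_size),
                            stringsAsFactors = FALSE),
         n_up = half)
  })
}

#' Simulate the developmental and aging reference panels
#'
#' Developmental timepoints share a common core signature whose per-gene
#' effect magnitude decays monotonically toward the adult endpoint
#' (emulating convergence to adulthood), with a nested activation scheme so
#' adjacent timepoints share at least ~85% of their active signature genes.
#' Aging timepoints share a distinct, partially disjoint signature whose
#' magnitude grows with age. Every list covers the whole universe; null
#' genes carry Normal(0, `null_fc_sd`) log2FC and Uniform(0,1) p-values.
#'
#' @param config a [sim_config()].
#' @return list with `references` (named list of [deg_list()]; names like
#'   `dev_08d`, `aging_16m`), and `truth` (signature tables with per-gene
#'   directions, the active genes per timepoint, and the universe).
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  ages_d <- if (config$n_dev_timepoints == 7L) {
    c(8, 11, 14, 17, 21, 25, 29)
  } else {
    seq_len(config$n_dev_timepoints)
  }
  ages_m <- if (config$n_aging_timepoints == 3L) {
    c(16, 24, 29)
  } else {
    seq_len(config$n_aging_timepoints)
  }
  dev_names <- sprintf("dev_%02dd", ages_d)
  aging_names <- sprintf("aging_%02dm", ages_m)

  dev_keep <- seq(1, 0.85, length.out = config$n_dev_timepoints)
  dev_decay <- seq(1, 0.45, length.out = config$n_dev_timepoints)
  aging_keep <- seq(0.75, 1, length.out = config$n_aging_timepoints)
  aging_gain <- seq(0.6, 1, length.out = config$n_aging_timepoints)

  refs <- list(); active <- list()
  base_mag <- with_seed(derive_seed(config$seed, 2L), {
    list(development = rtrunc_abs_effect(config$signature_size,
                                         config$effect_mu, config$effect_sd,
                                         config$effect_min),
         aging = rtrunc_abs_effect(config$signature_size, config$effect_mu,
                                   config$effect_sd, config$effect_min))
  })
  build <- function(family, name, keep, scale_fac, offset) {
    sig <- truth[[family]]
    on_genes <- sig$persistence <= keep
    genes <- sig$gene_id[on_genes]
    effects <- sig$direction[on_genes] * base_mag[[family]][on_genes] * scale_fac
    rec <- with_seed(derive_seed(config$seed, offset),
                     simulate_records(truth$universe, genes, effects, config))
    active[[name]] <<- genes
    deg_list(rec, dataset_id = name, species = "mouse",
             region = "hippocampus DG",
             life_stage = if (family == "development") "juvenile" else "aged",
             universe = truth$universe)
  }
  for (t in seq_len(config$n_dev_timepoints)) {
    refs[[dev_names[t]]] <- build("development", dev_names[t], dev_keep[t],
                                  dev_decay[t], 10L + t)
  }
  for (t in seq_len(config$n_aging_timepoints)) {
    refs[[aging_names[t]]] <- build("aging", aging_names[t], aging_keep[t],
                                    aging_gain[t], 40L + t)
  }
  truth$active <- active
  list(references = refs, truth = truth)
}

#' Simulate one model dataset with planted concordance
#'
#' A fraction |f| of the chosen reference signature is differentially
#' expressed in the model — in the reference's direction when f > 0
#' (planted hyper-maturity / accelerated aging) and in the opposite
#' direction when f < 0 (planted immaturity). The remaining DEGs are drawn
#' from non-signature genes with random directions so every model carries
#' `signature_size` true DEGs in total. Ground truth (planted genes,
#' directions, f, family) is attached as attribute `truth`.
#'
#' @param config a [sim_config()].
#' @param model_index 1-based model index (`<= n_models`).
#' @param truth optional precomputed truth from
#'   [simulate_reference_panel()]; regenerated deterministically if omitted.
#' @return a [deg_list()] covering the whole universe, with a `truth`
#'   attribute.
#' @export
simulate_model_dataset <- function(config, model_index, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (model_index < 1 || model_index > config$n_models) {
    stop("model_index must be in 1..n_models", call. = FALSE)
  }
  if (is.null(truth)) truth <- sim_truth(config)
  f <- config$concordance_grid[model_index]
  family <- config$model_family[model_index]
  sig <- truth[[family]]

  with_seed(derive_seed(config$seed, 100L + model_index), {
    n_planted <- round(abs(f) * config$signature_size)
    planted_rows <- if (n_planted > 0) {
      sort(sample.int(config$signature_size, n_planted))
    } else {
      integer(0)
    }
    planted <- data.frame(
      gene_id = sig$gene_id[planted_rows],
      direction = sign(f) * sig$direction[planted_rows],
      source = rep("signature", n_planted),
      stringsAsFactors = FALSE
    )
    n_bg <- config$signature_size - n_planted
    bg_pool <- setdiff(truth$universe,
                       c(truth$development$gene_id, truth$aging$gene_id))
    background <- data.frame(
      gene_id = sample(bg_pool, n_bg),
      direction = sample(c(1, -1), n_bg, replace = TRUE),
      source = rep("background", n_bg),
      stringsAsFactors = FALSE
    )
    tru <- rbind(planted, background)
    mags <- rtrunc_abs_effect(nrow(tru), config$effect_mu, config$effect_sd,
                              config$effect_min)
    rec <- simulate_records(truth$universe, tru$gene_id,
                            tru$direction * mags, config)
    out <- deg_list(rec, dataset_id = sprintf("model_%02d", model_index),
                    species = "mouse", region = "hippocampus DG",
                    life_stage = "adult", universe = truth$universe)
    attr(out, "truth") <- list(planted = tru, f = f, family = family)
    out
  })
}

#' Simulate a behavioral summary table linked to planted maturity
#'
#' Each model receives 1-3 anxiety-related measures drawn from a pool with
#' both polarities (e.g. time in open arms, polarity -1; latency to enter
#' the light box, polarity +1). Each measure's true polarity-adjusted
#' effect size is d = slope * f + Normal(0, noise_sd); the written group
#' means and SDs reproduce that population d exactly, so the generated
#' table is the population-level summary (no additional sampling noise).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `model`, `measure`, `polarity`,
#'   `mean_model`, `sd_model`, `n_model`, `mean_control`, `sd_control`,
#'   `n_control`; per-model true effects are attached as attribute `truth`
#'   (`model`, `f`, `d_true`).
#' @export
simulate_behavior_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pool <- data.frame(
    measure = c("time_in_open_arms", "open_arm_entries", "time_in_light_box",
                "latency_to_light_box", "thigmotaxis_time",
                "marble_burying_count"),
    polarity = c(-1, -1, -1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  slope <- config$effect_size_link$slope
  noise <- config$effect_size_link$noise_sd
  with_seed(derive_seed(config$seed, 3L), {
    rows <- list(); d_model <- numeric(config$n_models)
    for (i in seq_len(config$n_models)) {
      f <- config$concordance_grid[i]
      k <- sample(1:3, 1)
      picks <- pool[sample.int(nrow(pool), k), , drop = FALSE]
      d_true <- slope * f + stats::rnorm(k, 0, noise)
      s <- stats::runif(k, 0.8, 1.2)  # same SD both groups => S_pooled = s
      rows[[i]] <- data.frame(
        model = sprintf("model_%02d", i),
        measure = picks$measure,
        polarity = picks$polarity,
        mean_model = 10 + picks$polarity * d_true * s,
        sd_model = s, n_model = 10L,
        mean_control = 10, sd_control = s, n_control = 10L,
        stringsAsFactors = FALSE
      )
      d_model[i] <- mean(d_true)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- data.frame(
      model = sprintf("model_%02d", seq_len(config$n_models)),
      f = config$concordance_grid, d_true = d_model,
      stringsAsFactors = FALSE
    )
    out
  })
}

#' Simulate a per-cell-type aging DEG atlas
#'
#' Generates one old-vs-young DEG list per cell type over the shared
#' universe. Designated contributor cell types carry a planted share of the
#' aging reference signature (concordant directions); all cell types carry
#' `n_background_degs` unrelated true DEGs. Ground-truth contributor
#' identities and planted genes are attached as attribute `truth`.
#'
#' @param config a [sim_config()].
#' @param truth optional truth from [simulate_reference_panel()].
#' @return named list of [deg_list()] (the atlas) with attribute `truth`.
#' @export
simulate_celltype_atlas <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- sim_truth(config)
  names11 <- c("astrocyte", "qNSC", "aNSPC", "neuroblast", "granule_cell",
               "cajal_retzius", "OPC", "endothelial", "pericyte", "SMC",
               "microglia")
  ct_names <- if (config$n_celltypes == 11L) {
    names11
  } else {
    sprintf("celltype_%02d", seq_len(config$n_celltypes))
  }
  shares <- stats::setNames(rep(0, length(ct_names)), ct_names)
  if (length(config$contributors)) {
    unknown <- setdiff(names(config$contributors), ct_names)
    if (length(unknown)) {
      stop("unknown contributor cell type(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    shares[names(config$contributors)] <- config$contributors
  }
  sig <- truth$aging
  bg_pool <- setdiff(truth$universe,
                     c(truth$development$gene_id, truth$aging$gene_id))
  atlas <- list(); planted_genes <- list()
  for (k in seq_along(ct_names)) {
    ct <- ct_names[k]
    built <- with_seed(derive_seed(config$seed, 200L + k), {
      n_planted <- round(shares[ct] * config$signature_size)
      rows <- if (n_planted > 0) {
        sort(sample.int(config$signature_size, n_planted))
      } else {
        integer(0)
      }
      genes <- c(sig$gene_id[rows], sample(bg_pool, config$n_background_degs))
      dirs <- c(sig$direction[rows],
                sample(c(1, -1), config$n_background_degs, replace = TRUE))
      mags <- rtrunc_abs_effect(length(genes), config$effect_mu,
                                config$effect_sd, config$effect_min)
      rec <- simulate_records(truth$universe, genes, dirs * mags, config)
      list(planted = sig$gene_id[rows],
           deg = deg_list(rec, dataset_id = paste0("celltype_", ct),
                          species = "mouse", region = "hippocampus DG",
                          life_stage = "aged", universe = truth$universe))
    })
    atlas[[ct]] <- built$deg
    planted_genes[[ct]] <- built$planted
  }
  attr(atlas, "truth") <- list(
    contributors = names(shares)[shares > 0],
    shares = shares, planted = planted_genes
  )
  atlas
}

#' Simulate a gene-set collection seeded from the signature
#'
#' One planted term (`CORE_MATURATION_PROGRAM`) contains a large sample of
#' the development signature genes; the remaining terms are random decoys
#' drawn from the universe. Used to exercise enrichment recovery.
#'
#' @param config a [sim_config()].
#' @param truth optional truth from [simulate_reference_panel()].
#' @param n_terms total number of terms (default 50).
#' @param planted_fraction fraction of signature genes in the planted term
#'   (default 0.7).
#' @param term_size_range decoy term sizes, sampled uniformly (default
#'   40-200).
#' @return a [gene_set_collection()] with attribute `planted_term`.
#' @export
simulate_gene_sets <- function(config, truth = NULL, n_terms = 50L,
                               planted_fraction = 0.7,
                               term_size_range = c(40L, 200L)) {
  stopifnot(inherits(config, "sim_config"), n_terms >= 2)
  if (is.null(truth)) truth <- sim_truth(config)
  with_seed(derive_seed(config$seed, 4L), {
    planted <- sample(truth$development$gene_id,
                      round(planted_fraction * config$signature_size))
    sets <- list(CORE_MATURATION_PROGRAM = planted)
    term_names <- c(CORE_MATURATION_PROGRAM = "planted maturation program")
    for (k in seq_len(n_terms - 1L)) {
      id <- sprintf("DECOY_%03d", k)
      sz <- sample(seq(term_size_range[1], term_size_range[2]), 1)
      sets[[id]] <- sample(truth$universe, sz)
      term_names[id] <- sprintf("random decoy pathway %d", k)
    }
    out <- gene_set_collection(sets, term_names = term_names,
                               name = "synthetic_collection")
    attr(out, "planted_term") <- "CORE_MATURATION_PROGRAM"
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper generating the reference panel, all model datasets,
#' the behavioral table, the cell-type atlas and the gene-set collection
#' under one configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `maturity_cohort` with elements `config`, `panel`,
#'   `models` (named list), `behavior`, `atlas`, `gene_sets`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  panel <- simulate_reference_panel(config)
  models <- lapply(seq_len(config$n_models), simulate_model_dataset,
                   config = config, truth = panel$truth)
  names(models) <- vapply(models, `[[`, character(1), "dataset_id")
  structure(
    list(config = config, panel = panel, models = models,
         behavior = simulate_behavior_table(config),
         atlas = simulate_celltype_atlas(config, panel$truth),
         gene_sets = simulate_gene_sets(config, panel$truth)),
    class = "maturity_cohort"
  )
}

#' @export
print.maturity_cohort <- function(x, ...) {
  cat(sprintf(paste0("<maturity_cohort> %d models, %d references, ",
                     "%d cell types (seed %d)\n"),
              length(x$models), length(x$panel$references),
              length(x$atlas), x$config$seed))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes every reference and model DEG table, the behavioral table, the
#' atlas, the gene-set collection (GMT) and plain tab-separated ground-truth
#' sidecars under `dir`, plus a `manifest.yaml` listing the files and the
#' generating configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_simulation <- function(config, dir) {
  cohort <- simulate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    name
  }
  for (nm in names(cohort$panel$references)) {
    files[[paste0("reference_", nm)]] <-
      wt(cohort$panel$references[[nm]]$records, paste0(nm, ".tsv"))
  }
  for (nm in names(cohort$models)) {
    files[[nm]] <- wt(cohort$models[[nm]]$records, paste0(nm, ".tsv"))
    tru <- attr(cohort$models[[nm]], "truth")
    files[[paste0(nm, "_truth")]] <-
      wt(tru$planted, paste0(nm, "_truth.tsv"))
  }
  files$behavior <- wt(cohort$behavior, "behavior.tsv")
  files$behavior_truth <- wt(attr(cohort$behavior, "truth"),
                             "behavior_truth.tsv")
  for (nm in names(cohort$atlas)) {
    files[[paste0("atlas_", nm)]] <-
      wt(cohort$atlas[[nm]]$records, paste0("atlas_", nm, ".tsv"))
  }
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  files$gene_sets <- "gene_sets.gmt"
  files$dev_signature <- wt(cohort$panel$truth$development,
                            "dev_signature_truth.tsv")
  files$aging_signature <- wt(cohort$panel$truth$aging,
                              "aging_signature_truth.tsv")
  manifest <- list(
    seed = config$seed,
    n_genes_universe = config$n_genes_universe,
    n_models = config$n_models,
    concordance_grid = config$concordance_grid,
    model_family = config$model_family,
    files = files
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
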