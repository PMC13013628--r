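test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_cfg(seed = 5)
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1, p2)
  expect_identical(simulate_model_dataset(cfg, 2, p1$truth),
                   simulate_model_dataset(cfg, 2, p1$truth))
  expect_identical(simulate_behavior_table(cfg), simulate_behavior_table(cfg))
  expect_identical(simulate_celltype_atlas(cfg, p1$truth),
                   simulate_celltype_atlas(cfg, p1$truth))
  # a different seed changes the data
  expect_false(identical(
    p1$references[[1]]$records,
    simulate_reference_panel(tiny_cfg(seed = 6))$references[[1]]$records))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(simulate_reference_panel(tiny_cfg()))
  expect_identical(rnorm(3), before)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_genes_universe = 100, signature_size = 800),
               "signature_size")
  expect_error(sim_config(n_models = 2, concordance_grid = c(0.5, 1.5)),
               "\\[-1, 1\\]")
  expect_error(sim_config(n_models = 3, concordance_grid = c(0.5, 0.5)),
               "one entry per model")
  expect_error(tiny_cfg(contributors = c(not_a_celltype = 0.5)) |>
                 simulate_celltype_atlas(), "unknown contributor")
})

test_that("adjacent developmental timepoints share their signature core", {
  panel <- simulate_reference_panel(tiny_cfg(seed = 2))
  active <- panel$truth$active[grep("^dev", names(panel$truth$active))]
  for (t in seq_len(length(active) - 1)) {
    shared <- length(intersect(active[[t]], active[[t + 1]]))
    frac <- shared / max(lengths(active[t:(t + 1)]))
    expect_gte(frac, 0.8)
  }
  # effect magnitudes decay monotonically for a persistently active gene
  always_on <- Reduce(intersect, active)
  g <- always_on[1]
  mags <- vapply(panel$references[names(active)], function(d) {
    abs(d$records$log2fc[d$records$gene_id == g])
  }, numeric(1))
  # observed magnitudes are noisy; compare first vs last timepoint
  expect_gt(mags[1], mags[length(mags)])
})

test_that("null genes carry uniform p-values", {
  cfg <- sim_config(n_genes_universe = 6000, signature_size = 400,
                    n_models = 2, concordance_grid = c(0.5, 0),
                    seed = 31)
  panel <- simulate_reference_panel(cfg)
  d <- panel$references$dev_08d
  null_p <- d$records$pvalue[!d$records$gene_id %in% panel$truth$active$dev_08d]
  expect_gte(length(null_p), 5000)
  expect_gt(stats::ks.test(null_p[1:5000], "punif")$p.value, 0.01)
})

test_that("planted concordance is honored at the extremes", {
  cfg <- sim_config(n_genes_universe = 4000, signature_size = 200,
                    n_models = 3, concordance_grid = c(1, -0.5, 0),
                    n_background_degs = 100, seed = 9)
  panel <- simulate_reference_panel(cfg)

  # f = +1: every signature gene planted, all concordant
  m1 <- simulate_model_dataset(cfg, 1, panel$truth)
  tru <- attr(m1, "truth")
  sig <- panel$truth$development
  expect_setequal(tru$planted$gene_id[tru$planted$source == "signature"],
                  sig$gene_id)
  expect_equal(
    tru$planted$direction[match(sig$gene_id, tru$planted$gene_id)],
    sig$direction)

  # f = -0.5: overall discordant against the development reference
  m2 <- apply_filter(simulate_model_dataset(cfg, 2, panel$truth))
  ref <- apply_filter(panel$references$dev_08d)
  expect_identical(compare_datasets(m2, ref)$sign, -1L)

  # f = 0: nothing planted from the signature
  m3 <- attr(simulate_model_dataset(cfg, 3, panel$truth), "truth")
  expect_equal(sum(m3$planted$source == "signature"), 0)
})

test_that("behavior tables encode the planted effect sizes exactly", {
  cfg0 <- sim_config(n_models = 4, concordance_grid = c(0.5, 0.2, -0.3, 0),
                     effect_size_link = list(slope = 1, noise_sd = 0),
                     seed = 4)
  beh <- simulate_behavior_table(cfg0)
  d <- vapply(seq_len(nrow(beh)), function(i) cohens_d(beh[i, ])$d_adjusted,
              numeric(1))
  expect_equal(d, cfg0$concordance_grid[
    as.integer(sub("model_", "", beh$model))], tolerance = 1e-10)

  # with noise, stored truth matches the realized population d
  cfg1 <- tiny_cfg(seed = 8)
  beh1 <- simulate_behavior_table(cfg1)
  eff <- anxiety_effect_sizes(beh1)
  tru <- attr(beh1, "truth")
  expect_equal(eff$models$anxiety_index[match(tru$model, eff$models$model)],
               tru$d_true, tolerance = 1e-10)
})

test_that("SEM-reported behavior tables are converted on ingestion", {
  path <- temp_tsv()
  writeLines(c(paste("model measure polarity mean_model sem_model n_model",
                     "mean_control sem_control n_control"),
               "m1 open_arms -1 8 0.5 10 10 0.5 10"),
             sep = "\n", con = path)
  tab <- utils::read.table(path, header = TRUE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  beh <- read_behavior_table(path)
  expect_equal(beh$sd_model, 0.5 * sqrt(10), tolerance = 1e-6)
  expect_equal(beh$sd_control, 1.5811, tolerance = 1e-4)
})

test_that("atlas plants contributors and records ground truth", {
  cfg <- tiny_cfg(seed = 12)
  atlas <- simulate_celltype_atlas(cfg)
  expect_length(atlas, cfg$n_celltypes)
  tru <- attr(atlas, "truth")
  expect_setequal(tru$contributors, c("microglia", "astrocyte"))
  expect_equal(length(tru$planted$microglia),
               round(0.55 * cfg$signature_size))
  expect_length(tru$planted$granule_cell, 0)

  null_atlas <- simulate_celltype_atlas(tiny_cfg(seed = 12,
                                                 contributors = numeric(0)))
  expect_length(attr(null_atlas, "truth")$contributors, 0)
})

test_that("gene-set simulation seeds one term from the signature", {
  cfg <- tiny_cfg(seed = 3)
  gs <- simulate_gene_sets(cfg, n_terms = 20)
  expect_s3_class(gs, "gene_set_collection")
  expect_length(gs, 20)
  planted <- attr(gs, "planted_term")
  sig <- sim_truth_genes <- simulate_reference_panel(cfg)$truth$development$gene_id
  expect_true(all(gs$sets[[planted]] %in% toupper(sig)))
})

test_that("a written simulation is complete and reloadable", {
  cfg <- tiny_cfg(seed = 14)
  dir <- file.path(tempdir(), "simrun")
  manifest_path <- write_simulation(cfg, dir)
  man <- yaml::read_yaml(manifest_path)
  expect_equal(man$seed, 14)
  expect_true(all(file.exists(file.path(dir, unlist(man$files)))))
  m1 <- read_deg_table(file.path(dir, "model_01.tsv"), "model_01")
  expect_equal(nrow(m1$records), cfg$n_genes_universe)
  gs <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_s3_class(gs, "gene_set_collection")
  unlink(dir, recursive = TRUE)
})
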