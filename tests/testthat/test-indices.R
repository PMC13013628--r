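test_that("the signed -log10 index follows its conventions", {
  expect_equal(maturity_index(1e-10, 1), 10)
  expect_equal(maturity_index(1e-10, -1), -10)
  expect_equal(maturity_index(1, 1), 0)
  expect_equal(maturity_index(1, -1), 0)
  expect_error(maturity_index(0, 1), "domain")
  expect_error(maturity_index(-0.5, 1), "domain")
  expect_error(maturity_index(0.5, 2), "sign")
  # exact log path bypasses the 1e-300 floor
  expect_equal(maturity_index(0, -1, log10_p = -1000), -1000)
  # strictly decreasing in p for positive sign
  ps <- sort(runif(20, 1e-12, 1))
  expect_true(all(diff(vapply(ps, maturity_index, numeric(1),
                              sign = 1)) < 0))
})

test_that("Cohen's d uses the unweighted pooled SD exactly", {
  expect_equal(cohens_d(list(mean_model = 5, sd_model = 2,
                             mean_control = 3, sd_control = 2))$d_raw, 1)
  expect_equal(cohens_d(list(mean_model = 4, sd_model = 1.3,
                             mean_control = 4, sd_control = 0.7))$d_raw, 0)
  d <- cohens_d(list(mean_model = 10, sd_model = 3,
                     mean_control = 8, sd_control = 1))
  expect_equal(d$d_raw, 2 / sqrt(5), tolerance = 1e-9)
  expect_equal(d$s_pooled, sqrt(5), tolerance = 1e-9)
  expect_error(cohens_d(list(mean_model = 1, sd_model = 0,
                             mean_control = 0, sd_control = 0)), "undefined")

  # polarity flips the adjusted effect only
  m <- list(mean_model = 6, sd_model = 1, mean_control = 5, sd_control = 1,
            polarity = -1)
  dd <- cohens_d(m)
  expect_equal(dd$d_adjusted, -dd$d_raw)

  # scale invariance: multiplying means and SDs by c > 0 leaves d unchanged
  set.seed(1)
  for (i in 1:10) {
    base <- list(mean_model = rnorm(1, 10), sd_model = runif(1, 0.5, 2),
                 mean_control = rnorm(1, 10), sd_control = runif(1, 0.5, 2))
    cc <- runif(1, 0.1, 50)
    scaled <- lapply(base, `*`, cc)
    expect_equal(cohens_d(scaled)$d_raw, cohens_d(base)$d_raw,
                 tolerance = 1e-9)
  }
})

test_that("model anxiety index averages polarity-adjusted effects", {
  one <- data.frame(mean_model = 6, sd_model = 1, mean_control = 5,
                    sd_control = 1, polarity = 1)
  expect_equal(model_anxiety_index(one), 1)

  two <- data.frame(mean_model = c(6, 4.2), sd_model = 1,
                    mean_control = c(5.6, 5), sd_control = 1,
                    polarity = c(1, -1))
  expect_equal(model_anxiety_index(two), mean(c(0.4, 0.8)), tolerance = 1e-9)
  expect_error(model_anxiety_index(two[0, ]), "no behavioral")
})

test_that("family summaries pick the most significant comparison", {
  m <- structure(matrix(c(2, 11, -1, -12, 3, 5), nrow = 2, byrow = TRUE,
                        dimnames = list(c("m1", "m2"), c("a", "b", "c"))),
                 class = c("index_table", "matrix"))
  s <- model_maturity_summary(m)
  expect_equal(unname(s), c(11, -12))
  expect_equal(unname(model_maturity_summary(m, method = "mean")),
               c(4, -4/3), tolerance = 1e-9)
  expect_equal(unname(model_maturity_summary(m, columns = "b",
                                             method = "column",
                                             column = "b")), c(11, 3))
  expect_error(model_maturity_summary(m, columns = character(0)), "family")
})

test_that("Pearson correlation and its t-based p-value are exact", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlate_indices(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-10)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)

  set.seed(2)
  a <- rnorm(19); b <- rnorm(19)
  res2 <- correlate_indices(a, b)
  ct <- stats::cor.test(a, b)
  expect_equal(res2$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(res2$p, ct$p.value, tolerance = 1e-10)

  expect_error(correlate_indices(1:2, 2:3), "n >= 3")
  expect_error(correlate_indices(rep(1, 5), rnorm(5)), "variance")
})

test_that("the correlation p-value is uniform under independence", {
  set.seed(77)
  ps <- replicate(1000, pearson_p_from_r(cor(rnorm(19), rnorm(19)), 19))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("index tables recover planted structure end to end", {
  cfg <- tiny_cfg(seed = 20)
  panel <- simulate_reference_panel(cfg)
  refs <- lapply(panel$references[1:3], apply_filter)
  models <- lapply(seq_len(cfg$n_models), function(i) {
    apply_filter(simulate_model_dataset(cfg, i, panel$truth))
  })
  names(models) <- sprintf("model_%02d", seq_len(cfg$n_models))
  idx <- compute_index_table(models, refs,
                             n_universe = cfg$n_genes_universe)
  expect_equal(dim(idx), c(cfg$n_models, 3))
  maturity <- model_maturity_summary(idx)
  # planted ordering recovered (strong > weak > discordant)
  expect_gte(cor(cfg$concordance_grid, maturity, method = "spearman"), 0.9)
  expect_lt(maturity[5], 0)  # the f = -0.5 model scores negative
})
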