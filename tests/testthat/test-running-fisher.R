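# exhaustive enumeration oracle for the hypergeometric upper tail:
# probability that a random k_b-subset of 1..n shares >= ov elements with a
# fixed k_a-subset
enum_tail <- function(k_a, k_b, ov, n) {
  if (k_b == 0) return(as.numeric(ov <= 0))
  sets <- utils::combn(n, k_b)
  mean(colSums(sets <= k_a) >= ov)
}

test_that("ranking splits by sign and orders by effect, p-value, gene id", {
  deg <- make_deg(c("A", "B", "C"), c(1, -0.5, 0.6), c(0.01, 0.02, 0.03))
  r <- rank_by_effect(deg)
  expect_equal(r$up, c("A", "C"))
  expect_equal(r$down, "B")

  tie <- make_deg(c("N", "M"), c(0.5, 0.5), c(0.02, 0.01))
  expect_equal(rank_by_effect(tie)$up, c("M", "N"))

  tie2 <- make_deg(c("N", "M"), c(0.5, 0.5), c(0.01, 0.01))
  expect_equal(rank_by_effect(tie2)$up, c("M", "N"))

  all_up <- make_deg(c("A", "B"), c(1, 2), c(0.01, 0.01))
  expect_length(rank_by_effect(all_up)$down, 0)

  zero <- make_deg(c("A", "B"), c(1, 0), c(0.01, 0.01))
  expect_warning(rz <- rank_by_effect(zero), "zero log2fc")
  expect_equal(rz$up, "A")
})

test_that("hypergeometric tail matches closed forms and enumeration", {
  expect_equal(hypergeom_overlap_p(3, 3, 3, 10), 1 / choose(10, 3),
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(5, 4, 0, 30), 1)
  expect_equal(hypergeom_overlap_p(10, 4, 4, 10), 1)  # k_a = N forces overlap
  expect_error(hypergeom_overlap_p(5, 5, 6, 10), "domain")
  expect_error(hypergeom_overlap_p(11, 5, 2, 10), "domain")

  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    k_a <- sample(0:n, 1)
    k_b <- sample(0:n, 1)
    ov <- sample(0:min(k_a, k_b), 1)
    expect_equal(hypergeom_overlap_p(k_a, k_b, ov, n),
                 enum_tail(k_a, k_b, ov, n), tolerance = 1e-12,
                 info = sprintf("N=%d k_a=%d k_b=%d ov=%d", n, k_a, k_b, ov))
  }
})

test_that("Fisher combination of two p-values follows the chi-squared form", {
  expect_equal(fisher_combine(1, 1), 1)
  # chi^2(4 df) survival at -2 ln(0.25) = 2.7726: exp(-x/2) (1 + x/2)
  expect_equal(fisher_combine(0.5, 0.5), 0.5965736, tolerance = 1e-6)
  expect_equal(fisher_combine(0.2, 0.9), fisher_combine(0.9, 0.2))
  expect_lt(fisher_combine(0.001, 0.001), 0.001)
  # log-scale path agrees with the linear path
  expect_equal(fisher_combine(log(0.03), log(0.4), log_p = TRUE),
               log(fisher_combine(0.03, 0.4)), tolerance = 1e-10)
})

test_that("rank-scan overlap behaves at the extremes", {
  genes <- sprintf("S%03d", 1:50)
  idres <- running_overlap_p(genes, genes, 20000)
  expect_lt(idres$log10_pvalue, -50)
  expect_equal(idres$shared_at_full, sort(genes))

  dis <- running_overlap_p(sprintf("A%02d", 1:30), sprintf("B%02d", 1:30),
                           20000)
  expect_equal(dis$pvalue, 1)
  expect_length(dis$shared_at_full, 0)

  expect_equal(running_overlap_p(character(0), genes, 20000)$pvalue, 1)
})

test_that("a single-cutoff scan reduces to the plain hypergeometric test", {
  set.seed(11)
  full <- scan_config(cutoff_fractions = 1, correction = "none")
  for (i in 1:20) {
    n <- 200
    a <- sample(sprintf("G%03d", 1:n), 25)
    b <- sample(sprintf("G%03d", 1:n), 40)
    res <- running_overlap_p(a, b, n, scan = full)
    expect_equal(res$pvalue,
                 hypergeom_overlap_p(25, 40, length(intersect(a, b)), n),
                 tolerance = 1e-12)
  }
})

test_that("directional comparison obeys the sign conventions", {
  x <- random_deg(80, id = "x", seed = 3)
  self <- compare_datasets(x, x)
  expect_identical(self$sign, 1L)
  expect_equal(self$quadrants$up_down$overlap, 0)
  expect_equal(self$quadrants$down_up$overlap, 0)
  expect_equal(self$overall_p, min(self$concordant_p, self$discordant_p))

  flipped <- compare_datasets(x, negate_deg(x))
  expect_identical(flipped$sign, -1L)
  expect_equal(flipped$overall_log10_p, self$overall_log10_p)

  # negating both arguments restores the sign
  both <- compare_datasets(negate_deg(x), negate_deg(x))
  expect_identical(both$sign, 1L)

  conc <- extract_concordant_genes(self)
  r <- rank_by_effect(x)
  expect_setequal(conc$up_shared, r$up)
  expect_setequal(conc$down_shared, r$down)
})

test_that("the four quadrant shared-gene sets are pairwise disjoint", {
  a <- random_deg(70, id = "a", seed = 5)
  b <- random_deg(70, id = "b", seed = 6)
  # force substantial overlap with mixed directions
  b$records$gene_id[1:30] <- a$records$gene_id[1:30]
  so <- compare_datasets(a, b)
  shared <- lapply(so$quadrants, `[[`, "shared_genes")
  all_genes <- unlist(shared)
  expect_equal(anyDuplicated(all_genes), 0)
  for (q in so$quadrants) {
    expect_true(q$overlap <= min(q$k_a, q$k_b))
    expect_true(q$pvalue > 0 && q$pvalue <= 1)
  }
})

test_that("adding a top-ranked concordant shared gene never hurts", {
  set.seed(21)
  for (i in 1:15) {
    a <- random_deg(30, id = "a")
    b <- random_deg(30, id = "b")
    b$records$gene_id[1:10] <- a$records$gene_id[1:10]
    b$records$log2fc[1:10] <- a$records$log2fc[1:10]
    base <- compare_datasets(a, b)
    add <- data.frame(gene_id = "ZZTOP", log2fc = 5, pvalue = 1e-8)
    a2 <- a; a2$records <- rbind(a$records, add)
    b2 <- b; b2$records <- rbind(b$records, add)
    more <- compare_datasets(a2, b2)
    expect_lte(more$overall_log10_p, base$overall_log10_p + 1e-9)
  }
})

test_that("scan configuration validates its grid", {
  expect_error(scan_config(c(0.5, 0.2, 1)), "increasing")
  expect_error(scan_config(c(0.2, 0.5)), "last")
  expect_error(scan_config(numeric(0)))
  expect_silent(scan_config(c(0.25, 0.5, 0.75, 1)))
})
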