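# shared fixtures: build everything in code, no stored data

make_deg <- function(gene_id, log2fc, pvalue, id = "x", ...) {
  deg_list(data.frame(gene_id = gene_id, log2fc = log2fc, pvalue = pvalue,
                      stringsAsFactors = FALSE),
           dataset_id = id, ...)
}

# small, already-filtered random signed DEG list over a numbered universe
random_deg <- function(n = 60, id = "r", universe_n = 20000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sample(sprintf("G%05d", seq_len(universe_n)), n)
  make_deg(genes,
           log2fc = sample(c(-1, 1), n, TRUE) * runif(n, 0.4, 2),
           pvalue = runif(n, 1e-6, 0.04), id = id)
}

# reduced-size study configuration for fast unit tests
tiny_cfg <- function(...) {
  sim_config(n_genes_universe = 4000L, signature_size = 200L,
             n_models = 6L,
             concordance_grid = c(0.9, 0.6, 0.4, 0.2, -0.5, 0),
             n_background_degs = 100L, ...)
}

# the toy five-record table used for filter-fidelity checks
toy_filter_deg <- function() {
  make_deg(c("g1", "g2", "g3", "g4", "g5"),
           log2fc = c(0.585, -0.378, 0.138, 1.0, 0.322),
           pvalue = c(0.01, 0.04, 0.001, 0.06, 0.05))
}

temp_tsv <- function() tempfile(fileext = ".tsv")
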