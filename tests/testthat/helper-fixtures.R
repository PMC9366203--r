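# programmatic fixtures shared across test files

random_counts <- function(n_genes, n_samples, seed = 1, mu_log_sd = 1.5, size = 10) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = exp(rnorm(n_genes, 5, mu_log_sd)), size = size),
              n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

tiny_annotation <- function(counts) {
  g <- nrow(counts)
  tibble::tibble(
    gene_id = rownames(counts), symbol = toupper(rownames(counts)),
    name = paste("gene", seq_len(g)), chrom = "chr1",
    start = as.integer(seq_len(g) * 10000L), end = as.integer(seq_len(g) * 10000L + 999L),
    strand = "+", length = 1000L)
}

null_cohort_config <- function(n_donors = 60, n_genes = 500, seed = 1) {
  simulation_config(
    n_donors = n_donors, n_genes = n_genes, n_t2d = round(n_donors / 4),
    n_t2d_hba1c_only = 0, n_igt = round(n_donors / 12),
    frac_purity_genes = 0, n_de_genes = 0, n_eqtl_genes = 0,
    n_variants_per_gene = 0, coexpr_module_size = 0, n_batches = 1,
    purity_t2d_shift = 0, seed = seed)
}

# textbook step-up BH, written straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
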