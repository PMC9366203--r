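test_that("spearman_rho handles ties by average ranks", {
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 4)), 0.9487, tolerance = 1e-4)
  expect_equal(spearman_rho(1:10, exp(1:10)), 1)
  set.seed(30)
  for (i in 1:100) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(spearman_rho(x, y), -spearman_rho(x, -y), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
})

test_that("the correlation null is deterministic, sorted, and sized as configured", {
  set.seed(31)
  lc <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(sprintf("g%02d", 1:40), NULL))
  expect_equal(formals(build_null)$n_pairs, 1e6)
  a <- build_null(lc, n_pairs = 2000, seed = 5)
  b <- build_null(lc, n_pairs = 2000, seed = 5)
  expect_identical(a$abs_rho_sorted, b$abs_rho_sorted)
  expect_equal(length(a$abs_rho_sorted), 2000)
  expect_true(!is.unsorted(a$abs_rho_sorted))
  expect_true(all(a$abs_rho_sorted >= 0 & a$abs_rho_sorted <= 1))
  expect_error(build_null(lc, n_pairs = 0), "positive")
})

test_that("background |rho| under independence matches the n=100 sampling scale", {
  set.seed(32)
  lc <- matrix(rnorm(300 * 100), 300, 100,
               dimnames = list(sprintf("g%03d", 1:300), sprintf("s%03d", 1:100)))
  null <- build_null(lc, n_pairs = 20000, seed = 6)
  med <- median(null$abs_rho_sorted)
  expect_gt(med, 0.04); expect_lt(med, 0.10)
})

test_that("empirical p-values equal exhaustive counting with a 1/n floor", {
  null <- structure(list(abs_rho_sorted = c(0.1, 0.2, 0.3, 0.9), n_pairs = 4L,
                         seed = 1L, gene_universe_hash = "x"),
                    class = "correlation_null")
  expect_equal(empirical_pvalue(0.25, null), 0.5)
  expect_equal(empirical_pvalue(0, null), 1)
  expect_equal(empirical_pvalue(0.95, null), 1 / 4)        # floor rule
  expect_equal(empirical_pvalue(0.95, null, floor = FALSE), 0)
  expect_equal(empirical_pvalue(0.2, null), 3 / 4)         # tie counts as extreme
  expect_equal(empirical_pvalue(-0.25, null), 0.5)         # two-sided on |rho|
})

test_that("p_emp is a non-increasing step function of |rho|", {
  set.seed(33)
  null <- structure(list(abs_rho_sorted = sort(runif(500)), n_pairs = 500L,
                         seed = 1L, gene_universe_hash = "x"),
                    class = "correlation_null")
  r <- seq(0, 1, by = 0.01)
  p <- empirical_pvalue(r, null)
  expect_true(all(diff(p) <= 0))
  expect_equal(p[1], 1)
})

test_that("coexpressed_with ranks by |rho| and respects the universe hash", {
  set.seed(34)
  lc <- matrix(rnorm(30 * 25), 30, 25, dimnames = list(sprintf("g%02d", 1:30), NULL))
  lc["g02", ] <- lc["g01", ]   # duplicate gene
  null <- build_null(lc, n_pairs = 1000, seed = 7)
  expect_equal(formals(coexpressed_with)$k, 100)
  top <- coexpressed_with("g01", lc, null, k = 5)
  expect_equal(top$gene_b[1], "g02")
  expect_equal(top$rho[1], 1)
  full <- coexpressed_with("g01", lc, null, k = 500)
  expect_equal(nrow(full), 29)   # no padding beyond the universe
  expect_error(coexpressed_with("nope", lc, null), "not in the expression universe")
  expect_error(coexpressed_with("g05", lc[-1, ], null), "different gene universe")
  # symmetry of the underlying correlation
  ab <- coexpressed_with("g05", lc, null, k = 29)
  ba <- coexpressed_with("g09", lc, null, k = 29)
  expect_equal(ab$rho[ab$gene_b == "g09"], ba$rho[ba$gene_b == "g05"], tolerance = 1e-12)
})

test_that("random-pair empirical p-values are approximately uniform under independence", {
  set.seed(35)
  lc <- matrix(rnorm(200 * 60), 200, 60, dimnames = list(sprintf("g%03d", 1:200), NULL))
  null <- build_null(lc, n_pairs = 20000, seed = 8)
  z <- isletview:::rank_standardize(lc)
  a <- sample(200, 10000, replace = TRUE)
  b <- sample(200, 10000, replace = TRUE)
  ok <- a != b
  rho <- rowSums(z[a[ok], ] * z[b[ok], ])
  p <- empirical_pvalue(rho, null)
  expect_gt(mean(p), 0.45); expect_lt(mean(p), 0.55)
})

test_that("hormone panel reports all six hormones with significance calls", {
  cfg <- simulation_config(n_donors = 80, n_genes = 300, n_t2d = 16,
                           n_t2d_hba1c_only = 0, n_igt = 10, n_de_genes = 0,
                           n_eqtl_genes = 0, n_variants_per_gene = 0,
                           frac_purity_genes = 0, n_batches = 1,
                           coexpr_module_size = 20, coexpr_loading = 1, seed = 36)
  co <- simulate_cohort(cfg)
  lc <- log2cpm(co$counts)
  null <- build_null(lc, n_pairs = 20000, seed = 9)
  ins_id <- co$annotation$gene_id[co$annotation$symbol == "INS"]
  hp <- hormone_panel(ins_id, lc, null, co$annotation)
  expect_equal(nrow(hp), 6)
  expect_equal(hp$rho[hp$hormone == "INS"], 1)
  member <- co$truth$coexpr_modules$GCG[1]
  hp2 <- hormone_panel(member, lc, null, co$annotation)
  expect_true(hp2$significant[hp2$hormone == "GCG"])
  # missing hormone produces a partial result with a warning
  ann2 <- co$annotation[co$annotation$symbol != "GHRL", ]
  expect_warning(hp3 <- hormone_panel(ins_id, lc, null, ann2), "GHRL")
  expect_equal(nrow(hp3), 5)
})

test_that("null objects survive the text round trip", {
  set.seed(37)
  lc <- matrix(rnorm(20 * 15), 20, 15, dimnames = list(sprintf("g%02d", 1:20), NULL))
  null <- build_null(lc, n_pairs = 500, seed = 10)
  path <- withr::local_tempfile(fileext = ".txt")
  write_null(null, path)
  back <- read_null(path)
  expect_equal(back$abs_rho_sorted, null$abs_rho_sorted, tolerance = 1e-15)
  expect_equal(back$gene_universe_hash, null$gene_universe_hash)
  expect_equal(empirical_pvalue(0.4, back), empirical_pvalue(0.4, null))
})
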