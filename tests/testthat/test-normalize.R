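test_that("sample depth filter is strict at the 10 million read boundary", {
  counts <- matrix(c(9999999L, 10000000L, 30000000L), 1, 3,
                   dimnames = list("g1", c("low", "edge", "high")))
  f <- filter_samples(counts)
  expect_equal(colnames(f$counts), c("edge", "high"))
  expect_equal(f$removed$sample, "low")

  depths <- c(5e6, 12e6, 30e6)
  m <- vapply(depths, function(d) rmultinom(1, d, rep(1, 50))[, 1], numeric(50))
  dimnames(m) <- list(sprintf("g%02d", 1:50), c("a", "b", "c"))
  f2 <- filter_samples(m)
  expect_equal(f2$removed$sample, "a")
  expect_error(filter_samples(m, min_reads = 1e12), "all samples removed")
})

test_that("fpkm matches its closed form", {
  counts <- matrix(c(10L, 0L), 1, 2, dimnames = list("g1", c("a", "b")))
  out <- fpkm(counts, lengths = 1000, lib_sizes = c(1e7, 1e7))
  expect_equal(unname(out[1, ]), c(1, 0))
  set.seed(4)
  m <- random_counts(30, 5)
  len <- sample(200:5000, 30)
  lib <- colSums(m)
  ref <- m * NA
  for (g in 1:30) for (s in 1:5) ref[g, s] <- m[g, s] * 1e9 / (len[g] * lib[s])
  expect_equal(fpkm(m, len), ref, tolerance = 1e-12)
  expect_error(fpkm(m, len, lib_sizes = rep(0, 5)), "zero library size")
})

test_that("gene filter applies detection-fraction and mean-FPKM rules", {
  fk <- matrix(1.5, 3, 100, dimnames = list(c("gA", "gB", "gC"), sprintf("s%03d", 1:100)))
  fk["gA", 1:6] <- 0          # detected in 94% < 95%
  fk["gB", ] <- 0.9           # detected everywhere, mean below 1
  out <- filter_genes(fk)
  expect_equal(out$retained, "gC")
  fk["gC", ] <- 0
  expect_length(filter_genes(fk)$retained, 0)
})

test_that("TMM factors are 1 for equal-composition libraries and shift for planted DE", {
  m <- random_counts(300, 2, seed = 9)
  m[, 2] <- m[, 1]
  expect_equal(unname(tmm_factors(m)$factors), c(1, 1))
  m2 <- cbind(a = m[, 1], b = 2L * m[, 1])
  rownames(m2) <- rownames(m)
  expect_equal(unname(tmm_factors(m2)$factors), c(1, 1), tolerance = 1e-9)

  m3 <- random_counts(500, 2, seed = 10)
  m3[1:100, 2] <- m3[1:100, 2] * 8L   # 20% of genes 8-fold up in B only
  f <- tmm_factors(m3)$factors
  expect_lt(unname(f["s02"]), 1)
  expect_equal(unname(prod(f)), 1, tolerance = 1e-9)
})

test_that("TMM matches the independent edgeR implementation", {
  skip_if_not_installed("edgeR")
  m <- random_counts(800, 5, seed = 11)
  m[1:150, 3] <- m[1:150, 3] * 4L
  mine <- tmm_factors(m)$factors
  ref <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  expect_equal(unname(mine), ref, tolerance = 1e-9)
})

test_that("log2-CPM follows its closed form and is scale invariant", {
  counts <- matrix(0L, 1, 1, dimnames = list("g", "s"))
  out <- log2cpm(counts, lib_sizes = 1e6, factors = 1)
  expect_equal(unname(out[1, 1]), log2(0.5 / 1000001 * 1e6), tolerance = 1e-9)

  m <- random_counts(50, 4, seed = 12)
  a <- log2cpm(m, colSums(m))
  b <- log2cpm(2L * m, 2 * colSums(m))
  expect_equal(a, b, tolerance = 1e-3)
  # independent re-derivation
  lib <- colSums(m)
  ref <- log2(sweep(m + 0.5, 2, lib + 1, `/`) * 1e6)
  expect_equal(log2cpm(m), ref, tolerance = 1e-12)
})

test_that("precision weights are positive, flat on homoskedastic data and track abundance", {
  set.seed(13)
  design <- cbind(1, rep(0:1, each = 10))
  flat <- matrix(2^rnorm(200 * 20, 8, 0.05), 200, 20,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:20)))
  storage.mode(flat) <- "integer"
  w_flat <- precision_weights(flat, design)
  expect_true(all(w_flat > 0))
  expect_lt(max(w_flat) / min(w_flat), 1.5)

  nb <- random_counts(400, 20, seed = 14)
  w <- precision_weights(nb, design)
  expect_true(all(w > 0 & is.finite(w)))
  expect_gt(cor(rowMeans(w), rowMeans(nb), method = "spearman"), 0)
})

test_that("precision weights reproduce the limma voom scheme", {
  skip_if_not_installed("limma")
  m <- random_counts(500, 12, seed = 15)
  design <- cbind(1, rep(0:1, each = 6))
  v <- limma::voom(m, design, lib.size = colSums(m))
  w <- precision_weights(m, design)
  expect_equal(unname(w), unname(v$weights), tolerance = 1e-8)
})

test_that("batch adjustment is the identity for one batch and removes planted offsets", {
  set.seed(16)
  x <- matrix(rnorm(100 * 30, 6), 100, 30,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:30)))
  expect_identical(batch_adjust(x, rep("b1", 30)), x)
  expect_error(batch_adjust(x, c(rep("b1", 29), "lonely")), "lonely")

  batch <- rep(c("b1", "b2"), each = 15)
  x2 <- x
  x2[, batch == "b2"] <- x2[, batch == "b2"] + 1
  adj <- batch_adjust(x2, batch)
  gap <- rowMeans(adj[, batch == "b2"]) - rowMeans(adj[, batch == "b1"])
  expect_lt(abs(mean(gap)), 0.05)
  expect_identical(dim(adj), dim(x2))
  expect_identical(rownames(adj), rownames(x2))
})

test_that("batch adjustment matches the sva parametric ComBat and spares variances", {
  skip_if_not_installed("sva")
  set.seed(17)
  x <- matrix(rnorm(200 * 40, 5, 1.2), 200, 40,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:40)))
  batch <- rep(c("b1", "b2"), each = 20)
  x[, batch == "b2"] <- x[, batch == "b2"] + rnorm(200, 0.8, 0.3)
  mine <- batch_adjust(x, batch)
  ref <- suppressMessages(sva::ComBat(x, batch = batch))
  # iteration stopping rules differ slightly; agreement far below data scale
  expect_equal(mine, ref, tolerance = 1e-5)

  # randomized labels must not shrink gene variances appreciably
  rand <- sample(batch)
  adj <- batch_adjust(x, rand)
  ratio <- apply(adj, 1, var) / apply(x, 1, var)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("purity correlation recovers exact monotone relations", {
  purity <- seq(40, 100, length.out = 20)
  x <- rbind(up = purity * 0.1 + 3, down = -purity * 0.05 + 9,
             flat = rep(5, 20) + rep(c(-0.01, 0.01), 10))
  colnames(x) <- sprintf("s%02d", 1:20)
  out <- purity_correlation(x, purity)
  expect_equal(out$rho[out$gene_id == "up"], 1)
  expect_equal(out$rho[out$gene_id == "down"], -1)
  expect_error(purity_correlation(x, rep(80, 20)), "constant")
})

test_that("independent genes rarely show strong purity correlation", {
  set.seed(18)
  hits <- 0
  for (rep in 1:200) {
    x <- matrix(rnorm(100), 1, 100)
    colnames(x) <- sprintf("s%03d", 1:100); rownames(x) <- "g"
    rho <- purity_correlation(x, runif(100, 40, 100))$rho
    hits <- hits + (abs(rho) < 0.3)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("expressed mask uses a strict >80% rule", {
  cpm_target <- function(n_hi, n) c(rep(2000L, n_hi), rep(0L, n - n_hi))
  counts <- rbind(hi = cpm_target(10, 12), lo = cpm_target(9, 12), zero = rep(0L, 12))
  # add a filler gene so library sizes are nonzero everywhere
  counts <- rbind(counts, fill = rep(1000000L, 12))
  colnames(counts) <- sprintf("s%02d", 1:12)
  mask <- expressed_mask(counts, rep("islet", 12))
  expect_true(mask$islet[mask$gene_id == "hi"])     # 10/12 = 83%
  expect_false(mask$islet[mask$gene_id == "lo"])    # 9/12 = 75%
  expect_false(mask$islet[mask$gene_id == "zero"])
})

test_that("gene filtering composed with fpkm is idempotent", {
  co <- simulate_cohort(null_cohort_config(n_donors = 20, n_genes = 150, seed = 19))
  expr <- prepare_expression(co$counts, co$annotation)
  lengths <- setNames(co$annotation$length, co$annotation$gene_id)
  fk <- fpkm(expr$counts, lengths[rownames(expr$counts)], expr$lib_sizes)
  again <- filter_genes(fk)
  expect_setequal(again$retained, rownames(expr$counts))
})
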