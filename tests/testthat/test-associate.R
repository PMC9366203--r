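test_that("glycemic strata follow the HbA1c boundaries and the clinical flag", {
  md <- tibble::tibble(
    donor_id = sprintf("d%d", 1:6), tissue = "islet",
    clinical_t2d = c(FALSE, TRUE, FALSE, FALSE, FALSE, NA),
    hba1c = c(6.2, 5.8, 6.8, 5.9, 6.5, NA),
    bmi = 25, sex = "F", age = 50, purity = 80, stimulatory_index = 3,
    batch = "b1")
  out <- suppressWarnings(assign_strata(md))
  expect_equal(as.character(out$stratum[1]), "IGT")    # 6.2, no diagnosis
  expect_equal(as.character(out$stratum[2]), "T2D")    # clinical flag dominates
  expect_true(out$in_de_contrast[2])
  expect_equal(as.character(out$stratum[3]), "T2D")    # 6.8 by HbA1c only
  expect_false(out$in_de_contrast[3])                  # excluded from DE contrast
  expect_equal(as.character(out$stratum[4]), "NGT")
  expect_equal(as.character(out$stratum[5]), "T2D")    # boundary 6.5 is T2D
  expect_false(out$usable[6])
  expect_warning(assign_strata(md), "neither")
})

test_that("design matrices encode each phenotype with the expected columns", {
  set.seed(20)
  md <- tibble::tibble(
    donor_id = sprintf("d%02d", 1:40), tissue = "islet",
    clinical_t2d = rep(c(TRUE, FALSE), c(10, 30)),
    hba1c = c(runif(10, 6.6, 9), runif(10, 6, 6.4), runif(20, 5, 5.9)),
    bmi = rnorm(40, 27), sex = rep(c("M", "F"), 20), age = runif(40, 30, 70),
    purity = runif(40, 40, 100), stimulatory_index = exp(rnorm(40)),
    batch = "b1")
  md <- assign_strata(md)
  d1 <- build_design(md, "t2d_status")
  expect_equal(ncol(d1$design), 5)       # intercept + t2d + purity + sex + age
  expect_equal(d1$term, "t2d")
  d2 <- build_design(md, "hba1c_stratum")
  expect_equal(ncol(d2$design), 6)
  expect_setequal(d2$term, c("stratumIGT", "stratumT2D"))
  md_same_sex <- dplyr::mutate(md, sex = "F")
  expect_warning(d3 <- build_design(md_same_sex, "t2d_status"), "constant")
  expect_equal(ncol(d3$design), 4)
  md_coll <- dplyr::mutate(md, age = purity)
  expect_error(build_design(md_coll, "t2d_status"), "collinear")
})

test_that("missing phenotype rows are dropped only for that phenotype", {
  co <- simulate_cohort(null_cohort_config(n_donors = 30, n_genes = 80, seed = 21))
  md <- co$metadata
  md$stimulatory_index[1:5] <- NA
  md <- assign_strata(md)
  dsi <- build_design(md, "stimulatory_index")
  expect_equal(length(dsi$dropped), 5)
  dbmi <- build_design(md, "bmi")
  expect_equal(length(dbmi$dropped), 0)
})

test_that("unmoderated fits equal an independent per-gene weighted regression", {
  co <- simulate_cohort(null_cohort_config(n_donors = 40, n_genes = 60, seed = 22))
  expr <- prepare_expression(co$counts, co$annotation)
  md <- assign_strata(co$metadata)
  des <- build_design(md, "t2d_status")
  set.seed(23)
  w <- matrix(runif(nrow(expr$logcpm) * length(des$samples), 0.5, 2),
              nrow(expr$logcpm), dimnames = list(rownames(expr$logcpm), des$samples))
  fit <- fit_linear(expr$logcpm, des, weights = w, moderation = FALSE)
  for (g in rownames(expr$logcpm)[c(1, 7, 20)]) {
    df <- data.frame(y = expr$logcpm[g, des$samples],
                     t2d = des$design[, "t2d"], purity = des$design[, "purity"],
                     sexM = des$design[, colnames(des$design)[4]],
                     age = des$design[, "age"])
    ref <- summary(lm(y ~ t2d + purity + sexM + age, data = df, weights = w[g, ]))
    row <- fit[fit$gene_id == g, ]
    expect_equal(row$beta, unname(coef(ref)["t2d", 1]), tolerance = 1e-8)
    expect_equal(row$statistic, unname(coef(ref)["t2d", 3]), tolerance = 1e-8)
    expect_equal(row$p, unname(coef(ref)["t2d", 4]), tolerance = 1e-8)
  }
})

test_that("a noiseless linear phenotype relation gives r2 1 and vanishing p", {
  co <- simulate_cohort(null_cohort_config(n_donors = 40, n_genes = 50, seed = 24))
  expr <- prepare_expression(co$counts, co$annotation)
  md <- assign_strata(co$metadata)
  des <- build_design(md, "bmi", covariates = character(0))
  lc <- expr$logcpm
  g1 <- rownames(lc)[1]
  lc[g1, des$samples] <- 2 + 0.3 * des$design[, "bmi"]
  fit <- fit_linear(lc, des, moderation = FALSE)
  row <- fit[fit$gene_id == g1, ]
  expect_equal(row$r2, 1, tolerance = 1e-9)
  expect_lt(row$p, 1e-30)
  expect_equal(row$beta, 0.3, tolerance = 1e-9)
})

test_that("moderated and ordinary t agree in sign and converge as the prior vanishes", {
  co <- simulate_cohort(null_cohort_config(n_donors = 36, n_genes = 120, seed = 25))
  expr <- prepare_expression(co$counts, co$annotation)
  md <- assign_strata(co$metadata[co$metadata$donor_id %in% colnames(expr$logcpm), ])
  des <- build_design(md, "t2d_status")
  mod <- fit_linear(expr$logcpm, des, moderation = TRUE)
  ord <- fit_linear(expr$logcpm, des, moderation = FALSE)
  expect_true(all(sign(mod$statistic) == sign(ord$statistic)))
  expect_gt(attr(mod, "d0"), 0)
  # identical variances force d0 -> Inf and a common posterior variance equal
  # to the log-scale bias-corrected pooled estimate
  sq <- isletview:::squeeze_variances(rep(2, 50), d = 10)
  expect_equal(sq$d0, Inf)
  expect_equal(sq$s2_post, rep(2 * (10 / 2) / exp(digamma(10 / 2)), 50), tolerance = 1e-12)
  # a huge residual df leaves the variances essentially unshrunk
  set.seed(99)
  s2 <- exp(rnorm(200))
  sq2 <- isletview:::squeeze_variances(s2, d = 1e5)
  expect_equal(sq2$s2_post, s2, tolerance = 1e-2)
})

test_that("moderated statistics match the independent limma implementation", {
  skip_if_not_installed("limma")
  m <- random_counts(300, 16, seed = 26)
  design <- cbind(`(Intercept)` = 1, grp = rep(0:1, each = 8))
  lc <- log2cpm(m)
  fit <- fit_linear(lc, design = design, term = "grp")
  eb <- limma::eBayes(limma::lmFit(lc, design))
  expect_equal(attr(fit, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(fit$statistic, unname(eb$t[, "grp"]), tolerance = 1e-8)
  expect_equal(fit$p, unname(eb$p.value[, "grp"]), tolerance = 1e-8)
})

test_that("stratum association reports a joint test plus per-stratum contrasts", {
  cfg <- simulation_config(n_donors = 60, n_genes = 100, n_t2d = 15, n_igt = 12,
                           n_t2d_hba1c_only = 0, n_de_genes = 0, n_eqtl_genes = 0,
                           n_variants_per_gene = 0, coexpr_module_size = 0,
                           frac_purity_genes = 0, n_batches = 1, seed = 27)
  co <- simulate_cohort(cfg)
  expr <- prepare_expression(co$counts, co$annotation)
  res <- associate_phenotype(expr, co$metadata, "hba1c_stratum")
  expect_true(all(is.na(res$beta)))
  expect_true(all(res$statistic >= 0))
  con <- attr(res, "contrasts")
  expect_setequal(unique(con$contrast), c("stratumIGT", "stratumT2D"))
  expect_equal(nrow(con), 2 * nrow(res))
})

test_that("BH adjustment and percentage ranks match their definitions", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)), c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(28)
  p <- runif(200)
  perm <- sample(200)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))

  p100 <- c(0.001, runif(99, 0.01, 1))
  expect_equal(percentage_rank(p100)[1], 1)
  expect_equal(max(percentage_rank(p100)), 100)
  tied <- c(0.001, 0.001, runif(98, 0.01, 1))
  expect_equal(percentage_rank(tied)[1:2], c(1.5, 1.5))
})

test_that("association fits carry tidy and glance methods", {
  co <- simulate_cohort(null_cohort_config(n_donors = 30, n_genes = 60, seed = 29))
  expr <- prepare_expression(co$counts, co$annotation)
  res <- associate_phenotype(expr, co$metadata, "t2d_status")
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "islet_fit"))
  gl <- generics::glance(res)
  expect_equal(gl$n_genes, nrow(res))
  expect_true(all(res$fdr >= res$p))
  expect_true(all(res$rank_pct > 0 & res$rank_pct <= 100))
})
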