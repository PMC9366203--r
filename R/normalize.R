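#' Remove low-depth samples
#'
#' Samples whose total read count is strictly below `min_reads` are excluded
#' (the default mirrors the common 10-million-read cutoff for bulk RNA-seq).
#'
#' @param counts Gene-by-sample count matrix.
#' @param min_reads Minimum total reads per sample (default 1e7).
#' @return List with `counts` (retained columns, order preserved) and
#'   `removed` (tibble of sample id and library size).
#' @export
filter_samples <- function(counts, min_reads = 1e7) {
  lib <- colSums(counts)
  keep <- lib >= min_reads
  if (!any(keep)) abort("all samples removed by the read-depth filter")
  list(counts = counts[, keep, drop = FALSE],
       removed = tibble(sample = colnames(counts)[!keep], lib_size = unname(lib[!keep])))
}

#' Fragments per kilobase per million mapped reads
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * lib_size[s])`.
#'
#' @param counts Gene-by-sample count matrix.
#' @param lengths Exonic lengths in bp, aligned to rows (or named).
#' @param lib_sizes Per-sample totals; defaults to column sums.
#' @return FPKM matrix of the same shape.
#' @export
fpkm <- function(counts, lengths, lib_sizes = colSums(counts)) {
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || anyNA(lengths)) {
    abort("lengths must cover every gene in counts")
  }
  if (any(lengths < 1)) abort("gene lengths must be >= 1")
  if (any(lib_sizes <= 0)) abort("zero library size")
  counts * 1e9 / outer(as.numeric(lengths), as.numeric(lib_sizes))
}

#' Expression-based gene filter
#'
#' Keeps genes detected (FPKM > 0) in at least `frac_nonzero` of samples and
#' with mean FPKM strictly above `min_mean_fpkm`.
#'
#' @param fpkm_mat FPKM matrix computed on the retained samples.
#' @param frac_nonzero Required detection fraction (default 0.95).
#' @param min_mean_fpkm Mean-FPKM cutoff, strict (default 1).
#' @return List with `retained` (gene ids, input order) and `stats` (per-gene
#'   detection fraction, mean FPKM and keep flag).
#' @export
filter_genes <- function(fpkm_mat, frac_nonzero = 0.95, min_mean_fpkm = 1) {
  det <- rowMeans(fpkm_mat > 0)
  mu <- rowMeans(fpkm_mat)
  keep <- det >= frac_nonzero & mu > min_mean_fpkm
  list(retained = rownames(fpkm_mat)[keep],
       stats = tibble(gene_id = rownames(fpkm_mat), frac_nonzero = unname(det),
                      mean_fpkm = unname(mu), retained = unname(keep)))
}

#' Trimmed mean of M-values scale factors
#'
#' Between-sample normalization factors robust to asymmetric differential
#' expression. The reference is the sample whose 75th CPM percentile is
#' closest to the mean 75th percentile. Per sample, M (log2 expression ratio
#' vs reference) and A (mean log2 abundance) are computed over genes nonzero
#' in both; the upper and lower `trim_m` of M and `trim_a` of A are discarded
#' and the factor is 2 to the weighted mean of the retained M-values, weights
#' the inverse asymptotic binomial variances. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts Filtered gene-by-sample count matrix (>= 2 samples).
#' @param lib_sizes Library sizes; defaults to column sums.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return A `tmm_factors` list: `factors` (named, geometric mean 1),
#'   `ref_sample`, `trim_m`, `trim_a`.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts), trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2) abort("TMM needs at least 2 samples")
  cpm_q <- vapply(seq_len(ncol(counts)),
                  function(j) quantile(counts[, j] / lib_sizes[j], 0.75), numeric(1))
  ref <- which.min(abs(cpm_q - mean(cpm_q)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = setNames(f, colnames(counts)),
                 ref_sample = colnames(counts)[ref],
                 trim_m = trim_m, trim_a = trim_a),
            class = "tmm_factors")
}

# single-pair TMM factor (obs vs ref), following the published estimator
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep0 <- obs > 0 & ref > 0
  if (!any(keep0)) abort("no genes nonzero in both sample and TMM reference")
  p_o <- obs[keep0] / n_obs
  p_r <- ref[keep0] / n_ref
  M <- log2(p_o / p_r)
  A <- 0.5 * log2(p_o * p_r)
  if (max(abs(M)) < 1e-6) return(1)
  w <- (n_obs - obs[keep0]) / (n_obs * obs[keep0]) +
       (n_ref - ref[keep0]) / (n_ref * ref[keep0])
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  f <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  if (!is.finite(f)) 1 else f
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("<tmm_factors> reference:", x$ref_sample, "\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6)`, the usual
#' half-count offset convention.
#'
#' @param counts Count matrix.
#' @param lib_sizes Library sizes; defaults to column sums.
#' @param factors A `tmm_factors` object, a numeric vector, or NULL (all 1).
#' @param prior Prior count (default 0.5).
#' @return log2-CPM matrix.
#' @export
log2cpm <- function(counts, lib_sizes = colSums(counts), factors = NULL, prior = 0.5) {
  f <- normalization_factor_vector(factors, colnames(counts), ncol(counts))
  eff <- lib_sizes * f + 2 * prior
  log2(sweep(counts + prior, 2, eff, `/`) * 1e6)
}

normalization_factor_vector <- function(factors, ids, n) {
  if (is.null(factors)) return(rep(1, n))
  f <- if (inherits(factors, "tmm_factors")) factors$factors else factors
  if (!is.null(names(f)) && !is.null(ids)) f <- f[ids]
  if (length(f) != n || anyNA(f) || any(f <= 0)) abort("invalid normalization factors")
  unname(f)
}

#' Counts per million
#' @param counts Count matrix.
#' @param lib_sizes Library sizes; defaults to column sums.
#' @return CPM matrix.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  sweep(counts, 2, lib_sizes, `/`) * 1e6
}

#' Mean-variance precision weights
#'
#' Fits per-gene linear models on log2-CPM, smooths the square-root residual
#' standard deviation against average log2 count with lowess (span 0.5), and
#' returns per-observation weights equal to the predicted standard deviation
#' at the observation's fitted log-count raised to the power -4. With fewer
#' than 10 genes the trend is flat (mean residual sd).
#'
#' @param counts Filtered count matrix.
#' @param design Full-rank model matrix (rows = samples).
#' @param lib_sizes Library sizes; defaults to column sums.
#' @param factors Optional normalization factors (see [log2cpm()]).
#' @param span Lowess span (default 0.5).
#' @return Gene-by-sample matrix of positive weights.
#' @export
precision_weights <- function(counts, design, lib_sizes = colSums(counts),
                              factors = NULL, span = 0.5) {
  n <- ncol(counts)
  if (nrow(design) != n) abort("design rows must match samples")
  if (qr(design)$rank < ncol(design)) abort("design is not full rank")
  if (n < ncol(design) + 1) abort("need more samples than design columns")
  f <- normalization_factor_vector(factors, colnames(counts), n)
  eff <- lib_sizes * f + 1
  y <- log2(sweep(counts + 0.5, 2, eff, `/`) * 1e6)
  fit <- lm.fit(design, t(y))
  res <- t(as.matrix(fit$residuals))
  df <- n - fit$rank
  s <- sqrt(rowSums(res^2) / df)
  sx <- rowMeans(y) + mean(log2(eff)) - log2(1e6)
  sy <- sqrt(s)
  fitted_logcpm <- t(as.matrix(fit$fitted.values))
  fitted_logcount <- sweep(fitted_logcpm, 2, log2(eff) - log2(1e6), `+`)
  if (nrow(counts) < 10 || sd(sx) < 1e-8) {
    pred <- matrix(mean(sy), nrow(counts), n)
  } else {
    lo <- lowess(sx, sy, f = span)
    pred <- matrix(approx(lo$x, lo$y, xout = as.vector(fitted_logcount), rule = 2,
                          ties = mean)$y,
                   nrow(counts), n)
  }
  pred <- pmax(pred, 1e-4)
  w <- pred^-4
  dimnames(w) <- dimnames(counts)
  w
}

#' Parametric empirical-Bayes batch adjustment
#'
#' Location/scale batch correction: per-gene standardization protecting
#' supplied covariates, estimation of per-batch gene means and variances,
#' shrinkage toward batch-level priors by moment matching (normal prior on
#' means, inverse-gamma on variances, solved by fixed-point iteration), then
#' back-transformation. A single batch is returned unchanged.
#'
#' @param x Gene-by-sample matrix (e.g., log2-CPM).
#' @param batch Batch labels, one per sample.
#' @param covariates Optional numeric matrix of covariates to protect
#'   (without intercept).
#' @return Adjusted matrix, same shape and order.
#' @export
batch_adjust <- function(x, batch, covariates = NULL) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) return(x)
  tab <- table(batch)
  if (any(tab < 2)) {
    abort(paste0("batch with a single sample: ", paste(names(tab)[tab < 2], collapse = ", ")))
  }
  n <- ncol(x)
  bdes <- model.matrix(~ 0 + batch)
  design <- if (is.null(covariates)) bdes else cbind(bdes, as.matrix(covariates))
  if (qr(design)$rank < ncol(design)) abort("batch/covariate design is rank-deficient")
  nb <- nlevels(batch)

  beta <- t(solve(crossprod(design), crossprod(design, t(x))))
  grand <- beta[, seq_len(nb), drop = FALSE] %*% (as.numeric(tab) / n)
  stand_mean <- matrix(grand, nrow(x), n)
  if (!is.null(covariates)) {
    stand_mean <- stand_mean +
      beta[, -seq_len(nb), drop = FALSE] %*% t(as.matrix(covariates))
  }
  resid_full <- x - t(design %*% t(beta))
  var_pooled <- rowMeans(resid_full^2)
  var_pooled <- pmax(var_pooled, 1e-12)
  z <- (x - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(solve(crossprod(bdes), crossprod(bdes, t(z))))  # gene x batch
  delta_hat <- matrix(NA_real_, nrow(x), nb)
  for (b in seq_len(nb)) {
    zb <- z[, batch == levels(batch)[b], drop = FALSE]
    delta_hat[, b] <- apply(zb, 1, var)
  }
  z_adj <- z
  for (b in seq_len(nb)) {
    idx <- batch == levels(batch)[b]
    gbar <- mean(gamma_hat[, b]); t2 <- var(gamma_hat[, b])
    d <- delta_hat[, b]
    a_pr <- (2 * var(d) + mean(d)^2) / var(d)
    b_pr <- (mean(d) * var(d) + mean(d)^3) / var(d)
    nb_s <- sum(idx)
    sol <- eb_fixed_point(z[, idx, drop = FALSE], gamma_hat[, b], d,
                          gbar, t2, a_pr, b_pr, nb_s)
    z_adj[, idx] <- (z[, idx, drop = FALSE] - sol$gamma) / sqrt(sol$delta)
  }
  out <- z_adj * sqrt(var_pooled) + stand_mean
  dimnames(out) <- dimnames(x)
  out
}

# joint fixed-point solution of the EB batch mean/variance estimates
eb_fixed_point <- function(zb, g_hat, d_hat, g_bar, t2, a_pr, b_pr, n_b,
                           conv = 1e-4, max_it = 100) {
  g_old <- g_hat; d_old <- d_hat
  for (it in seq_len(max_it)) {
    g_new <- (t2 * n_b * g_hat + d_old * g_bar) / (t2 * n_b + d_old)
    ss <- rowSums((zb - g_new)^2)
    d_new <- (0.5 * ss + b_pr) / (n_b / 2 + a_pr - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-8))
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_old, delta = pmax(d_old, 1e-12))
}

#' Per-gene Spearman correlation with islet purity
#'
#' @param logcpm log2-CPM matrix.
#' @param purity Purity percentages aligned to columns.
#' @return Tibble with `gene_id`, `rho`, `p` (asymptotic t approximation).
#' @export
purity_correlation <- function(logcpm, purity) {
  if (length(purity) != ncol(logcpm) || anyNA(purity)) {
    abort("purity must be present for every sample")
  }
  if (sd(purity) == 0) abort("purity is constant")
  n <- ncol(logcpm)
  rp <- rank(purity)
  rx <- t(apply(logcpm, 1, rank))
  rho <- as.vector(cor(t(rx), rp))
  rho[is.na(rho)] <- 0
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[abs(rho) >= 1] <- 0
  tibble(gene_id = rownames(logcpm), rho = rho, p = p)
}

#' Per-tissue expressed-gene mask
#'
#' A gene is called expressed in a tissue when its CPM is at least `cpm_min`
#' in strictly more than `frac` of that tissue's samples.
#'
#' @param counts Count matrix over all tissue samples.
#' @param tissue Tissue label per sample.
#' @param cpm_min CPM threshold (default 1).
#' @param frac Required fraction, strict (default 0.80).
#' @return Tibble: `gene_id` plus one logical column per tissue.
#' @export
expressed_mask <- function(counts, tissue, cpm_min = 1, frac = 0.80) {
  if (length(tissue) != ncol(counts)) abort("tissue labels must match samples")
  cp <- cpm(counts)
  out <- tibble(gene_id = rownames(counts))
  for (t in sort(unique(tissue))) {
    sub <- cp[, tissue == t, drop = FALSE]
    out[[t]] <- rowMeans(sub >= cpm_min) > frac
  }
  out
}

#' Run the QC and normalization stage
#'
#' Applies the sample depth filter, FPKM-based gene filter, TMM factors and
#' the log2-CPM transform in one call.
#'
#' @param counts Raw gene-by-sample count matrix.
#' @param annotation Annotation tibble supplying exonic lengths.
#' @param min_reads Sample filter cutoff (default 1e7).
#' @param frac_nonzero,min_mean_fpkm Gene filter parameters (0.95, 1).
#' @return An `islet_expression` list: filtered `counts`, `lib_sizes`,
#'   `factors`, `logcpm`, `removed_samples`, `gene_stats`.
#' @export
prepare_expression <- function(counts, annotation, min_reads = 1e7,
                               frac_nonzero = 0.95, min_mean_fpkm = 1) {
  sf <- filter_samples(counts, min_reads = min_reads)
  lengths <- setNames(annotation$length, annotation$gene_id)
  fk <- fpkm(sf$counts, lengths)
  gf <- filter_genes(fk, frac_nonzero = frac_nonzero, min_mean_fpkm = min_mean_fpkm)
  cts <- sf$counts[gf$retained, , drop = FALSE]
  lib <- colSums(sf$counts)   # depth over all genes, fixed before gene filtering
  tf <- tmm_factors(cts, lib_sizes = lib)
  structure(list(counts = cts, lib_sizes = lib, factors = tf,
                 logcpm = log2cpm(cts, lib, tf),
                 removed_samples = sf$removed, gene_stats = gf$stats),
            class = "islet_expression")
}

#' @export
print.islet_expression <- function(x, ...) {
  cat("<islet_expression> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", nrow(x$removed_samples), " samples removed, ",
      sum(!x$gene_stats$retained), " genes filtered)\n", sep = "")
  invisible(x)
}
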