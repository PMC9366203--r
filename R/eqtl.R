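#' Enumerate cis gene-variant pairs
#'
#' A variant is cis to a gene when it lies on the same chromosome within
#' `window` bp of the gene body, boundaries inclusive. Distance is 0 inside
#' the gene body, otherwise the signed distance to the nearest gene edge
#' (negative upstream of `start`).
#'
#' @param annotation Annotation tibble.
#' @param genotypes A `genotype_matrix`.
#' @param window Cis window in bp (default 2e6).
#' @return Tibble `gene_id, variant_id, distance`.
#' @export
cis_pairs <- function(annotation, genotypes, window = 2e6) {
  v <- genotypes$variants
  joined <- dplyr::inner_join(
    annotation[, c("gene_id", "chrom", "start", "end")],
    v[, c("variant_id", "chrom", "pos")],
    by = "chrom", relationship = "many-to-many")
  joined <- dplyr::filter(joined, .data$pos >= .data$start - window,
                          .data$pos <= .data$end + window)
  dplyr::transmute(
    joined, gene_id = .data$gene_id, variant_id = .data$variant_id,
    distance = dplyr::case_when(
      pos < start ~ as.numeric(pos - start),
      pos > end ~ as.numeric(pos - end),
      TRUE ~ 0
    ))
}

#' Residualize rows of a matrix on covariates
#'
#' Each row is replaced by its residuals from ordinary least squares on the
#' covariates plus an intercept.
#'
#' @param x Matrix (features in rows, samples in columns).
#' @param covariates Optional numeric covariate matrix (samples in rows,
#'   no intercept column needed).
#' @return Residual matrix of the same shape.
#' @export
residualize <- function(x, covariates = NULL) {
  n <- ncol(x)
  X <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) abort("covariate matrix is rank-deficient")
  qx <- qr.Q(qr(X))
  out <- x - (x %*% qx) %*% t(qx)
  dimnames(out) <- dimnames(x)
  out
}

#' cis-eQTL scan
#'
#' For every cis pair, regresses residualized expression on residualized
#' allele dosage. The t statistic is `r * sqrt(d / (1 - r^2))` with residual
#' degrees of freedom `d = n - 1 - rank(intercept + covariates)`; p-values
#' are two-sided from the t distribution and the FDR is BH-adjusted across
#' all emitted tests. Pairs whose dosage has zero variance after
#' residualization are skipped and counted.
#'
#' @param expression Gene-by-sample matrix (batch-adjusted log2-CPM).
#' @param genotypes A `genotype_matrix` with matching samples.
#' @param pairs Tibble from [cis_pairs()] (or with the same columns).
#' @param covariates Optional covariate matrix (samples in rows); the scan
#'   default is none beyond upstream batch adjustment.
#' @return `islet_eqtl` tibble: `variant_id, gene_id, beta, se, t, p, fdr,
#'   distance, ea` (effect allele fixed to alt); skipped-pair count in
#'   `attr(, "skipped")`.
#' @export
eqtl_scan <- function(expression, genotypes, pairs, covariates = NULL) {
  samples <- intersect(colnames(expression), colnames(genotypes$dosage))
  if (length(samples) < 4) abort("too few shared samples between expression and genotypes")
  E <- expression[, samples, drop = FALSE]
  D <- genotypes$dosage[, samples, drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) {
      covariates <- covariates[samples, , drop = FALSE]
    } else if (nrow(covariates) != ncol(expression)) {
      abort("covariates must be named by sample or aligned to the expression columns")
    } else {
      covariates <- covariates[match(samples, colnames(expression)), , drop = FALSE]
    }
  }
  n <- length(samples)
  q_cov <- qr(if (is.null(covariates)) matrix(1, n, 1) else cbind(1, covariates))$rank
  d <- n - 1L - q_cov
  if (d <= 0) abort("no residual degrees of freedom in the eQTL scan")

  pairs <- dplyr::filter(pairs, .data$gene_id %in% rownames(E),
                         .data$variant_id %in% rownames(D))
  if (nrow(pairs) == 0) {
    out <- tibble(variant_id = character(), gene_id = character(), beta = numeric(),
                  se = numeric(), t = numeric(), p = numeric(), fdr = numeric(),
                  distance = numeric(), ea = character())
    attr(out, "skipped") <- 0L
    class(out) <- c("islet_eqtl", class(out))
    return(out)
  }
  Er <- residualize(E[unique(pairs$gene_id), , drop = FALSE], covariates)
  Dr <- residualize(D[unique(pairs$variant_id), , drop = FALSE], covariates)
  e_sd <- sqrt(rowSums(Er^2))
  g_sd <- sqrt(rowSums(Dr^2))

  gi <- match(pairs$gene_id, rownames(Er))
  vi <- match(pairs$variant_id, rownames(Dr))
  ok <- g_sd[vi] > 1e-12 & e_sd[gi] > 1e-12
  skipped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]; gi <- gi[ok]; vi <- vi[ok]

  num <- rowSums(Er[gi, , drop = FALSE] * Dr[vi, , drop = FALSE])
  r <- num / (e_sd[gi] * g_sd[vi])
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(d / pmax(1 - r^2, 1e-300))
  beta <- num / g_sd[vi]^2
  se <- ifelse(abs(tstat) > 0, beta / tstat, NA_real_)
  # se via residual variance when t == 0
  resvar <- (e_sd[gi]^2 - beta * num) / d
  se[!is.finite(se)] <- sqrt(pmax(resvar[!is.finite(se)], 0)) / g_sd[vi][!is.finite(se)]
  p <- 2 * pt(-abs(tstat), d)
  av <- genotypes$variants$alt[match(pairs$variant_id, genotypes$variants$variant_id)]
  out <- tibble(variant_id = pairs$variant_id, gene_id = pairs$gene_id,
                beta = unname(beta), se = unname(se), t = unname(tstat),
                p = unname(p), fdr = bh_adjust(unname(p)),
                distance = pairs$distance, ea = av)
  attr(out, "skipped") <- skipped
  attr(out, "df") <- d
  class(out) <- c("islet_eqtl", class(out))
  out
}

#' Per-gene eQTL summaries
#'
#' The lead eQTL per gene is the record with the smallest p (ties broken by
#' smaller absolute distance, then variant id); `top` holds the k best
#' records per gene sorted by p.
#'
#' @param records An eQTL record tibble from [eqtl_scan()].
#' @param k Records per gene to keep (default 10).
#' @return List with `lead` (one row per gene) and `top` (up to k rows per
#'   gene).
#' @export
eqtl_summaries <- function(records, k = 10) {
  if (nrow(records) == 0) return(list(lead = records, top = records))
  ord <- records %>%
    arrange(.data$gene_id, .data$p, abs(.data$distance), .data$variant_id)
  top <- ord %>% group_by(.data$gene_id) %>% slice_head(n = k) %>% ungroup()
  lead <- ord %>% group_by(.data$gene_id) %>% slice_head(n = 1) %>% ungroup()
  list(lead = lead, top = top)
}
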