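#' Bootstrap test for coexpression enrichment of a gene set
#'
#' Tests whether a gene set is enriched for genes co-expressed with a target
#' gene (typically an islet hormone gene). The statistic is the mean
#' empirical coexpression p-value of the set against the target; the null
#' distribution is formed by repeatedly drawing random gene sets of the same
#' size from the expression universe (target excluded, without replacement
#' within a set) and recomputing the mean. Small means indicate enrichment;
#' the bootstrap p uses the add-one rule and is never exactly zero.
#'
#' @param gene_set Character vector of gene ids (>= 2, subset of the
#'   universe).
#' @param target_gene Gene id of the coexpression target.
#' @param logcpm Expression matrix over the null's gene universe.
#' @param null A `correlation_null` built on the same universe.
#' @param B Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param two_sided Double the tail for a two-sided test (default FALSE).
#' @return An `enrichment_result` list: `set_size`, `observed_stat`,
#'   `null_stats` (length B), `p_boot`, `B`, `seed`.
#' @export
bootstrap_enrichment <- function(gene_set, target_gene, logcpm, null,
                                 B = 10000, seed = 1L, two_sided = FALSE) {
  check_null_universe(null, logcpm)
  gene_set <- unique(gene_set)
  if (length(gene_set) < 2) abort("gene_set must contain at least 2 genes")
  missing <- setdiff(gene_set, rownames(logcpm))
  if (length(missing)) {
    abort(paste0("gene_set members not in the universe: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  if (!target_gene %in% rownames(logcpm)) abort("target gene not in the universe")
  gene_set <- setdiff(gene_set, target_gene)

  z <- rank_standardize(logcpm)
  rho <- as.vector(z %*% z[target_gene, ])
  names(rho) <- rownames(logcpm)
  rho <- rho[names(rho) != target_gene]
  p_emp <- empirical_pvalue(rho, null)
  names(p_emp) <- names(rho)

  observed <- mean(p_emp[gene_set])
  set.seed(seed)
  m <- length(gene_set)
  universe <- length(p_emp)
  null_stats <- vapply(seq_len(B), function(b) {
    mean(p_emp[sample.int(universe, m)])
  }, numeric(1))
  tail_lo <- (1 + sum(null_stats <= observed)) / (B + 1)
  p_boot <- if (two_sided) {
    min(1, 2 * min(tail_lo, (1 + sum(null_stats >= observed)) / (B + 1)))
  } else tail_lo
  structure(list(set_size = m, observed_stat = observed, null_stats = null_stats,
                 p_boot = p_boot, B = as.integer(B), seed = as.integer(seed),
                 target_gene = target_gene),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> set of ", x$set_size, " genes vs ", x$target_gene,
      ": mean empirical p = ", signif(x$observed_stat, 3),
      ", bootstrap p = ", signif(x$p_boot, 3), " (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Tidy a bootstrap enrichment result
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble of the test summary.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(target_gene = x$target_gene, set_size = x$set_size,
         observed_stat = x$observed_stat,
         null_mean = mean(x$null_stats), p_boot = x$p_boot, B = x$B)
}
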