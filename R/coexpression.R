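#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values.
#'
#' @param x,y Numeric vectors of equal length >= 3, non-constant.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) abort("need equal-length vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector in spearman_rho")
  cor(rank(x), rank(y))
}

# rank rows, centre and scale to unit norm so rho is a plain inner product
rank_standardize <- function(x) {
  r <- t(apply(x, 1, rank))
  r <- r - rowMeans(r)
  nrm <- sqrt(rowSums(r^2))
  if (any(nrm == 0)) abort("constant gene row in expression matrix")
  r / nrm
}

#' Build an empirical background distribution of gene-gene correlations
#'
#' Samples `n_pairs` unordered gene pairs uniformly with replacement
#' (self-pairs excluded) from the expression matrix, computes absolute
#' Spearman correlations and stores them sorted. The background defines
#' empirical coexpression p-values via [empirical_pvalue()]; it is tied to
#' the gene universe through a digest and is invalidated if the universe
#' changes.
#'
#' @param logcpm log2-CPM matrix over the filtered gene universe.
#' @param n_pairs Number of background pairs (default 1e6).
#' @param seed Integer seed.
#' @return A `correlation_null`: `abs_rho_sorted`, `n_pairs`, `seed`,
#'   `gene_universe_hash`.
#' @export
build_null <- function(logcpm, n_pairs = 1e6, seed = 1L) {
  if (nrow(logcpm) < 2) abort("need at least 2 genes to build a correlation null")
  if (n_pairs <= 0) abort("n_pairs must be positive")
  set.seed(seed)
  g <- nrow(logcpm)
  z <- rank_standardize(logcpm)
  out <- numeric(n_pairs)
  chunk <- 200000L
  done <- 0L
  while (done < n_pairs) {
    m <- min(chunk, n_pairs - done)
    a <- sample.int(g, m, replace = TRUE)
    b <- sample.int(g, m, replace = TRUE)
    clash <- a == b
    while (any(clash)) {
      b[clash] <- sample.int(g, sum(clash), replace = TRUE)
      clash <- a == b
    }
    out[done + seq_len(m)] <- abs(rowSums(z[a, , drop = FALSE] * z[b, , drop = FALSE]))
    done <- done + m
  }
  structure(list(abs_rho_sorted = sort(pmin(out, 1)), n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed),
                 gene_universe_hash = rlang::hash(sort(rownames(logcpm)))),
            class = "correlation_null")
}

#' @export
print.correlation_null <- function(x, ...) {
  cat("<correlation_null> ", x$n_pairs, " background pairs (seed ", x$seed,
      "); median |rho| = ", signif(median(x$abs_rho_sorted), 3), "\n", sep = "")
  invisible(x)
}

check_null_universe <- function(null, logcpm) {
  if (!identical(null$gene_universe_hash, rlang::hash(sort(rownames(logcpm))))) {
    abort("correlation null was built on a different gene universe")
  }
}

#' Empirical coexpression p-value
#'
#' The proportion of background pairs with absolute correlation at least as
#' extreme as the observed value. By default a zero count is floored at
#' `1 / n_pairs` so downstream -log10 transforms stay finite; `floor = FALSE`
#' returns the raw proportion.
#'
#' @param rho Observed correlation(s), vectorized.
#' @param null A `correlation_null`.
#' @param floor Apply the `1/n_pairs` floor (default TRUE).
#' @return Empirical p-value(s).
#' @export
empirical_pvalue <- function(rho, null, floor = TRUE) {
  bg <- null$abs_rho_sorted
  n <- length(bg)
  if (n == 0) abort("empty correlation null")
  # count of background values >= |rho|: n minus the number strictly below
  n_ge <- n - findInterval(abs(rho), bg, left.open = TRUE)
  p <- n_ge / n
  if (floor) p <- pmax(p, 1 / n)
  p
}

#' Top coexpressed genes for a query gene
#'
#' Spearman correlation of the query against every other gene in the
#' universe, ranked by absolute correlation (ties broken by gene id).
#'
#' @param gene Gene id present in `logcpm` rownames.
#' @param logcpm Expression matrix over the null's gene universe.
#' @param null A `correlation_null` built on the same universe.
#' @param k Number of genes to return (default 100).
#' @return Tibble `gene_a, gene_b, rho, p_emp`, strongest first.
#' @export
coexpressed_with <- function(gene, logcpm, null, k = 100) {
  if (!gene %in% rownames(logcpm)) abort(paste0("gene '", gene, "' not in the expression universe"))
  check_null_universe(null, logcpm)
  z <- rank_standardize(logcpm)
  rho <- as.vector(z %*% z[gene, ])
  names(rho) <- rownames(logcpm)
  rho <- rho[names(rho) != gene]
  ord <- order(-abs(rho), names(rho))
  top <- rho[ord][seq_len(min(k, length(rho)))]
  tibble(gene_a = gene, gene_b = names(top), rho = unname(pmin(pmax(top, -1), 1)),
         p_emp = empirical_pvalue(top, null))
}

#' Coexpression of a gene with the islet hormone genes
#'
#' Correlates the query gene with the secretory genes INS, GCG, SST, PPY,
#' IAPP and GHRL and flags empirical significance at `p_emp <= 0.05`.
#' Hormone genes missing from the universe produce a partial result with a
#' warning.
#'
#' @param gene Gene id in the universe.
#' @param logcpm Expression matrix.
#' @param null A `correlation_null` on the same universe.
#' @param annotation Annotation tibble used to resolve hormone symbols.
#' @param hormones Hormone symbols (default the six islet hormones).
#' @param alpha Significance cutoff on the empirical p (default 0.05).
#' @return Tibble `hormone, gene_b, rho, p_emp, significant`.
#' @export
hormone_panel <- function(gene, logcpm, null, annotation,
                          hormones = hormone_symbols(), alpha = 0.05) {
  check_null_universe(null, logcpm)
  rows <- list()
  z <- rank_standardize(logcpm)
  for (h in hormones) {
    hit <- annotation[annotation$symbol == h, , drop = FALSE]
    if (nrow(hit) != 1 || !hit$gene_id %in% rownames(logcpm)) {
      warn(paste0("hormone gene ", h, " not in the expression universe; skipped"))
      next
    }
    hid <- hit$gene_id
    rho <- if (hid == gene) 1 else sum(z[gene, ] * z[hid, ])
    rho <- min(max(rho, -1), 1)
    rows[[h]] <- tibble(hormone = h, gene_b = hid, rho = rho,
                        p_emp = empirical_pvalue(rho, null))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$significant <- out$p_emp <= alpha
  out
}

#' Persist a correlation null as text + JSON sidecar
#' @param null A `correlation_null`.
#' @param path Base path; writes `<path>` (values, one per line) and
#'   `<path>.json` (seed, n_pairs, universe hash).
#' @return `path`, invisibly.
#' @export
write_null <- function(null, path) {
  readr::write_lines(formatC(null$abs_rho_sorted, format = "g", digits = 17), path)
  jsonlite::write_json(
    list(n_pairs = null$n_pairs, seed = null$seed,
         gene_universe_hash = null$gene_universe_hash),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a correlation null written by [write_null()]
#' @param path Base path used in [write_null()].
#' @return A `correlation_null`.
#' @export
read_null <- function(path) {
  vals <- as.numeric(readr::read_lines(path))
  side <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(abs_rho_sorted = sort(vals), n_pairs = as.integer(side$n_pairs),
                 seed = as.integer(side$seed),
                 gene_universe_hash = side$gene_universe_hash),
            class = "correlation_null")
}
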