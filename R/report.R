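#' Expression percentile of a gene among all genes
#'
#' Percentile of the gene's average log2-CPM, counted from the top: the
#' highest-expressed gene of 200 is in the top 0.5%.
#'
#' @param gene Gene id.
#' @param logcpm log2-CPM matrix.
#' @param stat Averaging statistic, `mean` (default) or `median`.
#' @return Percentile in (0, 100].
#' @export
rank_expression <- function(gene, logcpm, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!gene %in% rownames(logcpm)) abort(paste0("gene '", gene, "' not in the expression universe"))
  avg <- if (stat == "mean") rowMeans(logcpm) else apply(logcpm, 1, median)
  unname(100 * rank(-avg, ties.method = "average")[gene] / length(avg))
}

#' Per-tissue expression summary
#'
#' Median and interquartile range of log2-CPM per tissue, per gene.
#'
#' @param logcpm log2-CPM matrix over the panel samples.
#' @param tissue Tissue label per sample.
#' @return Tibble `gene_id, tissue, median, q25, q75, n`.
#' @export
tissue_expression_summary <- function(logcpm, tissue) {
  if (length(tissue) != ncol(logcpm)) abort("tissue labels must match samples")
  rows <- lapply(sort(unique(tissue)), function(t) {
    sub <- logcpm[, tissue == t, drop = FALSE]
    tibble(gene_id = rownames(sub), tissue = t,
           median = apply(sub, 1, median),
           q25 = apply(sub, 1, quantile, 0.25),
           q75 = apply(sub, 1, quantile, 0.75),
           n = ncol(sub))
  })
  dplyr::bind_rows(rows)
}

segment_labels <- function() {
  # partition of islet-expressed genes by which other tissues share them
  c("islet" = "A",
    "islet+liver" = "B",
    "islet+muscle" = "C",
    "fat+islet" = "D",
    "fat+islet+liver" = "E",
    "islet+liver+muscle" = "F",
    "fat+islet+muscle" = "G",
    "fat+islet+liver+muscle" = "H")
}

#' Classify genes into cross-tissue expression segments
#'
#' Islet-expressed genes are labelled A-H by which of the four tissues they
#' are expressed in: A = islet only, B = islet+liver, C = islet+muscle,
#' D = fat+islet, E = fat+islet+liver, F = islet+liver+muscle,
#' G = fat+islet+muscle, H = all four. Genes not expressed in islet carry no
#' segment.
#'
#' @param mask Tibble from [expressed_mask()] with logical columns `fat`,
#'   `islet`, `liver`, `muscle`.
#' @param gene_set Optional gene ids to restrict to (e.g., DEGs).
#' @return Tibble `gene_id, expressed_in, segment`; per-segment counts in
#'   `attr(, "counts")`.
#' @export
classify_segments <- function(mask, gene_set = NULL) {
  tissues <- c("fat", "islet", "liver", "muscle")
  miss <- setdiff(tissues, colnames(mask))
  if (length(miss)) abort(paste0("missing tissue mask(s): ", paste(miss, collapse = ", ")))
  if (!is.null(gene_set)) mask <- mask[mask$gene_id %in% gene_set, , drop = FALSE]
  expressed_in <- apply(as.matrix(mask[, tissues]), 1, function(z) {
    paste(tissues[z], collapse = "+")
  })
  segment <- unname(segment_labels()[expressed_in])
  segment[!mask$islet] <- NA_character_
  out <- tibble(gene_id = mask$gene_id, expressed_in = expressed_in, segment = segment)
  counts <- table(factor(out$segment, levels = LETTERS[1:8]))
  attr(out, "counts") <- counts
  out
}

#' Assemble a per-gene report
#'
#' Collects the per-gene view from the upstream result tables: cross-tissue
#' expression, purity correlation, expression rank, phenotype associations,
#' hormone coexpression, top coexpressed genes, top eQTLs and an optional
#' cell-type lookup. No statistic is recomputed here; every number is taken
#' from exactly one upstream table. Panels without upstream input are marked
#' absent with a reason.
#'
#' @param gene Gene id, symbol or name.
#' @param annotation Annotation tibble.
#' @param logcpm Cohort log2-CPM matrix (for the expression-rank panel).
#' @param associations Named list of `islet_association` tibbles keyed by
#'   phenotype.
#' @param purity Tibble from [purity_correlation()], or NULL.
#' @param tissue_panel Tibble from [tissue_expression_summary()], or NULL.
#' @param hormones Tibble from [hormone_panel()], or NULL.
#' @param top_coexpressed Tibble from [coexpressed_with()], or NULL.
#' @param top_eqtls eQTL record tibble (<= 10 rows used), or NULL.
#' @param celltype_lookup Optional user-supplied per-cell-type reference
#'   tibble with a `gene_id` column.
#' @param gene_stats Optional `gene_stats` tibble from [prepare_expression()]
#'   used to explain why a filtered-out gene is absent.
#' @return A `gene_report` list, serializable with [write_gene_report()].
#' @export
build_gene_report <- function(gene, annotation, logcpm, associations = list(),
                              purity = NULL, tissue_panel = NULL,
                              hormones = NULL, top_coexpressed = NULL,
                              top_eqtls = NULL, celltype_lookup = NULL,
                              gene_stats = NULL) {
  ann <- resolve_gene(gene, annotation)
  gid <- ann$gene_id
  if (!gid %in% rownames(logcpm)) {
    reason <- "gene not in the filtered expression universe"
    if (!is.null(gene_stats) && gid %in% gene_stats$gene_id) {
      st <- gene_stats[gene_stats$gene_id == gid, ]
      reason <- paste0("removed by filter_genes (detected in ",
                       round(100 * st$frac_nonzero, 1), "% of samples, mean FPKM ",
                       signif(st$mean_fpkm, 3), ")")
    }
    abort(paste0("gene '", gene, "' has no report: ", reason))
  }
  panel <- function(x, what) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
      list(absent = TRUE, reason = paste0(what, " not supplied"))
    } else x
  }
  take <- function(tab) if (is.null(tab)) NULL else tab[tab$gene_id == gid, , drop = FALSE]
  assoc <- lapply(associations, take)
  report <- list(
    schema_version = "1.0",
    gene = as.list(ann),
    tissue_panel = panel(take(tissue_panel), "tissue panel"),
    purity_panel = panel(take(purity), "purity correlation"),
    rank_panel = list(percentile = rank_expression(gid, logcpm), statistic = "mean"),
    phenotype_panels = if (length(assoc)) assoc else
      list(absent = TRUE, reason = "associations not supplied"),
    hormone_panels = panel(hormones, "hormone coexpression"),
    top_coexpressed = panel(top_coexpressed, "coexpression table"),
    top_eqtls = panel(
      if (is.null(top_eqtls)) NULL else head(take(top_eqtls), 10), "eQTL records"),
    celltype_lookup = panel(take(celltype_lookup), "cell-type reference")
  )
  class(report) <- "gene_report"
  report
}

#' Serialize a gene report to JSON
#'
#' Deterministic, schema-versioned output: identical inputs give
#' byte-identical files.
#'
#' @param report A `gene_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_gene_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.gene_report <- function(x, ...) {
  cat("<gene_report> ", x$gene$symbol, " (", x$gene$gene_id, "), expression percentile ",
      round(x$rank_panel$percentile, 2), "\n", sep = "")
  invisible(x)
}
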