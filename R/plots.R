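#' Gene expression versus islet purity
#' @param logcpm log2-CPM matrix.
#' @param metadata Phenotype tibble with `donor_id` and `purity`.
#' @param gene Gene id.
#' @return A ggplot object.
#' @export
plot_purity <- function(logcpm, metadata, gene) {
  df <- tibble(purity = metadata$purity[match(colnames(logcpm), metadata$donor_id)],
               expr = logcpm[gene, ])
  ggplot2::ggplot(df, ggplot2::aes(.data$purity, .data$expr)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Islet purity (%)", y = "log2-CPM", title = gene)
}

#' Gene expression by phenotype
#' @param logcpm log2-CPM matrix.
#' @param metadata Phenotype tibble (after [assign_strata()] for strata).
#' @param gene Gene id.
#' @param phenotype Metadata column to plot against (e.g., `stratum`,
#'   `hba1c`, `bmi`).
#' @return A ggplot object.
#' @export
plot_phenotype <- function(logcpm, metadata, gene, phenotype) {
  v <- metadata[[phenotype]][match(colnames(logcpm), metadata$donor_id)]
  df <- tibble(value = v, expr = logcpm[gene, ])
  df <- df[!is.na(df$value), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$expr))
  p <- if (is.numeric(df$value)) {
    p + ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE)
  } else {
    p + ggplot2::geom_boxplot(outlier.alpha = 0.4)
  }
  p + ggplot2::labs(x = phenotype, y = "log2-CPM", title = gene)
}

#' Cross-tissue expression panel for a gene
#' @param tissue_summary Tibble from [tissue_expression_summary()].
#' @param gene Gene id.
#' @return A ggplot object.
#' @export
plot_tissue_panel <- function(tissue_summary, gene) {
  df <- tissue_summary[tissue_summary$gene_id == gene, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$tissue, .data$median)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q25, ymax = .data$q75), width = 0.2) +
    ggplot2::labs(x = NULL, y = "median log2-CPM (IQR)", title = gene)
}

#' Volcano plot of an association result
#' @param object An `islet_association` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.islet_association <- function(object, ...) {
  df <- tibble(beta = object$beta, p = object$p,
               sig = object$fdr <= 0.05)
  ggplot2::ggplot(df, ggplot2::aes(.data$beta, -log10(.data$p), colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50"),
                                 name = "FDR ≤ 0.05") +
    ggplot2::labs(x = "effect (log2-CPM)", y = "-log10 p",
                  title = attr(object, "phenotype"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
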