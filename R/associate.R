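#' Assign glycemic strata and analysis-set flags
#'
#' Strata: `T2D` when the donor has a clinical diagnosis or HbA1c >= 6.5;
#' `IGT` when HbA1c is in \[6, 6.5) without a clinical diagnosis; `NGT`
#' otherwise. Donors who are T2D by HbA1c alone (no clinical diagnosis) are
#' flagged out of the T2D-vs-control differential-expression contrast
#' (`in_de_contrast = FALSE`) while keeping their stratum.
#'
#' @param metadata Phenotype tibble with `clinical_t2d` and/or `hba1c`.
#' @param igt_lower,t2d_lower Stratum boundaries (6.0 inclusive, 6.5
#'   inclusive for T2D).
#' @return `metadata` with added `stratum`, `in_de_contrast`, `usable`.
#' @export
assign_strata <- function(metadata, igt_lower = 6.0, t2d_lower = 6.5) {
  clin <- metadata$clinical_t2d %in% TRUE
  hb <- metadata$hba1c
  usable <- clin | !is.na(hb) | !is.na(metadata$clinical_t2d)
  if (any(!usable)) {
    warn(paste0(sum(!usable), " donor(s) have neither HbA1c nor a clinical flag; marked unusable"))
  }
  stratum <- rep(NA_character_, nrow(metadata))
  stratum[usable] <- "NGT"
  stratum[!is.na(hb) & hb >= igt_lower & hb < t2d_lower] <- "IGT"
  stratum[(!is.na(hb) & hb >= t2d_lower) | clin] <- "T2D"
  in_de <- (stratum == "T2D" & clin) | stratum %in% c("NGT", "IGT")
  in_de[is.na(in_de)] <- FALSE
  dplyr::mutate(metadata,
                stratum = factor(stratum, levels = c("NGT", "IGT", "T2D")),
                in_de_contrast = in_de & usable,
                usable = usable)
}

supported_phenotypes <- function() {
  c("t2d_status", "hba1c_stratum", "hba1c", "bmi", "stimulatory_index")
}

#' Build the association design matrix
#'
#' Intercept + phenotype encoding + covariate columns. `t2d_status` is a
#' binary T2D-vs-control contrast restricted to `in_de_contrast` donors;
#' `hba1c_stratum` uses two dummy columns with NGT as reference; continuous
#' phenotypes enter as numeric columns. Rows with a missing phenotype or
#' covariate are dropped and reported; constant covariates are dropped with a
#' warning.
#'
#' @param metadata Output of [assign_strata()].
#' @param phenotype One of `t2d_status`, `hba1c_stratum`, `hba1c`, `bmi`,
#'   `stimulatory_index`.
#' @param covariates Covariate column names (default purity, sex, age).
#' @return List: `design` (model matrix), `term` (phenotype column names),
#'   `samples` (donor ids kept), `dropped` (donor ids removed).
#' @export
build_design <- function(metadata, phenotype,
                         covariates = c("purity", "sex", "age")) {
  phenotype <- match.arg(phenotype, supported_phenotypes())
  md <- metadata
  if (!"stratum" %in% colnames(md)) md <- assign_strata(md)
  keep <- md$usable
  if (phenotype == "t2d_status") {
    keep <- keep & md$in_de_contrast
    value <- as.numeric(md$stratum == "T2D")
  } else if (phenotype == "hba1c_stratum") {
    value <- md$stratum
  } else {
    value <- md[[phenotype]]
  }
  keep <- keep & !is.na(value)
  for (cv in covariates) {
    if (!cv %in% colnames(md)) abort(paste0("covariate '", cv, "' not in metadata"))
    keep <- keep & !is.na(md[[cv]])
  }
  md <- md[keep, , drop = FALSE]
  if (nrow(md) < length(covariates) + 3) abort("too few usable donors for this design")

  cols <- list("(Intercept)" = rep(1, nrow(md)))
  if (phenotype == "hba1c_stratum") {
    s <- droplevels(md$stratum)
    for (lev in setdiff(levels(s), "NGT")) {
      cols[[paste0("stratum", lev)]] <- as.numeric(s == lev)
    }
    term <- setdiff(names(cols), "(Intercept)")
  } else if (phenotype == "t2d_status") {
    cols[["t2d"]] <- as.numeric(md$stratum == "T2D")
    term <- "t2d"
  } else {
    cols[[phenotype]] <- as.numeric(md[[phenotype]])
    term <- phenotype
  }
  for (cv in covariates) {
    v <- md[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      if (nlevels(droplevels(v)) < 2) {
        warn(paste0("covariate '", cv, "' is constant; dropped"))
        next
      }
      for (lev in levels(droplevels(v))[-1]) cols[[paste0(cv, lev)]] <- as.numeric(v == lev)
    } else {
      if (sd(v) == 0) { warn(paste0("covariate '", cv, "' is constant; dropped")); next }
      cols[[cv]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- md$donor_id
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep_col <- qrX$pivot[seq_len(qrX$rank)]
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), keep_col)]
    abort(paste0("design is rank-deficient; collinear column(s): ", paste(bad, collapse = ", ")))
  }
  list(design = X, term = term, samples = md$donor_id,
       dropped = setdiff(metadata$donor_id, md$donor_id))
}

#' Per-gene weighted linear-model association with moderated inference
#'
#' Fits a weighted least-squares model per gene and tests the phenotype
#' term(s). With `moderation = TRUE`, per-gene residual variances are shrunk
#' toward a common prior estimated by moment matching of the log residual
#' variances against a scaled F distribution; t (and F for multi-column
#' terms) statistics then use the posterior variance with `d0 + d` degrees of
#' freedom. `r2` is the partial coefficient of determination of the phenotype
#' term(s) given the covariates.
#'
#' @param logcpm log2-CPM matrix restricted to (or indexable by) the design
#'   samples.
#' @param design Model-matrix list from [build_design()], or a plain matrix.
#' @param term Phenotype column name(s) in the design (defaults to the
#'   `term` element of `design`).
#' @param weights Optional positive gene-by-sample precision weights.
#' @param moderation Use empirical-Bayes variance shrinkage (default TRUE).
#' @return An `islet_fit` tibble: `gene_id, term, beta, se, statistic, df, p,
#'   r2` (one row per gene; `beta`/`se` are NA for joint multi-column tests)
#'   with the prior df `d0` and prior variance `s0_2` as attributes. Per-dummy
#'   contrasts for multi-column terms are in `attr(, "contrasts")`.
#' @export
fit_linear <- function(logcpm, design, term = NULL, weights = NULL, moderation = TRUE) {
  if (is.list(design) && !is.null(design$design)) {
    if (is.null(term)) term <- design$term
    X <- design$design
  } else X <- design
  if (is.null(term)) abort("term must be supplied")
  samples <- rownames(X)
  if (!is.null(samples) && all(samples %in% colnames(logcpm))) {
    logcpm <- logcpm[, samples, drop = FALSE]
    if (!is.null(weights)) weights <- weights[, samples, drop = FALSE]
  }
  n <- ncol(logcpm)
  if (nrow(X) != n) abort("design rows must match expression samples")
  if (!all(term %in% colnames(X))) abort("term not found in design columns")
  if (!is.null(weights) && any(weights <= 0)) abort("weights must be positive")
  d <- n - ncol(X)
  if (d <= 0) abort("no residual degrees of freedom")
  if (any(!is.finite(logcpm))) {
    bad <- rownames(logcpm)[!apply(is.finite(logcpm), 1, all)]
    abort(paste0("non-finite expression for gene(s): ", paste(head(bad, 5), collapse = ", ")))
  }

  tcols <- match(term, colnames(X))
  G <- nrow(logcpm)
  q <- length(tcols)
  beta <- se_unscaled <- s2 <- r2 <- rep(NA_real_, G)
  fstat_num <- rep(NA_real_, G)
  con_beta <- con_se <- matrix(NA_real_, G, q)
  for (i in seq_len(G)) {
    y <- logcpm[i, ]
    w <- if (is.null(weights)) rep(1, n) else weights[i, ]
    fit <- lm.wfit(X, y, w)
    rss_full <- sum(w * fit$residuals^2)
    s2[i] <- rss_full / d
    XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
    su <- sqrt(diag(XtWX_inv))
    con_beta[i, ] <- fit$coefficients[tcols]
    con_se[i, ] <- su[tcols]
    if (q == 1) {
      beta[i] <- fit$coefficients[tcols]
      se_unscaled[i] <- su[tcols]
    }
    fit_red <- lm.wfit(X[, -tcols, drop = FALSE], y, w)
    rss_red <- sum(w * fit_red$residuals^2)
    r2[i] <- if (rss_red > 0) max(0, (rss_red - rss_full) / rss_red) else 0
    fstat_num[i] <- (rss_red - rss_full) / q
  }

  if (moderation) {
    sq <- squeeze_variances(s2, d)
    s2_post <- sq$s2_post; df_total <- d + sq$d0
  } else {
    sq <- list(d0 = 0, s0_2 = NA_real_)
    s2_post <- s2; df_total <- d
  }
  if (q == 1) {
    se <- se_unscaled * sqrt(s2_post)
    stat <- beta / se
    p <- 2 * pt(-abs(stat), df_total)
  } else {
    se <- rep(NA_real_, G)
    stat <- fstat_num / s2_post
    p <- pf(stat, q, df_total, lower.tail = FALSE)
  }
  con_t <- con_beta / (con_se * sqrt(s2_post))
  contrasts <- tibble(
    gene_id = rep(rownames(logcpm), each = q),
    contrast = rep(term, times = G),
    beta = as.vector(t(con_beta)),
    se = as.vector(t(con_se * sqrt(s2_post))),
    statistic = as.vector(t(con_t)),
    p = 2 * pt(-abs(as.vector(t(con_t))), rep(df_total, each = q))
  )
  out <- tibble(
    gene_id = rownames(logcpm),
    term = paste(term, collapse = "+"),
    beta = beta, se = se, statistic = stat,
    df = if (length(df_total) == 1) rep(df_total, G) else df_total,
    p = pmin(pmax(p, 0), 1), r2 = r2
  )
  attr(out, "d0") <- sq$d0
  attr(out, "s0_2") <- sq$s0_2
  attr(out, "df_residual") <- d
  attr(out, "moderation") <- moderation
  attr(out, "contrasts") <- contrasts
  class(out) <- c("islet_fit", class(out))
  out
}

# empirical-Bayes variance shrinkage: moment matching of log s^2 against a
# scaled F distribution; returns prior df d0, prior variance s0^2 and the
# posterior variances
squeeze_variances <- function(s2, d) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_2 <- exp(emean)
    s2_post <- rep(s0_2, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

# Newton solve of trigamma(y) = x on y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, in input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same length and order).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Percentage rank of p-values
#'
#' `100 * rank(p) / n` with average ranks for ties; the most significant gene
#' of 100 has rank 1.
#'
#' @param p Vector of p-values.
#' @return Percentage ranks in (0, 100].
#' @export
percentage_rank <- function(p) {
  if (length(p) == 0) abort("empty p-value vector")
  100 * rank(p, ties.method = "average") / length(p)
}

#' Associate every gene's expression with a phenotype
#'
#' End-to-end association stage: strata assignment, design construction,
#' optional mean-variance precision weights, weighted moderated linear-model
#' fit, BH adjustment and percentage ranks.
#'
#' @param expr An `islet_expression` object from [prepare_expression()], or a
#'   list with `counts`, `lib_sizes`, `factors`, `logcpm`.
#' @param metadata Phenotype tibble.
#' @param phenotype Phenotype name (see [build_design()]).
#' @param covariates Covariates (default purity, sex, age).
#' @param use_weights Compute precision weights under this design (default
#'   TRUE).
#' @param moderation Moderated inference (default TRUE).
#' @return `islet_association` tibble: `islet_fit` columns plus `fdr` and
#'   `rank_pct`, plus `phenotype` attribute.
#' @export
associate_phenotype <- function(expr, metadata, phenotype,
                                covariates = c("purity", "sex", "age"),
                                use_weights = TRUE, moderation = TRUE) {
  metadata <- metadata[metadata$donor_id %in% colnames(expr$logcpm), , drop = FALSE]
  md <- assign_strata(metadata)
  des <- build_design(md, phenotype, covariates)
  w <- NULL
  if (use_weights) {
    cts <- expr$counts[, des$samples, drop = FALSE]
    w <- precision_weights(cts, des$design,
                           lib_sizes = expr$lib_sizes[des$samples],
                           factors = expr$factors)
  }
  fit <- fit_linear(expr$logcpm, des, weights = w, moderation = moderation)
  fit$fdr <- bh_adjust(fit$p)
  fit$rank_pct <- percentage_rank(fit$p)
  attr(fit, "phenotype") <- phenotype
  class(fit) <- unique(c("islet_association", class(fit)))
  fit
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a per-gene association fit
#' @param x An `islet_fit`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.islet_fit <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attributes(out)[c("d0", "s0_2", "df_residual", "moderation", "contrasts",
                    "phenotype")] <- NULL
  out
}

#' One-row summary of a per-gene association fit
#' @param x An `islet_fit`.
#' @param ... Unused.
#' @return Tibble with gene count, prior df, prior variance and the number of
#'   genes at FDR <= 0.05 (when present).
#' @export
glance.islet_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    term = x$term[1],
    d0 = attr(x, "d0"),
    s0_2 = attr(x, "s0_2"),
    df_residual = attr(x, "df_residual"),
    n_fdr_05 = if ("fdr" %in% colnames(x)) sum(x$fdr <= 0.05) else NA_integer_
  )
}
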