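#' Configuration for the synthetic donor-cohort generator
#'
#' Defaults emulate the study cohort the analyses target: 188 islet donors of
#' whom 33 carry a clinical T2D diagnosis, 25 further donors are T2D by HbA1c
#' only (HbA1c above 6.5%), 30 are IGT (HbA1c in 6-6.5%), and the remainder
#' NGT; islet purity is a strong expression confounder loading on half of all
#' genes; counts are negative binomial at realistic sequencing depths.
#'
#' @param n_donors Number of donors (188).
#' @param n_genes Number of simulated genes (2000, desk scale).
#' @param n_t2d Donors with a clinical T2D diagnosis (33).
#' @param n_t2d_hba1c_only Donors that are T2D by HbA1c >= 6.5 only, with no
#'   clinical diagnosis (25); excluded from the T2D-vs-control DE contrast.
#' @param n_igt Donors with HbA1c in \[6, 6.5) (30).
#' @param frac_purity_genes Fraction of genes with a linear purity loading on
#'   the log2 scale (0.5).
#' @param purity_loading_range Absolute loading per percentage point purity,
#'   log2 units; sign random (c(0.01, 0.03)).
#' @param purity_t2d_shift Mean purity reduction (percentage points) in T2D
#'   donors, creating the purity-status confound (15).
#' @param n_de_genes Genes with a planted T2D effect (100).
#' @param de_log2fc Planted log2 fold change magnitude, random sign (1).
#' @param n_eqtl_genes Genes with one planted cis-eQTL (50).
#' @param eqtl_beta Planted log2 expression change per alt allele (1).
#' @param maf_range Range of simulated minor-allele frequencies (c(0.3, 0.3)).
#' @param n_variants_per_gene Cis variants simulated per genotyped gene (10).
#' @param n_decoys_per_gene Decoy variants beyond 2.5 Mb per genotyped gene (2).
#' @param coexpr_module_size Genes per hormone-anchored coexpression module (30).
#' @param coexpr_loading Loading of the shared latent factor (1).
#' @param n_batches Sequencing batches (2).
#' @param batch_shift_sd SD of per-gene, per-batch location shifts, log2 (0.2).
#' @param batch_scale_sd SD of log per-gene, per-batch dispersion scaling (0.1).
#' @param nb_dispersion Negative-binomial dispersion (0.1).
#' @param depth_range Per-donor total read depth range (c(12e6, 60e6)).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_donors = 188, n_genes = 2000,
                              n_t2d = 33, n_t2d_hba1c_only = 25, n_igt = 30,
                              frac_purity_genes = 0.5,
                              purity_loading_range = c(0.01, 0.03),
                              purity_t2d_shift = 15,
                              n_de_genes = 100, de_log2fc = 1,
                              n_eqtl_genes = 50, eqtl_beta = 1,
                              maf_range = c(0.3, 0.3),
                              n_variants_per_gene = 10, n_decoys_per_gene = 2,
                              coexpr_module_size = 30, coexpr_loading = 1,
                              n_batches = 2, batch_shift_sd = 0.2,
                              batch_scale_sd = 0.1,
                              nb_dispersion = 0.1,
                              depth_range = c(12e6, 60e6), seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_donors", "n_genes", "n_t2d", "n_t2d_hba1c_only", "n_igt",
              "n_de_genes", "n_eqtl_genes", "n_variants_per_gene",
              "n_decoys_per_gene", "coexpr_module_size", "n_batches")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0) {
      abort(paste0("invalid config: ", f, " must be a non-negative count"))
    }
  }
  if (frac_purity_genes < 0 || frac_purity_genes > 1) abort("invalid config: frac_purity_genes outside [0, 1]")
  if (!is.finite(de_log2fc)) abort("invalid config: de_log2fc not finite")
  if (n_t2d + n_t2d_hba1c_only + n_igt > n_donors) abort("invalid config: strata exceed n_donors")
  if (n_de_genes > n_genes) abort("invalid config: n_de_genes > n_genes")
  if (n_eqtl_genes > n_genes) abort("invalid config: n_eqtl_genes > n_genes")
  if (maf_range[1] > maf_range[2] || maf_range[1] < 0 || maf_range[2] > 0.5) {
    abort("invalid config: maf_range must lie within [0, 0.5]")
  }
  if (depth_range[1] > depth_range[2] || depth_range[1] <= 0) abort("invalid config: bad depth_range")
  if (n_batches > 0 && n_donors > 0 && n_donors < 2 * n_batches) abort("invalid config: fewer than 2 donors per batch")
  class(cfg) <- "simulation_config"
  cfg
}

hormone_symbols <- function() c("INS", "GCG", "SST", "PPY", "IAPP", "GHRL")

hormone_full_names <- function() {
  c(INS = "insulin", GCG = "glucagon", SST = "somatostatin",
    PPY = "pancreatic polypeptide", IAPP = "islet amyloid polypeptide",
    GHRL = "ghrelin")
}

# genes spaced 6 Mb apart so +-2 Mb cis windows of neighbours never overlap a
# gene's own decoy band (2.5-2.9 Mb)
simulate_annotation <- function(n_genes) {
  per_chr <- 50L
  idx <- seq_len(n_genes)
  chrom <- paste0("chr", ((idx - 1L) %/% per_chr) + 1L)
  slot <- (idx - 1L) %% per_chr
  start <- 4e6 + slot * 6e6
  len <- pmax(200L, as.integer(round(rlnorm(n_genes, log(2000), 0.6))))
  hs <- hormone_symbols()
  symbol <- sprintf("SYN%04d", idx)
  nm <- paste("synthetic gene", idx)
  symbol[seq_along(hs)] <- hs
  nm[seq_along(hs)] <- hormone_full_names()[hs]
  tibble(
    gene_id = sprintf("SIMG%011d", idx), symbol = symbol, name = nm,
    chrom = chrom, start = as.integer(start), end = as.integer(start + len - 1L),
    strand = rep(c("+", "-"), length.out = n_genes), length = len
  )
}

#' Simulate a donor islet cohort with planted ground truth
#'
#' Generative model: per-gene baseline log2 means from a normal on the log
#' scale; latent purity per donor Uniform\[40, 100\] (shifted down for T2D
#' donors to create confounding) with linear loadings on a configurable gene
#' fraction; planted T2D log2 fold changes with random sign; HbA1c drawn
#' consistently with the donor stratum (NGT < 6, IGT in \[6, 6.5), T2D >= 6.5);
#' six hormone-anchored coexpression modules driven by shared standard-normal
#' latent factors; per-gene, per-batch location/scale perturbations; negative
#' binomial counts at a per-donor depth; genotypes Binomial(2, maf) within
#' 1 Mb of their gene plus decoy variants beyond 2.5 Mb; planted eQTLs add
#' `eqtl_beta` x dosage to the gene's log2 mean.
#'
#' @param config A [simulation_config()].
#' @return An `islet_cohort` list: `counts` (gene x donor matrix), `metadata`
#'   (phenotype tibble), `annotation`, `genotypes` (`genotype_matrix`), and
#'   `truth` (planted DE genes, purity loadings, eQTL pairs, module members,
#'   batch assignment).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_donors; g <- config$n_genes
  ann <- simulate_annotation(g)
  donors <- sprintf("D%04d", seq_len(n))

  status <- rep("NGT", n)
  if (config$n_t2d > 0) status[seq_len(config$n_t2d)] <- "T2D_clinical"
  if (config$n_t2d_hba1c_only > 0) {
    status[config$n_t2d + seq_len(config$n_t2d_hba1c_only)] <- "T2D_hba1c"
  }
  if (config$n_igt > 0) {
    status[config$n_t2d + config$n_t2d_hba1c_only + seq_len(config$n_igt)] <- "IGT"
  }
  is_t2d <- status %in% c("T2D_clinical", "T2D_hba1c")
  hba1c <- numeric(n)
  hba1c[status == "NGT"] <- round(runif(sum(status == "NGT"), 4.8, 5.9), 2)
  hba1c[status == "IGT"] <- round(runif(sum(status == "IGT"), 6.0, 6.49), 2)
  hba1c[is_t2d] <- round(runif(sum(is_t2d), 6.6, 10.5), 2)

  purity <- runif(n, 40, 100)
  purity[is_t2d] <- pmax(20, purity[is_t2d] - config$purity_t2d_shift)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- round(runif(n, 25, 75))
  bmi <- round(rnorm(n, 26 + 2 * is_t2d, 3.5), 1)
  si <- round(exp(rnorm(n, log(4) - 0.5 * is_t2d, 0.6)), 2)
  batch <- if (config$n_batches > 0) {
    sample(rep_len(paste0("batch", seq_len(config$n_batches)), n))
  } else rep("batch1", n)

  base <- rnorm(g, 4, 2)
  n_h <- min(length(hormone_symbols()), g)
  base[seq_len(n_h)] <- c(13, 12, 11, 10, 10, 9)[seq_len(n_h)]
  logmu <- matrix(base, g, n)

  # purity loadings (negative = exocrine-like), centred at 70% purity
  n_pur <- round(config$frac_purity_genes * g)
  pur_idx <- sort(sample(g, n_pur))
  pur_load <- numeric(0)
  if (n_pur > 0) {
    pur_load <- sample(c(-1, 1), n_pur, TRUE) *
      runif(n_pur, config$purity_loading_range[1], config$purity_loading_range[2])
    logmu[pur_idx, ] <- logmu[pur_idx, ] + pur_load %o% (purity - 70)
  }

  de_idx <- integer(0); de_lfc <- numeric(0)
  if (config$n_de_genes > 0) {
    de_idx <- sort(sample(g, config$n_de_genes))
    de_lfc <- sample(c(-1, 1), config$n_de_genes, TRUE) * config$de_log2fc
    logmu[de_idx, is_t2d] <- logmu[de_idx, is_t2d] + de_lfc
  }

  modules <- list()
  if (config$coexpr_module_size > 0 && g > n_h) {
    pool <- setdiff(seq_len(g), seq_len(n_h))
    for (h in seq_len(n_h)) {
      m_size <- min(config$coexpr_module_size, length(pool))
      if (m_size == 0) break
      members <- sort(sample(pool, m_size))
      pool <- setdiff(pool, members)
      fac <- rnorm(n)
      rows <- c(h, members)
      logmu[rows, ] <- logmu[rows, ] + config$coexpr_loading * rep(fac, each = length(rows))
      modules[[hormone_symbols()[h]]] <- ann$gene_id[members]
    }
  }

  geno <- NULL; eqtl_truth <- tibble(variant_id = character(), gene_id = character(), beta = numeric())
  if (config$n_variants_per_gene > 0 && config$n_eqtl_genes >= 0) {
    n_geno_genes <- min(g, max(config$n_eqtl_genes * 2, config$n_eqtl_genes))
    geno_genes <- sort(sample(g, n_geno_genes))
    eqtl_genes <- if (config$n_eqtl_genes > 0) sort(sample(geno_genes, config$n_eqtl_genes)) else integer(0)
    vrows <- list(); dos <- list()
    for (gi in geno_genes) {
      offs <- as.integer(round(runif(config$n_variants_per_gene, -1e6, 1e6)))
      pos <- pmax(1L, ann$start[gi] + offs)
      if (config$n_decoys_per_gene > 0) {
        dec <- as.integer(round(runif(config$n_decoys_per_gene, 2.5e6, 2.9e6)))
        side <- sample(c(-1L, 1L), config$n_decoys_per_gene, TRUE)
        pos <- c(pos, pmax(1L, ifelse(side < 0, ann$start[gi] - dec, ann$end[gi] + dec)))
      }
      maf <- runif(length(pos), config$maf_range[1], config$maf_range[2])
      for (k in seq_along(pos)) {
        d <- rbinom(n, 2, maf[k])
        vid <- sprintf("%s_v%02d", ann$gene_id[gi], k)
        vrows[[length(vrows) + 1L]] <- tibble(
          variant_id = vid, chrom = ann$chrom[gi], pos = pos[k], ref = "A", alt = "G")
        dos[[length(dos) + 1L]] <- d
        is_cis <- k <= config$n_variants_per_gene
        if (is_cis && gi %in% eqtl_genes && k == 1L) {
          logmu[gi, ] <- logmu[gi, ] + config$eqtl_beta * d
          eqtl_truth <- dplyr::bind_rows(eqtl_truth, tibble(
            variant_id = vid, gene_id = ann$gene_id[gi], beta = config$eqtl_beta))
        }
      }
    }
    if (length(vrows) > 0) {
      dosage <- do.call(rbind, dos)
      variants <- dplyr::bind_rows(vrows)
      rownames(dosage) <- variants$variant_id
      colnames(dosage) <- donors
      geno <- new_genotype_matrix(variants, dosage, maf_min = 0)
    }
  }

  # batch location/scale perturbations, then NB sampling at the donor depth
  shift <- matrix(rnorm(g * config$n_batches, 0, config$batch_shift_sd), g)
  scale <- matrix(exp(rnorm(g * config$n_batches, 0, config$batch_scale_sd)), g)
  b_idx <- match(batch, paste0("batch", seq_len(max(config$n_batches, 1))))
  if (config$n_batches > 1) logmu <- logmu + shift[, b_idx]
  depth <- runif(n, config$depth_range[1], config$depth_range[2])
  w <- 2^logmu
  mu <- sweep(w, 2, depth / colSums(w), `*`)
  size <- 1 / (config$nb_dispersion * (if (config$n_batches > 1) scale[, b_idx] else matrix(1, g, n)))
  counts <- matrix(rnbinom(g * n, size = size, mu = mu), g, n,
                   dimnames = list(ann$gene_id, donors))

  metadata <- tibble(
    donor_id = donors, tissue = "islet",
    clinical_t2d = status == "T2D_clinical",
    hba1c = hba1c, bmi = bmi, sex = sex, age = age, purity = round(purity, 1),
    stimulatory_index = si, batch = batch
  )
  truth <- list(
    de_genes = tibble(gene_id = ann$gene_id[de_idx], log2fc = de_lfc),
    purity_genes = tibble(gene_id = ann$gene_id[pur_idx], loading = pur_load),
    eqtl_pairs = eqtl_truth,
    coexpr_modules = modules,
    batch_assignments = setNames(batch, donors)
  )
  structure(list(counts = counts, metadata = metadata, annotation = ann,
                 genotypes = geno, truth = truth, config = config),
            class = "islet_cohort")
}

#' @export
print.islet_cohort <- function(x, ...) {
  cat("<islet_cohort> ", nrow(x$counts), " genes x ", ncol(x$counts), " donors; ",
      sum(x$metadata$clinical_t2d), " clinical T2D; ",
      nrow(x$truth$de_genes), " planted DE genes; ",
      nrow(x$truth$eqtl_pairs), " planted eQTLs\n", sep = "")
  invisible(x)
}

#' Simulate a four-tissue expression panel
#'
#' Emulates biopsies of fat, islet, liver and muscle from the same pool of
#' individuals. A designated tissue-specific gene set per tissue is expressed
#' (CPM >= 1 in more than 80% of samples, by construction) only in its own
#' tissue; ubiquitous genes are expressed everywhere.
#'
#' @param config A [simulation_config()]; `n_genes`, `nb_dispersion`, `seed`
#'   are used, depth is fixed at 10M reads per sample.
#' @param n_per_tissue Samples per tissue (default 12).
#' @return List with `counts`, `metadata` (donor_id, tissue), and `truth`
#'   (list of tissue-specific gene-id sets).
#' @export
simulate_tissue_panel <- function(config, n_per_tissue = 12) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_per_tissue < 1) abort("invalid config: n_per_tissue must be >= 1")
  set.seed(config$seed + 101L)
  tissues <- c("fat", "islet", "liver", "muscle")
  g <- config$n_genes
  ann <- simulate_annotation(g)
  n <- 4L * n_per_tissue
  tissue <- rep(tissues, each = n_per_tissue)
  samples <- sprintf("P%02d_%s", rep(seq_len(n_per_tissue), times = 4), tissue)

  n_spec <- max(1L, round(0.05 * g))
  pool <- seq_len(g)
  spec <- list()
  for (t in tissues) {
    spec[[t]] <- sort(sample(pool, min(n_spec, length(pool))))
    pool <- setdiff(pool, spec[[t]])
  }
  base <- rnorm(g, 4, 1.5)
  logmu <- matrix(base, g, n)
  for (t in tissues) {
    off <- tissue != t
    logmu[spec[[t]], off] <- -10   # ~0.1 CPM at 10M reads: silent off-tissue
    logmu[spec[[t]], !off] <- pmax(base[spec[[t]]], 5)
  }
  depth <- rep(1e7, n)
  w <- 2^logmu
  mu <- sweep(w, 2, depth / colSums(w), `*`)
  counts <- matrix(rnbinom(g * n, size = 1 / config$nb_dispersion, mu = mu), g, n,
                   dimnames = list(ann$gene_id, samples))
  metadata <- tibble(donor_id = samples, tissue = tissue)
  list(counts = counts, metadata = metadata, annotation = ann,
       truth = lapply(spec, function(i) ann$gene_id[i]))
}
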