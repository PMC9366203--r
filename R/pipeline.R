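#' Pipeline configuration
#'
#' Aggregates all stage thresholds and seeds. Defaults are the standard
#' analysis constants: 10 million reads for the sample filter, detection in
#' 95% of samples and mean FPKM > 1 for the gene filter, 1 CPM in more than
#' 80% of samples for tissue expression calls, a 2 Mb cis window, 1 million
#' background correlation pairs and 10,000 bootstrap iterations.
#'
#' @param simulation A [simulation_config()] describing the cohort to
#'   simulate, or NULL when `inputs` point at files on disk.
#' @param inputs Named list of input paths (`counts`, `phenotypes`,
#'   `annotation`, `genotypes`), used when `simulation` is NULL.
#' @param min_reads,frac_nonzero,min_mean_fpkm,cpm_min,frac_expressed QC
#'   thresholds.
#' @param cis_window Cis window in bp (2e6).
#' @param n_pairs Background correlation pairs (1e6).
#' @param B Bootstrap iterations (10000).
#' @param covariates Association covariates.
#' @param batch_adjust_eqtl Batch-adjust expression before the eQTL scan
#'   (default TRUE); the association path never includes batch.
#' @param moderation Moderated association inference (default TRUE).
#' @param p_floor Floor empirical p-values at 1/n_pairs (default TRUE).
#' @param maf_min Genotype MAF filter (0.05).
#' @param report_genes Gene queries to write reports for (default the six
#'   hormone genes).
#' @param seeds Named per-stage seeds (`null`, `enrichment`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            inputs = NULL,
                            min_reads = 1e7, frac_nonzero = 0.95,
                            min_mean_fpkm = 1, cpm_min = 1, frac_expressed = 0.80,
                            cis_window = 2e6, n_pairs = 1e6, B = 10000,
                            covariates = c("purity", "sex", "age"),
                            batch_adjust_eqtl = TRUE, moderation = TRUE,
                            p_floor = TRUE, maf_min = 0.05,
                            report_genes = hormone_symbols(),
                            seeds = list(null = 1L, enrichment = 2L)) {
  cfg <- as.list(environment())
  if (is.null(cfg$simulation) && is.null(cfg$inputs)) {
    abort("pipeline needs either a simulation config or input paths")
  }
  for (f in c("min_reads", "frac_nonzero", "min_mean_fpkm", "cpm_min",
              "frac_expressed", "cis_window", "n_pairs", "B", "maf_min")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      abort(paste0("invalid pipeline config: ", f))
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$simulation <- if (!is.null(obj$simulation)) unclass(obj$simulation)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_pipeline_config()] (or compatible).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sim <- if (!is.null(obj$simulation)) do.call(simulation_config, obj$simulation)
  args <- obj[setdiff(names(obj), "simulation")]
  args$covariates <- unlist(args$covariates)
  args$report_genes <- unlist(args$report_genes)
  do.call(pipeline_config, c(list(simulation = sim), args))
}

pipeline_log <- function(con, ...) {
  line <- paste0(...)
  writeLines(line, con)
  invisible(line)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: simulate (or load inputs),
#' normalize, associate (all five phenotypes), coexpression null, cis-eQTL
#' scan, bootstrap enrichment of each hormone-anchored module, tissue-panel
#' segment classification, and per-gene reports. Every output file is listed
#' in `manifest.json` with its MD5 content hash; `run.log` records seeds and
#' filter counts. Reruns with an identical configuration produce identical
#' hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Manifest tibble (`file`, `md5`), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con), add = TRUE)
  pipeline_log(con, "isletview pipeline, package version ",
               as.character(utils::packageVersion("isletview")))
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  # --- stage: inputs -----------------------------------------------------
  if (!is.null(config$simulation)) {
    pipeline_log(con, "stage simulate: seed ", config$simulation$seed)
    cohort <- simulate_cohort(config$simulation)
    panel <- simulate_tissue_panel(config$simulation)
    emit(write_counts(cohort$counts, file.path(out_dir, "counts.tsv")))
    emit(write_phenotypes(cohort$metadata, file.path(out_dir, "phenotypes.csv")))
    emit(write_annotation(cohort$annotation, file.path(out_dir, "annotation.tsv")))
    if (!is.null(cohort$genotypes)) {
      emit(write_genotypes_vcf(cohort$genotypes, file.path(out_dir, "genotypes.vcf")))
    }
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(
      de_genes = cohort$truth$de_genes, purity_genes = cohort$truth$purity_genes,
      eqtl_pairs = cohort$truth$eqtl_pairs, coexpr_modules = cohort$truth$coexpr_modules,
      batch_assignments = as.list(cohort$truth$batch_assignments)),
      truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(truth_path)
    counts <- cohort$counts; metadata <- cohort$metadata
    annotation <- cohort$annotation; genotypes <- cohort$genotypes
  } else {
    for (f in c("counts", "phenotypes", "annotation")) {
      if (is.null(config$inputs[[f]]) || !file.exists(config$inputs[[f]])) {
        abort(paste0("stage inputs failed: missing input file for '", f, "'"))
      }
    }
    counts <- read_counts(config$inputs$counts)
    metadata <- read_phenotypes(config$inputs$phenotypes)
    annotation <- read_annotation(config$inputs$annotation)
    genotypes <- if (!is.null(config$inputs$genotypes)) {
      read_genotypes(config$inputs$genotypes, maf_min = config$maf_min,
                     samples = metadata$donor_id)
    }
    panel <- NULL
  }

  # --- stage: normalize ---------------------------------------------------
  expr <- prepare_expression(counts, annotation, min_reads = config$min_reads,
                             frac_nonzero = config$frac_nonzero,
                             min_mean_fpkm = config$min_mean_fpkm)
  pipeline_log(con, "stage normalize: ", nrow(expr$counts), " genes retained, ",
               nrow(expr$removed_samples), " samples removed")
  emit(write_tsv_file(tibble(sample = colnames(expr$counts)),
                      file.path(out_dir, "retained_samples.tsv")))
  emit(write_tsv_file(expr$gene_stats, file.path(out_dir, "gene_filter.tsv")))
  emit(write_tsv_file(tibble(sample = names(expr$factors$factors),
                             factor = unname(expr$factors$factors)),
                      file.path(out_dir, "factors.tsv")))
  emit(write_counts(round(expr$logcpm, 6), file.path(out_dir, "logcpm.tsv")))

  # --- stage: associate ---------------------------------------------------
  metadata <- assign_strata(metadata)
  assoc <- list()
  for (ph in supported_phenotypes()) {
    res <- tryCatch(
      associate_phenotype(expr, metadata, ph, covariates = config$covariates,
                          moderation = config$moderation),
      error = function(e) {
        pipeline_log(con, "stage associate (", ph, ") skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    assoc[[ph]] <- res
    emit(write_tsv_file(tidy(res), file.path(out_dir, paste0("association_", ph, ".tsv"))))
    pipeline_log(con, "stage associate: ", ph, ", ", sum(res$fdr <= 0.05),
                 " genes at FDR <= 0.05")
  }
  pur <- purity_correlation(expr$logcpm,
                            metadata$purity[match(colnames(expr$logcpm), metadata$donor_id)])
  emit(write_tsv_file(pur, file.path(out_dir, "purity_correlation.tsv")))

  # --- stage: coexpression null -------------------------------------------
  pipeline_log(con, "stage coexpress: ", config$n_pairs, " pairs, seed ",
               config$seeds$null)
  null <- build_null(expr$logcpm, n_pairs = config$n_pairs, seed = config$seeds$null)
  emit(write_null(null, file.path(out_dir, "correlation_null.txt")))
  emit(file.path(out_dir, "correlation_null.txt.json"))

  # --- stage: eqtl ----------------------------------------------------------
  eqtl <- NULL
  if (!is.null(genotypes)) {
    adj <- expr$logcpm
    if (config$batch_adjust_eqtl) {
      batch <- metadata$batch[match(colnames(adj), metadata$donor_id)]
      if (length(unique(batch)) > 1) adj <- batch_adjust(adj, batch)
    }
    pairs <- cis_pairs(annotation, genotypes, window = config$cis_window)
    eqtl <- eqtl_scan(adj, genotypes, pairs)
    emit(write_tsv_file(as_tibble(eqtl), file.path(out_dir, "eqtl.tsv")))
    pipeline_log(con, "stage eqtl: ", nrow(eqtl), " tests, ",
                 sum(eqtl$fdr <= 0.05), " at FDR <= 0.05, ",
                 attr(eqtl, "skipped"), " pairs skipped")
  } else pipeline_log(con, "stage eqtl skipped: no genotypes")

  # --- stage: enrichment ----------------------------------------------------
  enr_rows <- list()
  if (!is.null(config$simulation)) {
    mods <- cohort$truth$coexpr_modules
    for (h in names(mods)) {
      target <- annotation$gene_id[annotation$symbol == h]
      set <- intersect(mods[[h]], rownames(expr$logcpm))
      if (length(set) < 2 || !target %in% rownames(expr$logcpm)) next
      er <- bootstrap_enrichment(set, target, expr$logcpm, null, B = config$B,
                                 seed = config$seeds$enrichment)
      enr_rows[[h]] <- tidy(er)
    }
    if (length(enr_rows)) {
      emit(write_tsv_file(dplyr::bind_rows(enr_rows, .id = "module"),
                          file.path(out_dir, "enrichment.tsv")))
    }
  }

  # --- stage: segments -----------------------------------------------------
  if (!is.null(panel)) {
    mask <- expressed_mask(panel$counts, panel$metadata$tissue,
                           cpm_min = config$cpm_min, frac = config$frac_expressed)
    seg <- classify_segments(mask)
    emit(write_tsv_file(seg, file.path(out_dir, "segments.tsv")))
    pipeline_log(con, "stage segments: ",
                 paste(names(attr(seg, "counts")), as.integer(attr(seg, "counts")),
                       sep = "=", collapse = " "))
  }

  # --- stage: report --------------------------------------------------------
  for (gq in config$report_genes) {
    ann_hit <- tryCatch(resolve_gene(gq, annotation), error = function(e) NULL)
    if (is.null(ann_hit) || !ann_hit$gene_id %in% rownames(expr$logcpm)) next
    gid <- ann_hit$gene_id
    hp <- suppressWarnings(hormone_panel(gid, expr$logcpm, null, annotation))
    cw <- coexpressed_with(gid, expr$logcpm, null, k = 100)
    te <- if (!is.null(eqtl)) eqtl_summaries(dplyr::filter(eqtl, .data$gene_id == gid))$top
    rep <- build_gene_report(gid, annotation, expr$logcpm,
                             associations = assoc, purity = pur,
                             tissue_panel = NULL, hormones = hp,
                             top_coexpressed = cw, top_eqtls = te,
                             gene_stats = expr$gene_stats)
    emit(write_gene_report(rep, file.path(out_dir, paste0("report_", ann_hit$symbol, ".json"))))
  }

  close(con); on.exit(NULL)
  manifest <- tibble(file = basename(c(files, log_path)),
                     md5 = unname(tools::md5sum(c(files, log_path))))
  manifest <- manifest[order(manifest$file), ]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}
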