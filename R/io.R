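#' Read a gene-by-sample count matrix from TSV
#'
#' Expects gene identifiers in the first column and one column per sample.
#' All cells must be non-negative numbers; gene and sample identifiers must be
#' unique.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix with genes in rows, samples in columns.
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2) abort("count table needs a gene-id column plus at least one sample column")
  ids <- tab[[1]]
  if (anyNA(ids) || any(ids == "")) abort("missing gene id in count table")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate gene id(s) in count table: ", paste(head(dup, 5), collapse = ", ")))
  }
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples)) abort("duplicate sample ids in count table header")
  vals <- suppressWarnings(vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, samples))
  if (anyNA(vals)) abort("non-numeric or missing cell in count table")
  if (any(vals < 0)) abort("negative count in count table")
  m <- matrix(as.integer(round(vals)), nrow = nrow(tab),
              dimnames = list(ids, samples))
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  df <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read gene annotation from GTF or a BED-like TSV
#'
#' GTF input uses `gene` features for coordinates and, when `exon` features
#' are present, the merged (union) exonic length per gene; otherwise length is
#' the gene span. TSV input needs columns `gene_id, symbol, chrom, start, end,
#' strand` (1-based inclusive) and optionally `name` and `length`.
#'
#' @param path Path to a `.gtf`/`.gff` file or a tab-separated annotation table.
#' @return Tibble with columns `gene_id, symbol, name, chrom, start, end,
#'   strand, length`.
#' @export
read_annotation <- function(path) {
  ann <- if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE)) {
    read_annotation_gtf(path)
  } else {
    read_annotation_tsv(path)
  }
  validate_annotation(ann)
  ann
}

read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0) abort("GTF contains no gene features")
  gid <- as.character(genes$gene_id)
  sym <- if (!is.null(genes$gene_name)) as.character(genes$gene_name) else gid
  exons <- gr[type == "exon"]
  len <- GenomicRanges::width(genes)
  if (length(exons) > 0) {
    by_gene <- S4Vectors::split(exons, as.character(exons$gene_id))
    merged <- sum(GenomicRanges::width(GenomicRanges::reduce(by_gene)))
    hit <- match(gid, names(merged))
    len[!is.na(hit)] <- as.integer(merged[hit[!is.na(hit)]])
  }
  tibble(
    gene_id = gid,
    symbol = sym,
    name = sym,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    length = as.integer(len)
  )
}

read_annotation_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) abort(paste0("annotation TSV missing column(s): ", paste(miss, collapse = ", ")))
  if (!"name" %in% colnames(tab)) tab$name <- tab$symbol
  if (!"length" %in% colnames(tab)) tab$length <- tab$end - tab$start + 1L
  tibble(
    gene_id = as.character(tab$gene_id), symbol = as.character(tab$symbol),
    name = as.character(tab$name), chrom = as.character(tab$chrom),
    start = as.integer(tab$start), end = as.integer(tab$end),
    strand = as.character(tab$strand), length = as.integer(tab$length)
  )
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) abort("duplicate gene_id in annotation")
  if (any(ann$start > ann$end)) {
    bad <- ann$gene_id[ann$start > ann$end]
    abort(paste0("annotation start > end for: ", paste(head(bad, 5), collapse = ", ")))
  }
  if (!all(ann$strand %in% c("+", "-", "*"))) abort("unknown strand symbol in annotation")
  if (any(ann$length < 1)) abort("annotation length < 1")
  invisible(ann)
}

#' Write gene annotation to TSV
#' @param annotation Annotation tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Read sample phenotypes from CSV
#'
#' Columns: `donor_id, tissue, clinical_t2d, hba1c, bmi, sex, age, purity,
#' stimulatory_index, batch` (missing optional columns are filled with NA).
#'
#' @param path CSV path.
#' @return Tibble of donor phenotypes.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (!"donor_id" %in% colnames(tab)) abort("phenotype table needs a donor_id column")
  for (col in c("tissue", "sex", "batch")) if (!col %in% colnames(tab)) tab[[col]] <- NA_character_
  for (col in c("hba1c", "bmi", "age", "purity", "stimulatory_index")) {
    if (!col %in% colnames(tab)) tab[[col]] <- NA_real_
  }
  if (!"clinical_t2d" %in% colnames(tab)) tab$clinical_t2d <- NA
  tab$clinical_t2d <- as.logical(tab$clinical_t2d)
  if (is.na(tab$tissue[1]) && all(is.na(tab$tissue))) tab$tissue <- "islet"
  key <- paste(tab$donor_id, tab$tissue)
  if (anyDuplicated(key)) abort("donor_id must be unique per tissue in phenotype table")
  ok_pur <- is.na(tab$purity) | (tab$purity >= 0 & tab$purity <= 100)
  if (!all(ok_pur)) abort("purity outside [0, 100]")
  if (any(!is.na(tab$hba1c) & tab$hba1c <= 0)) abort("hba1c must be positive")
  if (any(!is.na(tab$stimulatory_index) & tab$stimulatory_index <= 0)) {
    abort("stimulatory_index must be positive")
  }
  as_tibble(tab[, c("donor_id", "tissue", "clinical_t2d", "hba1c", "bmi", "sex",
                    "age", "purity", "stimulatory_index", "batch")])
}

#' Write sample phenotypes to CSV
#' @param metadata Phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(metadata, path) {
  readr::write_csv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' For VCF input the `DS` FORMAT field is preferred when present (imputed
#' dosage fidelity); otherwise dosages are alt-allele counts from `GT`.
#' Multi-allelic records are split into one biallelic record per alt allele.
#' Dosage-TSV input needs columns `variant_id, chrom, pos, ref, alt` followed
#' by one column per sample. Variants with minor-allele frequency below
#' `maf_min` or zero dosage variance are dropped; the removal counts are kept
#' in the result.
#'
#' @param path Path to a `.vcf`(`.gz`) file or a dosage TSV.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param samples Optional sample ids that must overlap the genotype columns.
#' @return A `genotype_matrix`: list with `variants` (tibble: variant_id,
#'   chrom, pos, ref, alt, maf), `dosage` (variant-by-sample matrix in [0, 2])
#'   and `dropped` (named removal counts).
#' @export
read_genotypes <- function(path, maf_min = 0.05, samples = NULL) {
  raw <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path)
  } else {
    read_genotypes_tsv(path)
  }
  if (!is.null(samples)) {
    common <- intersect(colnames(raw$dosage), samples)
    if (length(common) == 0) abort("genotype samples are disjoint from the metadata samples")
    raw$dosage <- raw$dosage[, common, drop = FALSE]
  }
  new_genotype_matrix(raw$variants, raw$dosage, maf_min = maf_min)
}

new_genotype_matrix <- function(variants, dosage, maf_min = 0) {
  stopifnot(nrow(variants) == nrow(dosage))
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) abort("dosage outside [0, 2]")
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  v <- apply(dosage, 1, var, na.rm = TRUE)
  keep_maf <- maf >= maf_min
  keep_var <- !is.na(v) & v > 0
  keep <- keep_maf & keep_var
  dropped <- c(low_maf = sum(!keep_maf), zero_variance = sum(keep_maf & !keep_var))
  variants <- variants[keep, , drop = FALSE]
  variants$maf <- unname(maf[keep])
  out <- list(variants = as_tibble(variants),
              dosage = dosage[keep, , drop = FALSE],
              dropped = dropped)
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " variants x ", ncol(x$dosage),
      " samples (dropped: ", x$dropped["low_maf"], " low-MAF, ",
      x$dropped["zero_variance"], " monomorphic)\n", sep = "")
  invisible(x)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  fmt <- vcf@gt[, 1]
  ds_avail <- grepl("(^|:)DS(:|$)", fmt)
  ds <- if (any(ds_avail)) suppressWarnings(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)) else NULL
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(vcf@gt)[-1]
  rows <- list(); dos <- list()
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    if (is.na(pos)) abort(paste0("malformed VCF record at line ", i, ": bad POS"))
    for (a in seq_along(alts)) {
      if (length(alts) == 1 && !is.null(ds) && ds_avail[i] && !all(is.na(ds[i, ]))) {
        d <- as.numeric(ds[i, ])
      } else {
        g <- gt[i, ]
        d <- count_alt_allele(g, a, line = i)
      }
      vid0 <- fix[i, "ID"]
      vid <- if (is.na(vid0) || vid0 == ".") {
        paste0(fix[i, "CHROM"], ":", pos, "_", fix[i, "REF"], "_", alts[a])
      } else if (length(alts) > 1) paste0(vid0, "_alt", a) else vid0
      rows[[length(rows) + 1L]] <- tibble(
        variant_id = vid, chrom = as.character(fix[i, "CHROM"]), pos = pos,
        ref = as.character(fix[i, "REF"]), alt = alts[a])
      dos[[length(dos) + 1L]] <- d
    }
  }
  dosage <- do.call(rbind, dos)
  variants <- dplyr::bind_rows(rows)
  rownames(dosage) <- variants$variant_id
  colnames(dosage) <- samples
  list(variants = variants, dosage = dosage)
}

count_alt_allele <- function(gt, alt_index, line = NA) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_real_, length(gt))
  ok <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  toks <- strsplit(gt[ok], "[/|]")
  bad <- vapply(toks, function(t) any(!grepl("^[0-9]+$", t)), logical(1))
  if (any(bad)) abort(paste0("malformed GT in VCF record at line ", line))
  out[ok] <- vapply(toks, function(t) sum(t == as.character(alt_index)), numeric(1))
  out
}

read_genotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) abort(paste0("dosage TSV missing column(s): ", paste(miss, collapse = ", ")))
  samples <- setdiff(colnames(tab), need)
  if (length(samples) == 0) abort("dosage TSV has no sample columns")
  dosage <- as.matrix(tab[, samples])
  mode(dosage) <- "numeric"
  rownames(dosage) <- tab$variant_id
  variants <- tibble(variant_id = as.character(tab$variant_id),
                     chrom = as.character(tab$chrom), pos = as.integer(tab$pos),
                     ref = as.character(tab$ref), alt = as.character(tab$alt))
  list(variants = variants, dosage = dosage)
}

#' Write genotypes as a plain VCF
#'
#' Integer dosages are written as GT calls, fractional dosages as a DS field.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosage
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]; d <- d[ord, , drop = FALSE]
  integral <- all(abs(d - round(d)) < 1e-9, na.rm = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               if (integral) "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
               else "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                       "FORMAT", colnames(d)), collapse = "\t")), con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(v))) {
    cells <- if (integral) {
      ifelse(is.na(d[i, ]), "./.", gt_of[round(d[i, ]) + 1L])
    } else {
      ifelse(is.na(d[i, ]), ".", formatC(d[i, ], format = "g", digits = 6))
    }
    writeLines(paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
                       ".", "PASS", ".", if (integral) "GT" else "DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Resolve a gene query against an annotation table
#'
#' Matching order: exact `gene_id`, then case-insensitive `symbol`, then
#' case-insensitive full `name`. An ambiguous symbol raises an error listing
#' all candidate gene ids; an unmatched query raises a not-found error that
#' suggests symbols within edit distance 2.
#'
#' @param query Gene id, symbol, or full name.
#' @param annotation Annotation tibble ([read_annotation()]).
#' @return One-row annotation tibble.
#' @export
resolve_gene <- function(query, annotation) {
  if (!nzchar(query)) abort("empty gene query")
  hit <- annotation[annotation$gene_id == query, , drop = FALSE]
  if (nrow(hit) == 0) hit <- annotation[tolower(annotation$symbol) == tolower(query), , drop = FALSE]
  if (nrow(hit) == 0) hit <- annotation[tolower(annotation$name) == tolower(query), , drop = FALSE]
  if (nrow(hit) > 1) {
    abort(paste0("ambiguous gene query '", query, "': matches ",
                 paste(hit$gene_id, collapse = ", ")))
  }
  if (nrow(hit) == 0) {
    dist <- utils::adist(tolower(query), tolower(annotation$symbol))[1, ]
    near <- unique(annotation$symbol[dist <= 2])
    abort(paste0("gene '", query, "' not found",
                 if (length(near)) paste0("; did you mean: ", paste(head(near, 5), collapse = ", "))
                 else ""))
  }
  hit
}
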