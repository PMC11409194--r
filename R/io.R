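# File interfaces. Tab-separated text with a header row everywhere;
# genotypes additionally as VCF 4.2 (GT field only), read through vcfR.
# Coordinates are 1-based inclusive throughout (VCF convention).

#' Write a data.frame as TSV (tab-separated, header, no quoting)
#' @param x data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

.require_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(what, " missing column(s): ", paste(miss, collapse = ", "))
  invisible(x)
}

#' Read a pQTL catalog TSV
#'
#' Expected columns: `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `protein_id`, `gene`, `beta`, `p_value`, `source`.
#' @param path Input file.
#' @return Catalog data.frame.
#' @export
read_catalog <- function(path) {
  x <- read_tsv(path)
  .require_cols(x, .catalog_cols, "catalog")
  x
}

#' Read a gene annotation TSV (columns `gene`, `chrom`, `tss`)
#' @param path Input file.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  x <- read_tsv(path)
  .require_cols(x, c("gene", "chrom", "tss"), "annotation")
  x
}

#' Read a covariate table (columns `sample_id`, `status`, `age_group`)
#' @param path Input file.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  x <- read_tsv(path)
  .require_cols(x, c("sample_id", "status", "age_group"), "covariates")
  x
}

#' Read a protein abundance matrix TSV
#'
#' First column `protein_id`, remaining columns one per sample. For the
#' plasma compartment, groups come from a covariate table; for tissue, the
#' sample columns must be named `<pair>_tumor` / `<pair>_adjacent`.
#'
#' @param path Input file.
#' @param compartment `"plasma"` or `"tissue"`.
#' @param covariates Covariate data.frame (required for plasma).
#' @return A [protein_matrix()].
#' @export
read_protein_matrix <- function(path, compartment = c("plasma", "tissue"),
                                covariates = NULL) {
  compartment <- match.arg(compartment)
  x <- read_tsv(path)
  if (names(x)[1L] != "protein_id") stop("first column must be protein_id")
  v <- as.matrix(x[, -1L, drop = FALSE])
  rownames(v) <- x$protein_id
  if (compartment == "plasma") {
    if (is.null(covariates)) stop("plasma matrix needs a covariate table")
    st <- covariates$status[match(colnames(v), covariates$sample_id)]
    if (anyNA(st)) stop("sample(s) missing from covariates: ",
                        paste(colnames(v)[is.na(st)], collapse = ", "))
    protein_matrix(v, ifelse(st == 1, "case", "control"), "plasma")
  } else {
    grp <- sub(".*_", "", colnames(v))
    if (!all(grp %in% c("tumor", "adjacent")))
      stop("tissue columns must be named <pair>_tumor / <pair>_adjacent")
    protein_matrix(v, grp, "tissue", pair_id = sub("_[^_]*$", "", colnames(v)))
  }
}

#' Write a protein matrix as TSV
#' @param matrix A [protein_matrix()].
#' @param path Output file.
#' @export
write_protein_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "protein_matrix"))
  df <- data.frame(protein_id = .protein_ids(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write genotypes as VCF 4.2 (GT only)
#'
#' REF is the non-effect allele and ALT the effect allele, so the ALT
#' dosage equals the effect-allele dosage. Missing dosages become `./.`.
#'
#' @param genotypes A [genotype_data()].
#' @param path Output file (plain text).
#' @export
write_genotype_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_data"))
  gt <- matrix(c("0/0", "0/1", "1/1")[genotypes$dosage + 1L],
               nrow = nrow(genotypes$dosage))
  gt[is.na(genotypes$dosage)] <- "./."
  info <- genotypes$snp_info
  body <- cbind(info$chrom, info$pos, info$snp_id, info$other_allele,
                info$effect_allele, ".", "PASS", ".", "GT", gt)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$samples$sample_id),
                   collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# GT string -> ALT-allele dosage; phase separators | and / are equivalent.
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
              "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)
  out <- lookup[gt]  # NA input (already-decoded missing) stays NA
  bad <- !is.na(gt) & !(gt %in% names(lookup))
  if (any(bad))
    stop("malformed GT value(s): ", paste(unique(gt[bad]), collapse = ", "))
  out
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF: biallelic records only; multiallelic sites are skipped with a
#' warning; GT is the only FORMAT field used; ALT counts as the effect
#' allele; sample order is preserved. TSV dialect: columns `snp_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, then one dosage column
#' per sample.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"`.
#' @param covariates Optional covariate data.frame supplying `status` and
#'   `age_group` per sample.
#' @return A [genotype_data()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"),
                           covariates = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))  # single-record files come back as a vector
      fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi)) {
      warning("skipping ", sum(multi), " multiallelic site(s): ",
              paste(fix[multi, "ID"], collapse = ", "))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt)))
      gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    dos <- matrix(.gt_to_dosage(as.vector(gt)), nrow = nrow(gt))
    snp_info <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                           pos = as.numeric(fix[, "POS"]),
                           effect_allele = fix[, "ALT"],
                           other_allele = fix[, "REF"],
                           stringsAsFactors = FALSE)
    sample_ids <- colnames(gt)
  } else {
    x <- read_tsv(path)
    meta <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
    .require_cols(x, meta, "dosage TSV")
    dos <- as.matrix(x[, setdiff(names(x), meta), drop = FALSE])
    snp_info <- x[, meta]
    sample_ids <- colnames(dos)
  }
  samples <- data.frame(sample_id = sample_ids, status = NA_integer_,
                        age_group = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    i <- match(sample_ids, covariates$sample_id)
    samples$status <- as.integer(covariates$status[i])
    samples$age_group <- as.integer(covariates$age_group[i])
  }
  genotype_data(dos, snp_info, samples)
}

#' Write a full simulated cohort to disk
#'
#' Emits `genotypes.vcf`, `plasma.tsv`, `tissue.tsv`, `covariates.tsv`,
#' `catalog.tsv` and `annotation.tsv` into `dir`. The files round-trip
#' losslessly through the corresponding readers, and two runs from the
#' same configuration are byte-identical.
#'
#' @param cohort list as returned by [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  write_genotype_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_protein_matrix(cohort$plasma, file.path(dir, "plasma.tsv"))
  write_protein_matrix(cohort$tissue, file.path(dir, "tissue.tsv"))
  write_tsv(cohort$genotypes$samples, file.path(dir, "covariates.tsv"))
  write_tsv(cohort$catalog, file.path(dir, "catalog.tsv"))
  write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  invisible(dir)
}

#' Simulate a complete cohort from a configuration
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_phenotype()], [simulate_proteomics()], [simulate_catalog()]
#' and [gene_annotation()].
#'
#' @param config A [sim_config()].
#' @return list with `genotypes`, `plasma`, `tissue`, `catalog`,
#'   `annotation`.
#' @export
simulate_cohort <- function(config) {
  gt <- simulate_phenotype(simulate_genotypes(config), config)
  prot <- simulate_proteomics(gt, config)
  list(genotypes = gt, plasma = prot$plasma, tissue = prot$tissue,
       catalog = simulate_catalog(config), annotation = gene_annotation(config))
}
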