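#' Protein abundance matrix with sample metadata
#'
#' Container for a proteins-by-samples matrix of log2 abundances together
#' with the per-sample grouping needed by the differential-expression tests.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns.
#'   Rownames are protein ids, colnames sample ids; both are required and
#'   must be unique.
#' @param group Character/factor of length `ncol(values)`; levels
#'   `c("case", "control")` for unpaired plasma designs or
#'   `c("tumor", "adjacent")` for paired tissue designs.
#' @param compartment `"plasma"` or `"tissue"`.
#' @param pair_id Subject label per column for paired designs (each id must
#'   appear exactly once per group), or `NULL` for unpaired designs.
#'
#' @return An object of class `protein_matrix`: a list with elements
#'   `values`, `group`, `compartment`, `pair_id`.
#' @export
protein_matrix <- function(values, group,
                           compartment = c("plasma", "tissue"),
                           pair_id = NULL) {
  compartment <- match.arg(compartment)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("`values` needs protein ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein_ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` must have one entry per sample column")
  if (!is.null(pair_id)) {
    pair_id <- as.character(pair_id)
    if (length(pair_id) != ncol(values))
      stop("`pair_id` must have one entry per sample column")
    tab <- table(pair_id, group)
    bad <- rownames(tab)[apply(tab, 1L, function(r) any(r != 1L))]
    if (length(bad))
      stop("pair_id(s) without exactly one column per group: ",
           paste(bad, collapse = ", "))
  }
  structure(list(values = values, group = group,
                 compartment = compartment, pair_id = pair_id),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix (%s): %d proteins x %d samples [%s]\n",
              x$compartment, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Genotype dosages with SNP metadata and sample phenotypes
#'
#' Biallelic genotypes coded as effect-allele dosage 0/1/2 (`NA` = missing),
#' SNPs in rows and samples in columns.
#'
#' @param dosage Integer matrix of dosages, rownames = SNP ids, colnames =
#'   sample ids.
#' @param snp_info data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, aligned with the rows of `dosage`.
#' @param samples data.frame with columns `sample_id`, `status` (1 = case,
#'   0 = control, `NA` if not yet assigned) and `age_group` (0 = 60 or
#'   younger, 1 = over 60, `NA` allowed), aligned with the columns.
#'
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosage, snp_info, samples) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  storage.mode(dosage) <- "integer"
  if (!all(dosage %in% c(0L, 1L, 2L, NA_integer_)))
    stop("dosages must be 0, 1, 2 or NA")
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(need %in% names(snp_info)))
    stop("snp_info missing column(s): ",
         paste(setdiff(need, names(snp_info)), collapse = ", "))
  if (nrow(snp_info) != nrow(dosage))
    stop("snp_info rows must match dosage rows")
  if (anyDuplicated(snp_info$snp_id))
    stop("duplicate snp_id: ",
         paste(unique(snp_info$snp_id[duplicated(snp_info$snp_id)]),
               collapse = ", "))
  if (!all(c("sample_id", "status", "age_group") %in% names(samples)))
    stop("samples needs columns sample_id, status, age_group")
  if (nrow(samples) != ncol(dosage))
    stop("samples rows must match dosage columns")
  rownames(dosage) <- snp_info$snp_id
  colnames(dosage) <- samples$sample_id
  rownames(snp_info) <- NULL
  rownames(samples) <- NULL
  structure(list(dosage = dosage, snp_info = snp_info, samples = samples),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  st <- x$samples$status
  cat(sprintf("genotype_data: %d SNPs x %d samples (%d cases, %d controls, %d unlabeled)\n",
              nrow(x$dosage), ncol(x$dosage),
              sum(st == 1L, na.rm = TRUE), sum(st == 0L, na.rm = TRUE),
              sum(is.na(st))))
  invisible(x)
}

# rownames helper tolerating empty matrices (R drops character(0) dimnames)
.protein_ids <- function(values) {
  if (is.null(rownames(values))) character(0) else rownames(values)
}
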