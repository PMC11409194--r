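# Candidate pQTL-SNP selection: catalog merging with allele harmonization,
# cis-window restriction, minor-allele-frequency filtering against a
# reference genotype panel, and greedy LD pruning on dosage r-squared.

.catalog_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "protein_id", "gene", "beta", "p_value", "source")

.check_catalog <- function(x) {
  miss <- setdiff(.catalog_cols, names(x))
  if (length(miss))
    stop("catalog missing column(s): ", paste(miss, collapse = ", "))
  if (any(x$p_value <= 0 | x$p_value > 1)) stop("catalog p_value must lie in (0, 1]")
  if (any(x$effect_allele == x$other_allele))
    stop("effect and other allele identical for: ",
         paste(x$snp_id[x$effect_allele == x$other_allele], collapse = ", "))
  x[, .catalog_cols]
}

#' Merge pQTL catalogs restricted to a protein set
#'
#' Takes the union of records across catalogs whose target protein is in
#' `restrict_to`. Effect alleles are harmonized against the first catalog
#' that mentions each SNP: records with swapped effect/other alleles have
#' their beta sign flipped (with a warning); records whose alleles neither
#' match nor swap are dropped with a message. When the same
#' (snp_id, protein_id) appears in several sources the record with the
#' smallest p-value is kept and all contributing sources are recorded
#' (semicolon-separated `source`).
#'
#' @param catalogs list of catalog data.frames (see [read_catalog()] for
#'   the column layout).
#' @param restrict_to Character vector of protein ids to keep (e.g. the
#'   `protein_id` column of [intersect_consistent()] output), or `NULL` for
#'   no restriction.
#' @return A merged, deduplicated catalog data.frame.
#' @export
merge_catalogs <- function(catalogs, restrict_to = NULL) {
  stopifnot(is.list(catalogs), length(catalogs) >= 1L)
  recs <- do.call(rbind, lapply(catalogs, .check_catalog))
  # allele harmonization against the first occurrence of each snp_id
  first <- !duplicated(recs$snp_id)
  ref_ea <- setNames(recs$effect_allele[first], recs$snp_id[first])
  ref_oa <- setNames(recs$other_allele[first], recs$snp_id[first])
  swapped <- recs$effect_allele == ref_oa[recs$snp_id] &
    recs$other_allele == ref_ea[recs$snp_id]
  matched <- recs$effect_allele == ref_ea[recs$snp_id] &
    recs$other_allele == ref_oa[recs$snp_id]
  if (any(swapped)) {
    warning("allele labels swapped relative to first catalog for ",
            paste(unique(recs$snp_id[swapped]), collapse = ", "),
            "; beta sign flipped")
    recs$beta[swapped] <- -recs$beta[swapped]
    recs$effect_allele[swapped] <- ref_ea[recs$snp_id[swapped]]
    recs$other_allele[swapped] <- ref_oa[recs$snp_id[swapped]]
  }
  unresolved <- !matched & !swapped
  if (any(unresolved)) {
    message("dropping ", sum(unresolved),
            " record(s) with unresolvable allele labels: ",
            paste(unique(recs$snp_id[unresolved]), collapse = ", "))
    recs <- recs[!unresolved, , drop = FALSE]
  }
  if (!is.null(restrict_to))
    recs <- recs[recs$protein_id %in% restrict_to, , drop = FALSE]
  if (nrow(recs) == 0L) return(recs)
  key <- paste(recs$snp_id, recs$protein_id, sep = "\r")
  all_src <- vapply(split(recs$source, key),
                    function(s) paste(unique(s), collapse = ";"), "")
  recs <- recs[order(key, recs$p_value), , drop = FALSE]
  keep <- !duplicated(paste(recs$snp_id, recs$protein_id, sep = "\r"))
  recs <- recs[keep, , drop = FALSE]
  recs$source <- unname(all_src[paste(recs$snp_id, recs$protein_id, sep = "\r")])
  rownames(recs) <- NULL
  recs
}

#' Keep cis records: SNP within a window of the target gene's TSS
#'
#' A record is cis when the SNP lies on the same chromosome as its target
#' gene and within `window` base pairs of the transcription start site
#' (closed interval, so a SNP exactly `window` bp away is kept). Records
#' whose gene is absent from the annotation are dropped with a message.
#'
#' @param records Catalog data.frame.
#' @param annotation data.frame with columns `gene`, `chrom`, `tss`.
#' @param window Window half-width in base pairs (default 1 Mb, the usual
#'   cis convention of plasma pQTL catalogs).
#' @return The cis subset of `records`.
#' @export
filter_cis <- function(records, annotation, window = 1e6) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(annotation)))
  i <- match(records$gene, annotation$gene)
  if (anyNA(i)) {
    message("dropping ", sum(is.na(i)), " record(s) with unannotated gene: ",
            paste(unique(records$gene[is.na(i)]), collapse = ", "))
  }
  keep <- !is.na(i) &
    records$chrom == annotation$chrom[i] &
    abs(records$pos - annotation$tss[i]) <= window
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minor allele frequencies of a reference genotype panel
#'
#' `maf = min(f, 1 - f)` where `f` is the effect-allele frequency
#' `sum(dosage) / (2 * n_nonmissing)`. SNPs with all genotypes missing get
#' `maf = NA` and are flagged.
#'
#' @param panel A [genotype_data()] reference panel.
#' @return data.frame with columns `snp_id`, `maf`, `n_nonmissing`.
#' @export
compute_maf <- function(panel) {
  stopifnot(inherits(panel, "genotype_data"))
  n_ok <- rowSums(!is.na(panel$dosage))
  f <- rowSums(panel$dosage, na.rm = TRUE) / (2 * n_ok)
  maf <- pmin(f, 1 - f)
  maf[n_ok == 0L] <- NA_real_
  if (any(n_ok == 0L))
    warning("MAF undefined (all genotypes missing) for: ",
            paste(panel$snp_info$snp_id[n_ok == 0L], collapse = ", "))
  data.frame(snp_id = panel$snp_info$snp_id, maf = maf,
             n_nonmissing = as.integer(n_ok), stringsAsFactors = FALSE)
}

#' Filter records by minor allele frequency
#'
#' Keeps records whose SNP has `maf > threshold` in the panel (strict
#' inequality, so a SNP at exactly the threshold is dropped). Records
#' without panel statistics are dropped with a message.
#'
#' @param records Catalog data.frame.
#' @param stats Output of [compute_maf()].
#' @param threshold MAF threshold (default 0.05).
#' @return Filtered records.
#' @export
filter_maf <- function(records, stats, threshold = 0.05) {
  m <- stats$maf[match(records$snp_id, stats$snp_id)]
  no_stats <- is.na(m)
  if (any(no_stats))
    message("dropping ", sum(no_stats),
            " record(s) without panel MAF: ",
            paste(unique(records$snp_id[no_stats]), collapse = ", "))
  out <- records[!no_stats & m > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Squared dosage correlation between two SNPs (composite LD)
#'
#' @param dosages_a,dosages_b Effect-allele dosage vectors of equal length
#'   (>= 3), both polymorphic.
#' @return Squared Pearson correlation, in `[0, 1]`.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b) || length(dosages_a) < 3L)
    stop("dosage vectors must have equal length >= 3")
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (var(dosages_a[ok]) == 0 || var(dosages_b[ok]) == 0)
    stop("LD undefined: monomorphic input")
  min(cor(dosages_a[ok], dosages_b[ok])^2, 1)
}

#' Greedy LD pruning of catalog records
#'
#' Records are visited by ascending pQTL p-value (ties broken by
#' chromosome, position, then snp_id). A record's SNP is accepted iff its
#' dosage r-squared with every already-accepted SNP on the same chromosome
#' is strictly below `r2_threshold`; all records of accepted SNPs are kept.
#' SNPs absent from the panel are treated as unlinked (kept, with a
#' message).
#'
#' @param records Catalog data.frame.
#' @param panel A [genotype_data()] supplying dosages.
#' @param r2_threshold LD threshold in (0, 1] (default 0.80).
#' @return Pruned records; all retained same-chromosome pairs have
#'   `ld_r2 < r2_threshold`.
#' @export
ld_prune <- function(records, panel, r2_threshold = 0.8) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  if (nrow(records) == 0L) return(records)
  ord <- order(records$p_value, records$chrom, records$pos, records$snp_id)
  recs <- records[ord, , drop = FALSE]
  in_panel <- recs$snp_id %in% panel$snp_info$snp_id
  if (any(!in_panel))
    message("SNP(s) absent from LD panel treated as unlinked: ",
            paste(unique(recs$snp_id[!in_panel]), collapse = ", "))
  accepted <- character(0)
  rejected <- character(0)
  keep <- logical(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    id <- recs$snp_id[i]
    if (id %in% accepted) { keep[i] <- TRUE; next }
    if (id %in% rejected) next
    ok <- TRUE
    if (id %in% panel$snp_info$snp_id) {
      same_chr <- accepted[recs$chrom[match(accepted, recs$snp_id)] == recs$chrom[i]]
      same_chr <- intersect(same_chr, panel$snp_info$snp_id)
      r2_or_zero <- function(a, b) {
        ok <- !is.na(a) & !is.na(b)
        if (var(a[ok]) == 0 || var(b[ok]) == 0) return(0)  # monomorphic: unlinked
        ld_r2(a, b)
      }
      for (a in same_chr) {
        if (r2_or_zero(panel$dosage[id, ], panel$dosage[a, ]) >= r2_threshold) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) accepted <- c(accepted, id) else rejected <- c(rejected, id)
    keep[i] <- ok
  }
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
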