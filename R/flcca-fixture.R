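# Bundled worked example: the seven pQTL-SNPs associated with female lung
# adenocarcinoma (LUAD) risk in the FLCCA GWAS (3453 never-smoking cases,
# 3710 controls), with their published genotype-by-status counts, the
# age-adjusted additive-model p-values, and the effect-allele signs of
# their plasma pQTL effects from the deCODE (Iceland) / FinnGen-style
# (Finland) catalogs. All six target proteins (COL6A3, BST1, ANTXR2,
# SPARCL1, NRP1, APOH) are down-regulated in both LUAD plasma and tumor
# tissue, i.e. tumor-suppressor roles. Catalog p-values below the double
# floating-point range are clamped to 1e-300; only the sign enters the
# concordance rule.

.flcca_file <- function(name) {
  f <- system.file("extdata", name, package = "pqtlscreen")
  if (f == "") f <- file.path("inst", "extdata", name)  # pre-install fallback
  f
}

#' Published FLCCA genotype counts for the seven LUAD-associated pQTL-SNPs
#'
#' Genotype-by-status contingency counts (reference homozygote = major
#' allele), plus the published age-adjusted additive odds ratio and
#' p-value per SNP.
#'
#' @return data.frame with the [genotype_counts()] layout plus `gene`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `adj_additive_or`,
#'   `adj_additive_p`.
#' @export
flcca_counts <- function() {
  read_tsv(.flcca_file("flcca_genotype_counts.tsv"))
}

#' pQTL effect signs and roles for the FLCCA SNPs
#'
#' Effect-allele signs of the catalog pQTL effects (`beta_sign`, +1 when
#' the variant allele raises the target protein) and the tumor-suppressor
#' role labels from the two-compartment differential-expression screen.
#'
#' @return data.frame with columns `snp_id`, `protein_id`, `gene`,
#'   `beta_sign`, `p_value`, `role`.
#' @export
flcca_effects <- function() {
  read_tsv(.flcca_file("flcca_pqtl_effects.tsv"))
}

#' Catalog records for the FLCCA fixture
#'
#' The published catalogs report beta magnitudes only graphically, so
#' `beta` carries the sign (+/-1); the concordance rule depends on the
#' sign alone.
#'
#' @return Catalog data.frame in the [read_catalog()] layout.
#' @export
flcca_catalog <- function() {
  cnt <- flcca_counts()
  eff <- flcca_effects()
  i <- match(eff$snp_id, cnt$snp_id)
  data.frame(snp_id = eff$snp_id, chrom = cnt$chrom[i], pos = cnt$pos[i],
             effect_allele = cnt$effect_allele[i],
             other_allele = cnt$other_allele[i],
             protein_id = eff$protein_id, gene = eff$gene,
             beta = eff$beta_sign, p_value = eff$p_value,
             source = "flcca_fixture", stringsAsFactors = FALSE)
}

# Expand a counts row into per-subject dosage and status vectors.
.expand_counts <- function(row) {
  list(g = c(rep(0:2, times = c(row$case_ref, row$case_het, row$case_hom)),
             rep(0:2, times = c(row$ctrl_ref, row$ctrl_het, row$ctrl_hom))),
       y = rep(1:0, times = c(row$case_ref + row$case_het + row$case_hom,
                              row$ctrl_ref + row$ctrl_het + row$ctrl_hom)))
}

#' Additive-model association results for the FLCCA fixture
#'
#' Refits the (unadjusted) additive logistic model per SNP from the
#' published genotype counts with [logistic_fit()], giving the odds-ratio
#' direction; the significance gate uses the published age-adjusted
#' additive p-values, since individual ages are not released. Directions
#' of the refitted crude ORs agree with the published adjusted ones for
#' all seven SNPs.
#'
#' @return data.frame in the [association_scan()] additive-row layout.
#' @export
flcca_association <- function() {
  cnt <- flcca_counts()
  rows <- lapply(seq_len(nrow(cnt)), function(i) {
    d <- .expand_counts(cnt[i, ])
    fit <- logistic_fit(cbind(`(Intercept)` = 1, additive = d$g), d$y)
    b <- fit$coef["additive"]; s <- fit$se["additive"]
    data.frame(snp_id = cnt$snp_id[i], model = "additive",
               or = exp(unname(b)),
               ci_low = exp(unname(b - 1.96 * s)),
               ci_high = exp(unname(b + 1.96 * s)),
               p_value = cnt$adj_additive_p[i],
               crude_p = unname(fit$p_value[2L]),
               adjusted = TRUE, covariates = "age_group",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance verdicts for the FLCCA fixture
#'
#' Runs [select_candidates()] on the seven published SNPs: additive OR
#' directions refitted from the genotype counts, catalog beta signs, and
#' tumor-suppressor roles for all six target proteins.
#'
#' @param alpha Significance threshold on the (age-adjusted) additive p.
#' @return As [select_candidates()]: list with `verdicts` and
#'   `candidates`.
#' @export
flcca_candidates <- function(alpha = 0.05) {
  eff <- flcca_effects()
  roles <- unique(eff[, c("protein_id", "role")])
  select_candidates(flcca_association(), flcca_catalog(), roles,
                    alpha = alpha)
}
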