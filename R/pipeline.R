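# End-to-end orchestration of the screen on a (simulated or loaded)
# cohort: differential expression -> catalog filtering -> association ->
# concordance -> biomarker ROC, with a machine-readable manifest of
# per-stage record counts.

.subset_snps <- function(genotypes, snp_ids) {
  i <- match(snp_ids, genotypes$snp_info$snp_id)
  genotype_data(genotypes$dosage[i, , drop = FALSE],
                genotypes$snp_info[i, , drop = FALSE],
                genotypes$samples)
}

#' Run the full pQTL screening pipeline on a cohort
#'
#' Executes, in order: direction-consistent differential-expression
#' intersection (plasma unpaired, tissue paired), catalog restriction to
#' the labeled proteins, cis / MAF / LD filters, the multi-model
#' association scan, the concordance classifier, and ROC evaluation of the
#' candidate proteins in plasma. The cohort's own genotypes serve as the
#' LD/MAF reference panel. Record counts per stage are collected in a
#' manifest; with `out_dir` set, every stage table plus `summary.json` is
#' written, and reruns under the same configuration are byte-identical.
#'
#' @param config A [sim_config()]; the cohort is simulated from it. Pass a
#'   ready-made cohort list (as from [simulate_cohort()]) via `cohort` to
#'   skip simulation.
#' @param out_dir Output directory, or `NULL` for no files.
#' @param cohort Optional pre-built cohort list.
#' @param alpha Significance level for the DE screen and the association
#'   flag.
#' @param maf_threshold Strict lower MAF bound.
#' @param r2_threshold LD pruning threshold.
#' @param cis_window Cis window half-width in bp.
#' @param models Genetic models for the association scan.
#' @param adjust Covariates for the adjusted fits.
#' @return list with `roles`, `snps`, `association`, `verdicts`,
#'   `candidates`, `roc`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL,
                         alpha = 0.05, maf_threshold = 0.05,
                         r2_threshold = 0.8, cis_window = 1e6,
                         models = c("het_vs_ref", "hom_vs_ref", "dominant",
                                    "recessive", "additive"),
                         adjust = "age_group") {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  gt <- cohort$genotypes

  de_plasma <- de_test_unpaired(cohort$plasma, alpha)
  de_tissue <- de_test_paired(cohort$tissue, alpha)
  roles <- intersect_consistent(de_plasma, de_tissue, alpha)

  merged <- merge_catalogs(list(cohort$catalog),
                           restrict_to = roles$protein_id)
  cis <- filter_cis(merged, cohort$annotation, window = cis_window)
  panel_maf <- compute_maf(gt)
  maf_ok <- filter_maf(cis, panel_maf, maf_threshold)
  pruned <- ld_prune(maf_ok, gt, r2_threshold)

  if (nrow(pruned) > 0L) {
    assoc <- association_scan(.subset_snps(gt, unique(pruned$snp_id)),
                              models = models, adjust = adjust,
                              alpha = alpha)
    conc <- select_candidates(assoc, pruned, roles, alpha = alpha)
  } else {
    assoc <- data.frame()
    conc <- list(verdicts = data.frame(), candidates = data.frame())
  }

  roc <- list()
  cand_prot <- intersect(unique(conc$candidates$protein_id),
                         rownames(cohort$plasma$values))
  status <- as.integer(cohort$plasma$group == "case")
  for (p in cand_prot)
    roc[[p]] <- auc_mann_whitney(cohort$plasma$values[p, ], status,
                                 marker = p, seed = config$seed + 3L)
  if (length(cand_prot) >= 2L)
    roc[["combined"]] <- combined_score(
      cohort$plasma$values[cand_prot, , drop = FALSE], status,
      seed = config$seed + 3L)

  manifest <- list(
    seed = config$seed,
    params = list(alpha = alpha, maf_threshold = maf_threshold,
                  r2_threshold = r2_threshold, cis_window = cis_window,
                  models = models, adjust = adjust),
    counts = list(
      proteins_total = nrow(cohort$plasma$values),
      de_plasma = sum(de_plasma$direction != "flat"),
      de_tissue = sum(de_tissue$direction != "flat"),
      proteins_consistent = nrow(roles),
      catalog_records = nrow(cohort$catalog),
      after_protein_restriction = nrow(merged),
      after_cis = nrow(cis),
      after_maf = nrow(maf_ok),
      after_ld = nrow(pruned),
      snps_tested = length(unique(pruned$snp_id)),
      snps_significant = if (nrow(assoc)) length(unique(
        assoc$snp_id[assoc$model == "additive" & assoc$significant])) else 0L,
      candidates = nrow(conc$candidates)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(de_plasma, file.path(out_dir, "de_plasma.tsv"))
    write_tsv(de_tissue, file.path(out_dir, "de_tissue.tsv"))
    write_tsv(roles, file.path(out_dir, "roles.tsv"))
    write_tsv(pruned, file.path(out_dir, "snps_selected.tsv"))
    if (nrow(assoc)) write_tsv(assoc, file.path(out_dir, "association.tsv"))
    if (nrow(conc$verdicts))
      write_tsv(conc$verdicts, file.path(out_dir, "verdicts.tsv"))
    if (length(roc)) {
      roc_df <- do.call(rbind, lapply(roc, function(r)
        data.frame(marker = r$marker, auc = r$auc, ci_low = r$ci_low,
                   ci_high = r$ci_high, n_cases = r$n_cases,
                   n_controls = r$n_controls, stringsAsFactors = FALSE)))
      write_tsv(roc_df, file.path(out_dir, "roc.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(roles = roles, snps = pruned, association = assoc,
       verdicts = conc$verdicts, candidates = conc$candidates,
       roc = roc, manifest = manifest)
}
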