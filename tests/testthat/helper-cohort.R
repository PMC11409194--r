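# Shared builders for small in-code fixtures.

toy_plasma <- function(values, status) {
  v <- as.matrix(values)
  if (is.null(rownames(v))) rownames(v) <- sprintf("P%02d", seq_len(nrow(v)))
  colnames(v) <- sprintf("S%02d", seq_len(ncol(v)))
  protein_matrix(v, ifelse(status == 1, "case", "control"), "plasma")
}

toy_tissue <- function(tumor, adjacent) {
  tu <- as.matrix(tumor); ad <- as.matrix(adjacent)
  n <- ncol(tu)
  v <- matrix(0, nrow(tu), 2 * n)
  v[, seq(1, 2 * n, 2)] <- tu
  v[, seq(2, 2 * n, 2)] <- ad
  pair <- sprintf("T%02d", seq_len(n))
  rownames(v) <- if (is.null(rownames(tu)))
    sprintf("P%02d", seq_len(nrow(tu))) else rownames(tu)
  colnames(v) <- paste0(rep(pair, each = 2), c("_tumor", "_adjacent"))
  protein_matrix(v, rep(c("tumor", "adjacent"), n), "tissue",
                 pair_id = rep(pair, each = 2))
}

toy_gt <- function(dosage, status = NULL, age = NULL,
                   chrom = NULL, pos = NULL) {
  d <- as.matrix(dosage)
  n_snp <- nrow(d); n_s <- ncol(d)
  if (is.null(rownames(d))) rownames(d) <- sprintf("rs%03d", seq_len(n_snp))
  snp_info <- data.frame(snp_id = rownames(d),
                         chrom = if (is.null(chrom)) rep("chr1", n_snp) else chrom,
                         pos = if (is.null(pos)) seq_len(n_snp) * 1000 else pos,
                         effect_allele = rep("A", n_snp),
                         other_allele = rep("G", n_snp),
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n_s)),
                        status = if (is.null(status)) NA_integer_ else as.integer(status),
                        age_group = if (is.null(age)) NA_integer_ else as.integer(age),
                        stringsAsFactors = FALSE)
  genotype_data(d, snp_info, samples)
}

toy_catalog <- function(snp_id, protein_id, beta = 1, p_value = 1e-6,
                        source = "cat1", chrom = "chr1", pos = 1000,
                        effect_allele = "A", other_allele = "G",
                        gene = protein_id) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             protein_id = protein_id, gene = gene, beta = beta,
             p_value = p_value, source = source, stringsAsFactors = FALSE)
}

single_locus_config <- function(seed, n_cases = 500, n_controls = 500,
                                maf = 0.3, log_or = 0, pqtl_beta = 0,
                                with_protein = pqtl_beta != 0, ...) {
  loci <- data.frame(snp_id = "rs001", chrom = "chr1", pos = 5e5,
                     effect_allele = "A", maf = maf,
                     per_allele_log_or = log_or, pqtl_beta = pqtl_beta,
                     target_protein = if (with_protein) "P001" else NA_character_,
                     stringsAsFactors = FALSE)
  proteins <- data.frame(protein_id = "P001", gene = "G001", chrom = "chr1",
                         tss = 5e5, role = "null", stringsAsFactors = FALSE)
  sim_config(n_cases, n_controls, loci = loci, proteins = proteins,
             disease_intercept = 0, age_effect = 0, seed = seed, ...)
}

# Cohort with 3 direction-concordant and 2 discordant planted
# suppressor-pQTL SNPs among null loci; used for end-to-end recovery.
e2e_config <- function(seed) {
  n_prot <- 50L
  j <- seq_len(n_prot)
  role <- c(rep("suppressor", 5L), rep("null", n_prot - 5L))
  shift <- c(rep(-1, 5L), rep(0, n_prot - 5L))
  proteins <- data.frame(protein_id = sprintf("P%03d", j),
                         gene = sprintf("G%03d", j),
                         chrom = paste0("chr", ((j - 1L) %% 10L) + 1L),
                         tss = 1e6 + ((j - 1L) %/% 10L) * 3e6,
                         role = role, plasma_shift = shift,
                         tissue_shift = shift, stringsAsFactors = FALSE)
  k <- seq_len(20L)
  loci <- data.frame(snp_id = sprintf("snp%03d", k),
                     chrom = paste0("chr", ((k - 1L) %% 10L) + 1L),
                     pos = 150e6 + k * 1e5,
                     effect_allele = "A", maf = 0.3,
                     per_allele_log_or = 0, pqtl_beta = 0,
                     target_protein = NA_character_,
                     stringsAsFactors = FALSE)
  targ <- sprintf("P%03d", 1:5)
  pi5 <- match(targ, proteins$protein_id)
  loci$chrom[1:5] <- proteins$chrom[pi5]
  loci$pos[1:5] <- proteins$tss[pi5]
  loci$target_protein[1:5] <- targ
  # concordant: suppressor, beta < 0, OR > 1 (snp001-003)
  # discordant: beta > 0 with OR > 1, and beta < 0 with OR < 1
  loci$pqtl_beta[1:5] <- c(-0.5, -0.5, -0.5, 0.5, -0.5)
  loci$per_allele_log_or[1:5] <- c(rep(log(1.8), 4L), -log(1.8))
  sim_config(500L, 500L, loci = loci, proteins = proteins,
             n_tissue_pairs = 65L, seed = seed)
}

# trapezoidal integration of the empirical ROC curve (independent of the
# rank formula)
trapezoid_auc <- function(scores, status) {
  pts <- roc_points(scores, status)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}
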