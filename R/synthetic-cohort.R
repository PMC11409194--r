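# Synthetic cohort generator: Hardy-Weinberg genotypes with block-wise LD,
# a logistic disease model with an age covariate, and log2-scale proteomics
# in two compartments with planted case/control shifts and per-allele pQTL
# effects. All draws are reproducible from a single integer seed.

.rho_cache <- new.env(parent = emptyenv())

# P(Z1 < qnorm(pa), Z2 < qnorm(pb)) under correlation rho, by conditioning
# on Z1 (mvtnorm-free orthant probability).
.bvn_lower <- function(rho, pa, pb) {
  za <- qnorm(pa)
  zb <- qnorm(pb)
  if (abs(rho) < 1e-12) return(pa * pb)
  integrate(function(z) dnorm(z) * pnorm((zb - rho * z) / sqrt(1 - rho^2)),
            -Inf, za, rel.tol = 1e-10)$value
}

# Correlation of the two thresholded Bernoulli alleles induced by latent
# bivariate-normal correlation rho.
.binary_corr <- function(rho, pa, pb) {
  (.bvn_lower(rho, pa, pb) - pa * pb) /
    sqrt(pa * (1 - pa) * pb * (1 - pb))
}

# Latent correlation giving allele-level correlation target_r (= sqrt of the
# target dosage r^2). Deterministic; cached because it is called per block
# per simulation.
.calibrate_rho <- function(pa, pb, target_r) {
  if (target_r <= 0) return(0)
  key <- sprintf("%.12g|%.12g|%.12g", pa, pb, target_r)
  if (!is.null(.rho_cache[[key]])) return(.rho_cache[[key]])
  f <- function(rho) .binary_corr(rho, pa, pb) - target_r
  upper <- 0.999999
  if (f(upper) < 0)
    stop(sprintf("target r2 %.3f unattainable for allele frequencies %.3f / %.3f",
                 target_r^2, pa, pb))
  rho <- uniroot(f, c(0, upper), tol = 1e-10)$root
  .rho_cache[[key]] <- rho
  rho
}

.validate_loci <- function(loci) {
  if (!is.data.frame(loci) || nrow(loci) == 0L)
    stop("`loci` must be a non-empty data.frame")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "effect_allele", "maf")
  if (!all(need %in% names(loci)))
    stop("loci missing column(s): ", paste(setdiff(need, names(loci)), collapse = ", "))
  if (anyDuplicated(loci$snp_id))
    stop("duplicate snp_id in loci: ",
         paste(unique(loci$snp_id[duplicated(loci$snp_id)]), collapse = ", "))
  if (any(loci$maf <= 0 | loci$maf > 0.5))
    stop("maf must lie in (0, 0.5]; offending snp(s): ",
         paste(loci$snp_id[loci$maf <= 0 | loci$maf > 0.5], collapse = ", "))
  if (is.null(loci$other_allele)) {
    bases <- c("A", "C", "G", "T")
    loci$other_allele <- vapply(loci$effect_allele,
                                function(a) setdiff(bases, a)[1L], "")
  }
  if (is.null(loci$ld_block)) loci$ld_block <- loci$snp_id
  if (is.null(loci$target_r2)) loci$target_r2 <- 0
  if (any(loci$target_r2 < 0 | loci$target_r2 >= 1))
    stop("target_r2 must lie in [0, 1)")
  if (is.null(loci$per_allele_log_or)) loci$per_allele_log_or <- 0
  if (is.null(loci$pqtl_beta)) loci$pqtl_beta <- 0
  if (is.null(loci$target_protein)) loci$target_protein <- NA_character_
  loci
}

.validate_proteins <- function(proteins) {
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (nrow(proteins) == 0L) {
    for (col in c("protein_id", "gene", "chrom", "role"))
      if (is.null(proteins[[col]])) proteins[[col]] <- character(0)
    for (col in c("tss", "plasma_shift", "tissue_shift", "baseline"))
      if (is.null(proteins[[col]])) proteins[[col]] <- numeric(0)
    return(proteins)
  }
  need <- c("protein_id", "gene", "chrom", "tss", "role")
  if (!all(need %in% names(proteins)))
    stop("proteins missing column(s): ",
         paste(setdiff(need, names(proteins)), collapse = ", "))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id")
  if (!all(proteins$role %in% c("suppressor", "oncogenic", "null")))
    stop("role must be suppressor, oncogenic or null")
  if (is.null(proteins$plasma_shift)) proteins$plasma_shift <- 0
  if (is.null(proteins$tissue_shift)) proteins$tissue_shift <- 0
  if (is.null(proteins$baseline)) proteins$baseline <- 12
  ok <- ifelse(proteins$role == "suppressor",
               proteins$plasma_shift < 0 & proteins$tissue_shift < 0,
        ifelse(proteins$role == "oncogenic",
               proteins$plasma_shift > 0 & proteins$tissue_shift > 0,
               proteins$plasma_shift == 0 & proteins$tissue_shift == 0))
  if (!all(ok))
    stop("planted shifts inconsistent with role for: ",
         paste(proteins$protein_id[!ok], collapse = ", "))
  proteins
}

#' Simulation configuration for a synthetic case-control cohort
#'
#' Bundles the cohort sizes, the loci and protein specifications and the
#' disease-model parameters used by [simulate_genotypes()],
#' [simulate_phenotype()] and [simulate_proteomics()].
#'
#' @param n_cases,n_controls Requested numbers of cases and controls
#'   (case-control sampling from the population model).
#' @param n_tissue_pairs Number of tumor/adjacent tissue pairs (a separate
#'   subject set, mirroring a paired tissue proteomics design).
#' @param loci data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `maf` and optionally `other_allele`, `ld_block`
#'   (loci sharing a label form an LD block whose first listed locus is the
#'   anchor), `target_r2` (target dosage r-squared with the anchor),
#'   `per_allele_log_or` (log odds ratio per effect allele in the disease
#'   model), `pqtl_beta` (log2 protein shift per effect allele) and
#'   `target_protein`.
#' @param proteins data.frame with columns `protein_id`, `gene`, `chrom`,
#'   `tss`, `role` (`"suppressor"`, `"oncogenic"`, `"null"`) and optionally
#'   `plasma_shift`, `tissue_shift` (log2 case-control / tumor-adjacent
#'   differences; sign must agree with the role) and `baseline`.
#' @param disease_intercept Log-odds intercept of the disease model.
#' @param age_effect Log-odds increment for the older age group. The default
#'   `log(1.27)` reproduces the odds contrast between a 51.7% vs 45.7%
#'   over-60 fraction in cases vs controls.
#' @param age_prevalence Marginal probability of the older age group.
#' @param noise_sd Residual standard deviation of log2 abundance.
#' @param subject_sd Standard deviation of the shared subject effect linking
#'   the two columns of a tissue pair.
#' @param seed Integer seed; a fixed seed makes every downstream simulation
#'   byte-identical.
#'
#' @return A list of class `sim_config`.
#' @seealso [default_config()] for a ready-made desk-scale configuration.
#' @export
sim_config <- function(n_cases, n_controls, loci, proteins,
                       n_tissue_pairs = 65L,
                       disease_intercept = 0,
                       age_effect = log(1.27),
                       age_prevalence = 0.5,
                       noise_sd = 1,
                       subject_sd = 1,
                       seed = 1L) {
  if (n_cases < 1L || n_controls < 1L) stop("n_cases and n_controls must be >= 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  loci <- .validate_loci(loci)
  proteins <- .validate_proteins(proteins)
  targ <- loci$target_protein[!is.na(loci$target_protein)]
  missing <- setdiff(targ, proteins$protein_id)
  if (length(missing))
    stop("unknown target_protein(s): ", paste(missing, collapse = ", "))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_tissue_pairs = as.integer(n_tissue_pairs),
                 loci = loci, proteins = proteins,
                 disease_intercept = disease_intercept,
                 age_effect = age_effect,
                 age_prevalence = age_prevalence,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Dosage sampler; uses (and advances) the current RNG stream. Within each
# LD block alleles come from thresholded latent Gaussians correlated with
# the block anchor; two independent haplotypes per individual, so every
# locus is in Hardy-Weinberg equilibrium at its allele frequency.
.sample_dosages <- function(loci, n) {
  dos <- matrix(0L, nrow(loci), n)
  blocks <- split(seq_len(nrow(loci)),
                  factor(loci$ld_block, levels = unique(loci$ld_block)))
  n_hap <- 2L * n
  odd <- seq(1L, n_hap, by = 2L)
  for (idx in blocks) {
    mafs <- loci$maf[idx]
    z0 <- rnorm(n_hap)
    h_anchor <- as.integer(z0 < qnorm(mafs[1L]))
    dos[idx[1L], ] <- h_anchor[odd] + h_anchor[odd + 1L]
    for (j in seq_along(idx)[-1L]) {
      rho <- .calibrate_rho(mafs[1L], mafs[j], sqrt(loci$target_r2[idx[j]]))
      zj <- rho * z0 + sqrt(1 - rho^2) * rnorm(n_hap)
      hj <- as.integer(zj < qnorm(mafs[j]))
      dos[idx[j], ] <- hj[odd] + hj[odd + 1L]
    }
  }
  dos
}

#' Simulate genotypes in Hardy-Weinberg equilibrium with block-wise LD
#'
#' Each locus is sampled at its specified effect-allele frequency; loci that
#' share an `ld_block` label are correlated with the block's first (anchor)
#' locus so that the realized dosage r-squared matches `target_r2`
#' (Gaussian-copula haplotype thresholding). Loci in distinct blocks are
#' independent.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals to draw; defaults to
#'   `n_cases + n_controls`.
#' @return A [genotype_data()] with unlabeled phenotypes.
#' @export
simulate_genotypes <- function(config, n = config$n_cases + config$n_controls) {
  stopifnot(inherits(config, "sim_config"))
  loci <- config$loci
  set.seed(config$seed)
  dos <- .sample_dosages(loci, n)
  snp_info <- loci[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele")]
  samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                        status = NA_integer_, age_group = NA_integer_,
                        stringsAsFactors = FALSE)
  genotype_data(dos, snp_info, samples)
}

#' Assign disease status and age under a logistic model, then case-control
#' sample
#'
#' Case probability is `plogis(intercept + sum(log_or * dosage) +
#' age_effect * age_group)`. Individuals are drawn from the population model
#' (extending the supplied pool with further genotype draws as needed) until
#' the requested numbers of cases and controls are reached, bounded at 100
#' times the requested cohort size.
#'
#' @param genotypes Pool of genotypes from [simulate_genotypes()] built from
#'   the same `config`.
#' @param config A [sim_config()].
#' @return A [genotype_data()] with exactly `n_cases` cases followed by
#'   `n_controls` controls; `status` and `age_group` filled. The total
#'   number of population draws used is attached as attribute `n_draws`.
#' @export
simulate_phenotype <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_data"))
  loci <- config$loci
  if (!identical(rownames(genotypes$dosage), loci$snp_id))
    stop("genotype rows do not match the configuration's loci")
  set.seed(config$seed + 1L)
  n_req <- c(config$n_cases, config$n_controls)
  batch <- sum(n_req)
  max_draws <- 100L * batch

  draw_labels <- function(dos) {
    age <- rbinom(ncol(dos), 1L, config$age_prevalence)
    lp <- config$disease_intercept +
      drop(crossprod(dos, loci$per_allele_log_or)) +
      config$age_effect * age
    status <- rbinom(ncol(dos), 1L, plogis(lp))
    list(age = age, status = status)
  }

  dos <- genotypes$dosage
  lab <- draw_labels(dos)
  age <- lab$age; status <- lab$status
  n_drawn <- ncol(dos)
  while ((sum(status == 1L) < n_req[1L] || sum(status == 0L) < n_req[2L]) &&
         n_drawn < max_draws) {
    extra <- .sample_dosages(loci, min(batch, max_draws - n_drawn))
    lab <- draw_labels(extra)
    dos <- cbind(dos, extra)
    age <- c(age, lab$age); status <- c(status, lab$status)
    n_drawn <- n_drawn + ncol(extra)
  }
  if (sum(status == 1L) < n_req[1L] || sum(status == 0L) < n_req[2L])
    stop(sprintf(paste0("could not obtain %d cases and %d controls within ",
                        "%d population draws (got %d cases, %d controls); ",
                        "check disease_intercept"),
                 n_req[1L], n_req[2L], max_draws,
                 sum(status == 1L), sum(status == 0L)))
  keep <- c(which(status == 1L)[seq_len(n_req[1L])],
            which(status == 0L)[seq_len(n_req[2L])])
  samples <- data.frame(sample_id = sprintf("S%05d", seq_along(keep)),
                        status = status[keep], age_group = age[keep],
                        stringsAsFactors = FALSE)
  out <- genotype_data(dos[, keep, drop = FALSE],
                       genotypes$snp_info, samples)
  attr(out, "n_draws") <- n_drawn
  out
}

#' Simulate plasma and tissue proteomics linked to genotype
#'
#' Log2 abundance is `baseline + role shift * I(case or tumor) +
#' pqtl_beta * dosage + Normal(0, noise_sd)`. The plasma matrix covers the
#' cohort samples; the tissue matrix contains `n_tissue_pairs` tumor and
#' adjacent columns from an independent subject set (with freshly drawn
#' genotypes) sharing a per-subject random effect.
#'
#' @param genotypes Phenotype-labeled cohort from [simulate_phenotype()].
#' @param config A [sim_config()].
#' @return list with elements `plasma` and `tissue`, both [protein_matrix()].
#' @export
simulate_proteomics <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_data"))
  status <- genotypes$samples$status
  if (anyNA(status)) stop("run simulate_phenotype() first: status not assigned")
  loci <- config$loci
  prot <- config$proteins
  set.seed(config$seed + 2L)

  add_pqtl <- function(vals, dos) {
    for (i in which(!is.na(loci$target_protein))) {
      p <- match(loci$target_protein[i], prot$protein_id)
      vals[p, ] <- vals[p, ] + loci$pqtl_beta[i] * dos[i, ]
    }
    vals
  }
  n_p <- nrow(prot)

  n_s <- ncol(genotypes$dosage)
  plasma_vals <- matrix(rnorm(n_p * n_s, 0, config$noise_sd), n_p, n_s)
  plasma_vals <- plasma_vals + prot$baseline + outer(prot$plasma_shift, status)
  plasma_vals <- add_pqtl(plasma_vals, genotypes$dosage)
  dimnames(plasma_vals) <- list(prot$protein_id, genotypes$samples$sample_id)
  plasma <- protein_matrix(plasma_vals,
                           ifelse(status == 1L, "case", "control"), "plasma")

  n_pair <- config$n_tissue_pairs
  tdos <- .sample_dosages(loci, n_pair)
  subj <- matrix(rnorm(n_p * n_pair, 0, config$subject_sd), n_p, n_pair)
  pq <- add_pqtl(matrix(0, n_p, n_pair), tdos)
  tumor <- prot$baseline + prot$tissue_shift + subj + pq +
    matrix(rnorm(n_p * n_pair, 0, config$noise_sd), n_p, n_pair)
  adjac <- prot$baseline + subj + pq +
    matrix(rnorm(n_p * n_pair, 0, config$noise_sd), n_p, n_pair)
  tiss_vals <- matrix(0, n_p, 2L * n_pair)
  tiss_vals[, seq(1L, 2L * n_pair, by = 2L)] <- tumor
  tiss_vals[, seq(2L, 2L * n_pair, by = 2L)] <- adjac
  pair <- sprintf("T%03d", seq_len(n_pair))
  dimnames(tiss_vals) <- list(prot$protein_id,
                              paste0(rep(pair, each = 2L),
                                     c("_tumor", "_adjacent")))
  tissue <- protein_matrix(tiss_vals,
                           rep(c("tumor", "adjacent"), n_pair), "tissue",
                           pair_id = rep(pair, each = 2L))
  list(plasma = plasma, tissue = tissue)
}

#' pQTL catalog records implied by the simulation configuration
#'
#' Emits one catalog record per locus with a target protein, carrying the
#' planted `pqtl_beta` as the catalog effect size.
#'
#' @param config A [sim_config()].
#' @param source Catalog label.
#' @param p_value Catalog p-value assigned to each record (the generator
#'   plants effects, it does not re-estimate them).
#' @return data.frame in the standard catalog layout (see [read_catalog()]).
#' @export
simulate_catalog <- function(config, source = "synthetic", p_value = 1e-8) {
  stopifnot(inherits(config, "sim_config"))
  loci <- config$loci
  keep <- which(!is.na(loci$target_protein))
  gene <- config$proteins$gene[match(loci$target_protein[keep],
                                     config$proteins$protein_id)]
  data.frame(snp_id = loci$snp_id[keep],
             chrom = loci$chrom[keep],
             pos = loci$pos[keep],
             effect_allele = loci$effect_allele[keep],
             other_allele = loci$other_allele[keep],
             protein_id = loci$target_protein[keep],
             gene = gene,
             beta = loci$pqtl_beta[keep],
             p_value = rep_len(p_value, length(keep)),
             source = rep_len(source, length(keep)),
             stringsAsFactors = FALSE)
}

#' Gene annotation table (gene, chromosome, TSS) for a configuration
#' @param config A [sim_config()].
#' @return data.frame with columns `gene`, `chrom`, `tss`.
#' @export
gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(gene = config$proteins$gene,
             chrom = config$proteins$chrom,
             tss = config$proteins$tss,
             stringsAsFactors = FALSE)
}

#' Desk-scale default configuration
#'
#' 500 cases / 500 controls, 65 tissue pairs, 50 loci and 200 proteins:
#' six planted pQTL loci whose target proteins carry unit log2 shifts
#' (three tumor-suppressor, three oncogenic roles, all direction-concordant
#' with their disease effects), five two-locus LD blocks at r-squared 0.5,
#' and null loci/proteins for the remainder.
#'
#' @param n_cases,n_controls,n_tissue_pairs Cohort sizes.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
default_config <- function(n_cases = 500L, n_controls = 500L,
                           n_tissue_pairs = 65L, seed = 1L) {
  n_prot <- 200L
  j <- seq_len(n_prot)
  role <- c(rep("suppressor", 3L), rep("oncogenic", 3L), rep("null", n_prot - 6L))
  shift <- c(rep(-1, 3L), rep(1, 3L), rep(0, n_prot - 6L))
  proteins <- data.frame(
    protein_id = sprintf("P%03d", j),
    gene = sprintf("G%03d", j),
    chrom = paste0("chr", ((j - 1L) %% 10L) + 1L),
    tss = 1e6 + ((j - 1L) %/% 10L) * 3e6,
    role = role, plasma_shift = shift, tissue_shift = shift,
    stringsAsFactors = FALSE)

  k <- seq_len(50L)
  bases <- c("A", "C", "G", "T")
  loci <- data.frame(
    snp_id = sprintf("snp%03d", k),
    chrom = paste0("chr", ((k - 1L) %% 10L) + 1L),
    pos = 150e6 + ((k - 1L) %/% 10L) * 1e6,
    effect_allele = bases[((k - 1L) %% 4L) + 1L],
    maf = rep(c(0.3, 0.2, 0.4, 0.1, 0.25), 10L),
    ld_block = sprintf("b%03d", k),
    target_r2 = 0,
    per_allele_log_or = 0,
    pqtl_beta = 0,
    target_protein = NA_character_,
    stringsAsFactors = FALSE)
  # six pQTL loci placed at their target protein's TSS (cis distance 0)
  targ <- sprintf("P%03d", 1:6)
  pi6 <- match(targ, proteins$protein_id)
  loci$chrom[1:6] <- proteins$chrom[pi6]
  loci$pos[1:6] <- proteins$tss[pi6]
  loci$maf[1:6] <- 0.3
  loci$target_protein[1:6] <- targ
  # concordant patterns: suppressor with beta<0 and OR>1; oncogenic with
  # beta>0 and OR>1
  loci$pqtl_beta[1:6] <- c(-0.5, -0.5, -0.5, 0.5, 0.5, 0.5)
  loci$per_allele_log_or[1:6] <- log(1.5)
  # five LD blocks of two loci at target r2 = 0.5
  for (b in 1:5) {
    i <- 6L + 2L * b - 1L
    loci$ld_block[c(i, i + 1L)] <- sprintf("blk%02d", b)
    loci$target_r2[i + 1L] <- 0.5
    loci$chrom[i + 1L] <- loci$chrom[i]
    loci$pos[i + 1L] <- loci$pos[i] + 5e4
    loci$maf[i + 1L] <- loci$maf[i]
  }
  sim_config(n_cases, n_controls, loci = loci, proteins = proteins,
             n_tissue_pairs = n_tissue_pairs, seed = seed)
}
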