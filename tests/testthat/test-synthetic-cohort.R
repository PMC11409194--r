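test_that("dosage matrix has the right shape, range and determinism", {
  loci <- data.frame(snp_id = c("a", "b"), chrom = "chr1", pos = c(1e5, 2e5),
                     effect_allele = "A", maf = 0.5)
  prot <- data.frame(protein_id = character(0))
  cfg <- sim_config(5, 5, loci = loci, proteins = prot, seed = 3)
  gt <- simulate_genotypes(cfg)
  expect_identical(dim(gt$dosage), c(2L, 10L))
  expect_true(all(gt$dosage %in% 0:2))
  expect_identical(gt$dosage, simulate_genotypes(cfg)$dosage)
})

test_that("configuration validation rejects bad loci and proteins", {
  loci <- data.frame(snp_id = "a", chrom = "chr1", pos = 1, effect_allele = "A",
                     maf = 0.6)
  expect_error(sim_config(5, 5, loci = loci, proteins = data.frame()),
               "maf")
  loci2 <- data.frame(snp_id = c("a", "a"), chrom = "chr1", pos = 1:2,
                      effect_allele = "A", maf = 0.2)
  expect_error(sim_config(5, 5, loci = loci2, proteins = data.frame()),
               "duplicate snp_id")
  loci3 <- data.frame(snp_id = "a", chrom = "chr1", pos = 1,
                      effect_allele = "A", maf = 0.2,
                      pqtl_beta = 1, target_protein = "nope")
  expect_error(sim_config(5, 5, loci = loci3, proteins = data.frame()),
               "unknown target_protein")
  prot <- data.frame(protein_id = "P1", gene = "G1", chrom = "chr1", tss = 1,
                     role = "suppressor", plasma_shift = 1, tissue_shift = -1)
  loci4 <- data.frame(snp_id = "a", chrom = "chr1", pos = 1,
                      effect_allele = "A", maf = 0.2)
  expect_error(sim_config(5, 5, loci = loci4, proteins = prot),
               "inconsistent with role")
})

test_that("simulated genotypes hit their allele frequency and HWE", {
  cfg <- single_locus_config(seed = 11, n_cases = 1, n_controls = 1, maf = 0.3)
  gt <- simulate_genotypes(cfg, n = 20000)
  d <- gt$dosage[1, ]
  f <- mean(d) / 2
  expect_lt(abs(f - 0.3), 0.01)
  obs <- tabulate(d + 1L, 3L)
  q <- f
  exp_cnt <- 20000 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((obs - exp_cnt)^2 / exp_cnt)
  expect_gt(pchisq(chi2, df = 1, lower.tail = FALSE), 0.001)
})

test_that("LD blocks realize the target r2 and cross-block independence", {
  loci <- data.frame(snp_id = c("a", "b", "c"),
                     chrom = "chr1", pos = c(1e5, 2e5, 9e6),
                     effect_allele = "A", maf = c(0.3, 0.3, 0.2),
                     ld_block = c("blk", "blk", "solo"),
                     target_r2 = c(0, 0.8, 0))
  cfg <- sim_config(1, 1, loci = loci, proteins = data.frame(), seed = 5)
  gt <- simulate_genotypes(cfg, n = 20000)
  r2_in <- cor(gt$dosage[1, ], gt$dosage[2, ])^2
  expect_lt(abs(r2_in - 0.8), 0.05)
  expect_lt(cor(gt$dosage[1, ], gt$dosage[3, ])^2, 0.02)
  expect_lt(cor(gt$dosage[2, ], gt$dosage[3, ])^2, 0.02)
})

test_that("null disease model yields ~half cases among population draws", {
  # requesting 9500 of each from a pool of 20000 succeeds only if the raw
  # case fraction is within [0.475, 0.525]
  cfg <- single_locus_config(seed = 7, n_cases = 9500, n_controls = 9500)
  gt <- simulate_genotypes(cfg, n = 20000)
  ph <- simulate_phenotype(gt, cfg)
  expect_identical(attr(ph, "n_draws"), 20000L)
  expect_identical(sum(ph$samples$status == 1), 9500L)
  expect_identical(sum(ph$samples$status == 0), 9500L)
})

test_that("planted per-allele odds ratio is recovered by refitting", {
  cfg <- single_locus_config(seed = 13, n_cases = 20000, n_controls = 20000,
                             log_or = log(1.5))
  ph <- simulate_phenotype(simulate_genotypes(cfg), cfg)
  fit <- logistic_fit(cbind(1, additive = ph$dosage[1, ]),
                      ph$samples$status)
  expect_gt(exp(fit$coef[2]), 1.4)
  expect_lt(exp(fit$coef[2]), 1.6)
})

test_that("unreachable case quota fails loudly within the draw bound", {
  cfg <- single_locus_config(seed = 2, n_cases = 50, n_controls = 50)
  cfg$disease_intercept <- -30
  gt <- simulate_genotypes(cfg)
  expect_error(simulate_phenotype(gt, cfg), "could not obtain")
})

test_that("planted pQTL beta is recovered by per-dosage regression", {
  cfg <- single_locus_config(seed = 17, n_cases = 2500, n_controls = 2500,
                             pqtl_beta = -0.5)
  ph <- simulate_phenotype(simulate_genotypes(cfg), cfg)
  pr <- simulate_proteomics(ph, cfg)
  slope <- coef(lm(pr$plasma$values["P001", ] ~ ph$dosage[1, ]))[2]
  expect_lt(abs(slope - (-0.5)), 0.05)
})

test_that("null proteins show no case-control shift beyond sampling error", {
  cfg <- single_locus_config(seed = 19, n_cases = 500, n_controls = 500)
  ph <- simulate_phenotype(simulate_genotypes(cfg), cfg)
  pr <- simulate_proteomics(ph, cfg)
  x <- pr$plasma$values["P001", ]
  st <- ph$samples$status
  d <- mean(x[st == 1]) - mean(x[st == 0])
  se <- sqrt(var(x[st == 1]) / sum(st == 1) + var(x[st == 0]) / sum(st == 0))
  expect_lt(abs(d), 3 * se)
})

test_that("tissue matrix is validly paired and the full simulation is
          deterministic under a fixed seed", {
  cfg <- e2e_config(seed = 23)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$genotypes$dosage, co2$genotypes$dosage)
  expect_identical(co1$plasma$values, co2$plasma$values)
  expect_identical(co1$tissue$values, co2$tissue$values)
  tab <- table(co1$tissue$pair_id, co1$tissue$group)
  expect_true(all(tab == 1L))
  expect_identical(ncol(co1$tissue$values), 130L)
})

test_that("detection of a planted suppressor shift matches closed-form
          power at 50 vs 100 samples", {
  # two-sample pooled t, |shift| = 1, sd = 1, n = 50/100:
  # power = pnorm(delta/se - z_{.975}) ~ 0.9999, so essentially every
  # seed must detect it
  hits <- 0L
  for (s in 1:30) {
    set.seed(100 + s)
    x <- rnorm(50, -1); y <- rnorm(100, 0)
    m <- toy_plasma(rbind(c(x, y)), c(rep(1, 50), rep(0, 100)))
    res <- de_test_unpaired(m)
    hits <- hits + (res$direction == "down")
  }
  expect_gte(hits, 29L)
})
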