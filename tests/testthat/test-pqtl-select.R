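test_that("catalog merging unions, deduplicates by smallest p, and
          restricts to the protein set", {
  c1 <- toy_catalog(c("r1", "r2", "r3"), c("A", "B", "C"), source = "ice")
  c2 <- toy_catalog(c("r4", "r5"), c("A", "B"), source = "fin")
  out <- merge_catalogs(list(c1, c2))
  expect_identical(nrow(out), 5L)
  # same snp/protein in both catalogs: smallest p wins, sources recorded
  c3 <- toy_catalog("r1", "A", p_value = 1e-8, source = "ice", beta = 2)
  c4 <- toy_catalog("r1", "A", p_value = 1e-5, source = "fin", beta = 3)
  dd <- merge_catalogs(list(c3, c4))
  expect_identical(nrow(dd), 1L)
  expect_equal(dd$p_value, 1e-8)
  expect_equal(dd$beta, 2)
  expect_identical(dd$source, "ice;fin")
  # restriction drops records for proteins outside the set
  out2 <- merge_catalogs(list(c1, c2), restrict_to = c("A"))
  expect_setequal(out2$snp_id, c("r1", "r4"))
})

test_that("allele harmonization flips beta for swapped labels and drops
          unresolvable records", {
  c1 <- toy_catalog("r1", "A", beta = 1.5, effect_allele = "A", other_allele = "G")
  c2 <- toy_catalog("r1", "B", beta = 0.7, effect_allele = "G", other_allele = "A")
  expect_warning(out <- merge_catalogs(list(c1, c2)), "swapped")
  expect_equal(out$beta[out$protein_id == "B"], -0.7)
  expect_identical(out$effect_allele[out$protein_id == "B"], "A")
  c5 <- toy_catalog("r1", "C", effect_allele = "T", other_allele = "C")
  expect_message(out2 <- merge_catalogs(list(c1, c5)), "unresolvable")
  expect_false("C" %in% out2$protein_id)
})

test_that("cis filter uses a closed +/- window around the TSS", {
  ann <- data.frame(gene = "A", chrom = "chr1", tss = 5e6)
  rec <- function(pos, chrom = "chr1", gene = "A")
    toy_catalog("r1", "A", pos = pos, chrom = chrom, gene = gene)
  expect_identical(nrow(filter_cis(rec(5e6), ann)), 1L)          # at TSS
  expect_identical(nrow(filter_cis(rec(6e6), ann)), 1L)          # exactly 1 Mb
  expect_identical(nrow(filter_cis(rec(6e6 + 1), ann)), 0L)      # 1 Mb + 1
  expect_identical(nrow(filter_cis(rec(5e6, chrom = "chr2"), ann)), 0L)
  expect_message(out <- filter_cis(rec(5e6, gene = "Z"), ann), "unannotated")
  expect_identical(nrow(out), 0L)
})

test_that("MAF computation and strict-threshold filtering", {
  gt <- toy_gt(rbind(rep(1, 4), c(0, 0, 1, 2), rep(0, 4),
                     rep(NA_integer_, 4)))
  expect_warning(st <- compute_maf(gt), "all genotypes missing")
  expect_equal(st$maf, c(0.5, 0.375, 0, NA))
  recs <- toy_catalog(sprintf("rs%03d", 1:4), "A")
  expect_message(kept <- filter_maf(recs, st, 0.05), "without panel MAF")
  expect_setequal(kept$snp_id, c("rs001", "rs002"))
  # boundary: maf exactly at the threshold is dropped, just above is kept
  st2 <- data.frame(snp_id = c("x", "y"), maf = c(0.05, 0.051))
  r2 <- toy_catalog(c("x", "y"), "A")
  expect_identical(filter_maf(r2, st2, 0.05)$snp_id, "y")
})

test_that("ld_r2 is the squared Pearson correlation of dosages", {
  a <- c(0, 1, 2, 0, 1)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)  # perfect negative correlation
  x <- c(0, 0, 1, 2); y <- c(0, 1, 1, 2)
  # independent hand computation: r = cov / (sd sd)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ld_r2(x, y), r_hand^2)
  expect_equal(ld_r2(x, y), 0.7272727, tolerance = 1e-6)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_error(ld_r2(c(0, 1), c(0, 1)), "length")
})

test_that("greedy LD pruning keeps the smallest p and allows chains", {
  v1 <- c(0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 2)
  v2 <- c(0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 1)
  v3 <- c(0, 0, 2, 0, 0, 0, 0, 2, 0, 0, 0, 1)
  # r2(1,2) = 0.857, r2(2,3) = 0.904, r2(1,3) = 0.582 at threshold 0.8
  panel <- toy_gt(rbind(v1, v2, v3))
  rownames(panel$dosage) <- panel$snp_info$snp_id <- c("s1", "s2", "s3")
  recs <- toy_catalog(c("s1", "s2", "s3"), "A", p_value = c(1e-8, 1e-6, 1e-4))
  pruned <- ld_prune(recs, panel, 0.8)
  expect_setequal(pruned$snp_id, c("s1", "s3"))
  # two linked SNPs: only the smaller pQTL p survives
  recs2 <- toy_catalog(c("s2", "s3"), "A", p_value = c(1e-4, 1e-8))
  expect_identical(ld_prune(recs2, panel, 0.8)$snp_id, "s3")
  # single record trivially kept; missing panel SNP treated as unlinked
  expect_identical(nrow(ld_prune(recs[1, ], panel, 0.8)), 1L)
  recs3 <- toy_catalog(c("s1", "zz"), "A", p_value = c(1e-8, 1e-7))
  expect_message(out <- ld_prune(recs3, panel, 0.8), "unlinked")
  expect_identical(nrow(out), 2L)
})

test_that("pruned output never contains a same-chromosome pair at or above
          the threshold", {
  loci <- data.frame(snp_id = sprintf("s%02d", 1:8), chrom = "chr1",
                     pos = (1:8) * 1e5, effect_allele = "A",
                     maf = 0.3,
                     ld_block = rep(c("b1", "b2", "b3", "b4"), each = 2),
                     target_r2 = rep(c(0, 0.9), 4))
  cfg <- sim_config(1, 1, loci = loci, proteins = data.frame(), seed = 77)
  panel <- simulate_genotypes(cfg, n = 1000)
  recs <- toy_catalog(loci$snp_id, "A", p_value = seq(1e-8, 1e-4, length.out = 8))
  pruned <- ld_prune(recs, panel, 0.8)
  ids <- pruned$snp_id
  for (i in seq_along(ids)) for (j in seq_len(i - 1L))
    expect_lt(ld_r2(panel$dosage[ids[i], ], panel$dosage[ids[j], ]), 0.8)
})

test_that("cis and MAF filters commute and the pipeline is monotone in its
          thresholds", {
  set.seed(5)
  n <- 30
  recs <- toy_catalog(sprintf("r%02d", 1:n), "A",
                      pos = round(runif(n, 4e6, 7e6)))
  ann <- data.frame(gene = "A", chrom = "chr1", tss = 5e6)
  st <- data.frame(snp_id = recs$snp_id, maf = runif(n, 0, 0.5))
  strip <- function(d) { rownames(d) <- NULL; d }
  ab <- filter_maf(filter_cis(recs, ann), st, 0.05)
  ba <- filter_cis(filter_maf(recs, st, 0.05), ann)
  expect_identical(strip(ab[order(ab$snp_id), ]),
                   strip(ba[order(ba$snp_id), ]))
  # tighter thresholds never enlarge the output
  expect_true(all(filter_cis(recs, ann, 5e5)$snp_id %in%
                  filter_cis(recs, ann, 1e6)$snp_id))
  expect_true(all(filter_maf(recs, st, 0.2)$snp_id %in%
                  filter_maf(recs, st, 0.05)$snp_id))
})
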