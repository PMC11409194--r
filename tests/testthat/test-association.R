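test_that("genotype counts tally by genotype and status, and an
          independent recount agrees", {
  gt <- toy_gt(rbind(c(0, 1, 1, 2)), status = c(1, 1, 0, 0))
  cnt <- genotype_counts(gt)
  expect_equal(unlist(cnt[1, c("case_ref", "case_het", "case_hom")]),
               c(case_ref = 1L, case_het = 1L, case_hom = 0L))
  expect_equal(unlist(cnt[1, c("ctrl_ref", "ctrl_het", "ctrl_hom")]),
               c(ctrl_ref = 0L, ctrl_het = 1L, ctrl_hom = 1L))
  # double-entry oracle on a larger random cohort
  set.seed(12)
  d <- matrix(sample(c(0:2, NA), 300, TRUE), nrow = 3)
  st <- rep(c(1, 0), 50)
  gt2 <- toy_gt(d, status = st)
  cnt2 <- genotype_counts(gt2)
  for (i in 1:3) for (g in 0:2) {
    expect_identical(cnt2[i, c("case_ref", "case_het", "case_hom")[g + 1]],
                     sum(d[i, ] == g & st == 1, na.rm = TRUE))
    expect_identical(cnt2[i, c("ctrl_ref", "ctrl_het", "ctrl_hom")[g + 1]],
                     sum(d[i, ] == g & st == 0, na.rm = TRUE))
  }
  expect_equal(rowSums(cnt2[, 2:7]) + cnt2$n_missing, rep(100, 3),
               ignore_attr = TRUE)
  # all-missing SNP excluded with warning
  d3 <- rbind(c(0, 1), c(NA, NA))
  expect_warning(c3 <- genotype_counts(toy_gt(d3, status = c(1, 0))),
                 "all genotypes missing")
  expect_identical(nrow(c3), 1L)
})

test_that("crude odds ratios, Wald CI and p match direct arithmetic", {
  tab <- data.frame(snp_id = "s", case_ref = 30, case_het = 10, case_hom = 5,
                    ctrl_ref = 40, ctrl_het = 20, ctrl_hom = 2)
  r <- crude_or(tab, "het_vs_ref")
  or <- (10 * 40) / (20 * 30)
  se <- sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 40)
  expect_equal(r$or, or)
  expect_equal(r$ci_low, exp(log(or) - 1.96 * se))
  expect_equal(r$ci_high, exp(log(or) + 1.96 * se))
  expect_equal(r$p_value, 2 * pnorm(-abs(log(or) / se)))
  rdom <- crude_or(tab, "dominant")
  expect_equal(rdom$or, (15 * 40) / (22 * 30))
  rrec <- crude_or(tab, "recessive")
  expect_equal(rrec$or, (5 * 60) / (2 * 40))
  # symmetric table: OR = 1, p = 1
  sym <- data.frame(snp_id = "s", case_ref = 50, case_het = 20, case_hom = 0,
                    ctrl_ref = 50, ctrl_het = 20, ctrl_hom = 0)
  rs <- crude_or(sym, "het_vs_ref")
  expect_equal(rs$or, 1)
  expect_equal(rs$p_value, 1)
  # zero cell triggers the Haldane-Anscombe correction
  rh <- crude_or(sym, "recessive")
  expect_true(rh$haldane)
  expect_equal(rh$or, (0.5 * 70.5) / (0.5 * 70.5))
})

test_that("logistic_fit agrees with glm and with closed forms", {
  # intercept only
  y <- rep(c(1, 0), c(30, 70))
  f <- logistic_fit(matrix(1, 100), y)
  expect_equal(unname(f$coef), log(30 / 70), tolerance = 1e-10)
  # random design: cross-check against stats::glm
  set.seed(21)
  x <- cbind(1, rnorm(300), rbinom(300, 1, 0.4))
  colnames(x) <- c("i", "a", "b")
  yy <- rbinom(300, 1, plogis(0.3 + 0.8 * x[, 2] - 0.5 * x[, 3]))
  mine <- logistic_fit(x, yy)
  ref <- glm(yy ~ x[, 2] + x[, 3], family = binomial)
  expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(mine$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
  expect_equal(unname(mine$p_value),
               unname(summary(ref)$coefficients[, "Pr(>|z|)"]),
               tolerance = 1e-6)
})

test_that("logistic_fit raises separation and rank-deficiency errors", {
  y <- rep(c(1, 0), each = 20)
  x_sep <- cbind(1, y)  # exposure identical to outcome
  expect_error(logistic_fit(x_sep, y), class = "pqtl_separation_error")
  x_rank <- cbind(1, 1:40, 2 * (1:40))
  expect_error(logistic_fit(x_rank, y), "rank-deficient")
})

test_that("binary-exposure logistic coefficient equals the log crude OR
          (saturated-model identity)", {
  set.seed(31)
  for (rep in 1:10) {
    cells <- rbinom(4, 400, 0.5) + 5  # a, b, c, d all positive
    g <- rep(c(1, 1, 0, 0), cells)
    y <- rep(c(1, 0, 1, 0), cells)
    f <- logistic_fit(cbind(1, exposure = g), y, tol = 1e-12)
    ln_or <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
    expect_lt(abs(unname(f$coef[2]) - ln_or), 1e-10 * max(1, abs(ln_or)))
  }
})

test_that("association_scan encodings reproduce crude ORs on a cohort
          expanded from counts", {
  cnt <- flcca_counts()[2, ]  # one SNP is enough for the identity
  g <- rep(rep(0:2, 2), c(cnt$case_ref, cnt$case_het, cnt$case_hom,
                          cnt$ctrl_ref, cnt$ctrl_het, cnt$ctrl_hom))
  st <- rep(c(1, 0), c(cnt$case_ref + cnt$case_het + cnt$case_hom,
                       cnt$ctrl_ref + cnt$ctrl_het + cnt$ctrl_hom))
  gt <- toy_gt(matrix(g, nrow = 1), status = st)
  scan <- association_scan(gt, alpha = 0.05)
  crude <- rbind(crude_or(cnt, "het_vs_ref"), crude_or(cnt, "hom_vs_ref"),
                 crude_or(cnt, "dominant"), crude_or(cnt, "recessive"))
  for (m in crude$model)
    expect_equal(scan$or[scan$model == m], crude$or[crude$model == m],
                 tolerance = 1e-8)
  expect_identical(unique(scan$adjusted), FALSE)
  expect_identical(unique(scan$or_direction), "risk")
})

test_that("scan survives separation on one SNP and flags by the additive
          model", {
  set.seed(41)
  st <- rep(c(1, 0), each = 100)
  ok <- rbinom(200, 2, 0.3)
  sep <- ifelse(st == 1, 2L, 0L)  # monotone dose: perfectly separating
  d <- rbind(ok, sep)
  rownames(d) <- NULL  # let the helper assign rs001/rs002
  gt <- toy_gt(d, status = st)
  expect_message(scan <- association_scan(gt), "fit failure")
  expect_true(all(is.na(scan$or[scan$snp_id == "rs002"])))
  expect_match(unique(scan$note[scan$snp_id == "rs002"]), "separation")
  expect_false(anyNA(scan$or[scan$snp_id == "rs001"]))
})

test_that("crude 95% CI covers OR = 1 at the nominal rate under the null", {
  set.seed(51)
  n_rep <- 1000
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- rbinom(1, 500, 0.3); c_ <- 500 - a
    b <- rbinom(1, 500, 0.3); d <- 500 - b
    tab <- data.frame(snp_id = "s", case_ref = c_, case_het = a, case_hom = 0,
                      ctrl_ref = d, ctrl_het = b, ctrl_hom = 0)
    res <- crude_or(tab, "het_vs_ref")
    cover[r] <- res$ci_low <= 1 && 1 <= res$ci_high
  }
  expect_gt(mean(cover), 0.93)
  expect_lt(mean(cover), 0.97)
})

test_that("additive OR lies between the codominant ORs under log-additive
          penetrance", {
  cfg <- single_locus_config(seed = 61, n_cases = 5000, n_controls = 5000,
                             log_or = log(1.5))
  ph <- simulate_phenotype(simulate_genotypes(cfg), cfg)
  scan <- association_scan(ph, models = c("het_vs_ref", "hom_vs_ref",
                                          "additive"))
  ors <- setNames(scan$or, scan$model)
  expect_gt(ors["additive"], min(ors["het_vs_ref"], ors["hom_vs_ref"]))
  expect_lt(ors["additive"], max(ors["het_vs_ref"], ors["hom_vs_ref"]))
})

test_that("age-adjusted scan recovers a planted age effect and OR", {
  cfg <- single_locus_config(seed = 71, n_cases = 3000, n_controls = 3000,
                             log_or = log(1.5))
  cfg$age_effect <- log(1.3)
  ph <- simulate_phenotype(simulate_genotypes(cfg), cfg)
  scan <- association_scan(ph, models = "additive", adjust = "age_group")
  expect_true(scan$adjusted)
  expect_identical(scan$covariates, "age_group")
  # recovery within 3 SE on the log scale
  se <- (log(scan$ci_high) - log(scan$or)) / 1.96
  expect_lt(abs(log(scan$or) - log(1.5)), 3 * se)
})
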