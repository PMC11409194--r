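---
title: "Methods: multi-stage pQTL-SNP screening for case-control risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stage pQTL-SNP screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlscreen)
```

# The screening model

The package links three layers of evidence about a protein-coding gene:
a variant's effect on protein abundance (the pQTL effect β, per effect
allele), the protein's behavior in disease (differential expression in
two independent compartments), and the variant's association with disease
status (an odds ratio from a case-control cohort). A variant survives the
screen only when all three are mutually consistent.

## Differential expression and protein roles

Plasma abundances are compared case vs control with Student's
pooled-variance two-sample *t* test; tissue abundances tumor vs adjacent
with a paired *t* on within-subject differences. Both operate on log2
abundances; `normalize_matrix()` offers log2 transformation with
per-sample median centering for raw inputs. A protein is retained when it
is significant (*p* < α, default 0.05) in **both** compartments **with
the same sign**, and its role is read off the shared direction: down in
both = tumor suppressor, up in both = oncogenic. Design choices worth
stating explicitly:

* *Student's rather than Welch's t* — the screening convention of the
  studies this design follows; with dozens of samples per group the
  difference is minor.
* *No multiple-testing correction* at the screening stage: the screen is
  a filter feeding later, independent evidence, not a discovery claim.
  The association stage reports a Bonferroni column for transparency.
* *Direction agreement is required at intersection time.* Joint
  significance alone would admit proteins that move oppositely in plasma
  and tissue, for which no coherent role label exists.
* Zero-variance proteins with equal group means get *p* = 1 (flat) with a
  warning rather than an error, so degenerate null fixtures run cleanly;
  zero variance with unequal means yields an infinite *t* and *p* = 0.

## Candidate variant selection

Catalog records are merged across sources with allele harmonization
(records whose effect/other alleles are swapped relative to the first
catalog have β negated; irreconcilable allele pairs are dropped and
logged). Duplicated (SNP, protein) pairs keep the smallest catalog *p*,
recording all sources. Filters, in order:

* **cis**: same chromosome and within ±1 Mb of the target gene's TSS
  (closed interval). 1 Mb is the convention of the large plasma pQTL
  catalogs; the boundary is inclusive so a SNP exactly at the window edge
  is kept.
* **MAF**: reference-panel minor allele frequency strictly greater than
  0.05, with MAF = min(f, 1−f) and f the effect-allele dosage mean over
  2·(non-missing samples).
* **LD pruning**: greedy, visiting records by ascending pQTL *p* (ties:
  chromosome, position, snp_id); a SNP is accepted iff its squared Pearson
  dosage correlation (composite LD — phase-free and deterministic) with
  every accepted same-chromosome SNP is below 0.80. Keeping the smallest
  *p* first retains the strongest pQTL evidence in each LD clump; the
  greedy rule guarantees the output's pairwise r² bound but, like all
  greedy pruning, is order-dependent for chains (a–b linked, b–c linked,
  a–c free keeps a and c).

## Association models

Per SNP, genotype-by-status counts feed two routes:

* **Crude odds ratios** from 2×2 cross-products, `OR = ad/bc`, Wald
  95% CI `exp(log OR ± 1.96·SE)` with `SE = √(1/a+1/b+1/c+1/d)`, and a
  two-sided Wald *p*. A zero cell triggers the Haldane–Anscombe +0.5
  correction on all four cells, flagged in the output — rare homozygotes
  at low MAF make this a live case.
* **Logistic regression** (`logistic_fit()`), fitted by Newton scoring /
  IRLS to a score-norm tolerance of 1e−8 (cap 100 iterations), with
  standard errors from the inverse observed information. Genotype
  encodings: two dummies (het, hom vs reference) for the codominant
  contrasts, indicator of ≥1 effect allele (dominant), indicator of 2
  (recessive), and the 0/1/2 dosage (additive). Covariates (the binary
  age group) are appended to the design.

Numerical details of the fitter: predictors are mean-centered internally
when an intercept column is present — this leaves slopes unchanged while
making the divergence check scale-free, since an uncentered covariate
(log2 abundances sit around 12) can legitimately push the intercept past
any fixed bound without separation. Perfect separation is declared when a
centered coefficient exceeds 15 in absolute value (odds ratios beyond
e¹⁵ have no finite MLE in practice) and raised as a typed condition that
the scan catches per SNP, logging the failure and continuing. A vanishing
Newton step is accepted as convergence alongside the score criterion,
because near the optimum the step bounds the remaining error while the raw
score stalls at floating-point noise. Rank-deficient designs (e.g. a
codominant encoding with no heterozygotes) are a validation error.

Significance is bound to the **additive** model (*p* < α): all candidate
variants in the motivating use case are flagged by that model, and it is
the usual single-df screen. The OR *direction* used downstream is the sign
of the additive log OR.

## The concordance rule

With role sign s (−1 suppressor, +1 oncogenic), pQTL sign sign(β), and
disease direction sign(log OR), a significant SNP is biologically
plausible iff

    sign(log OR) = s · sign(β)

split into `plausible_risk` (OR > 1) and `plausible_protective`
(OR < 1); the other four of the eight sign combinations are `discordant`.
SNPs lacking a catalog record, a role, or a defined sign (β = 0, OR = 1,
or sources disagreeing on the sign of β) are reported `unevaluable`
rather than silently dropped. The rule is a pure function of three signs;
`verdict_report()` renders the full eight-row truth table.

## Biomarker evaluation

AUC uses the Mann–Whitney rank formula with midranks,
`AUC = (R₁ − n₁(n₁+1)/2)/(n₁n₂)`, which equals trapezoidal integration of
the empirical ROC curve exactly (asserted to 1e−12 in the tests).
Orientation `auto` flips scores so AUC ≥ 0.5 and records the choice. The
CI is a stratified percentile bootstrap (default 2000 replicates,
resampling cases and controls separately, seedable) — chosen over DeLong
for implementation transparency and exact reproducibility under a seed.
Multi-marker combination fits an in-sample logistic model and scores the
linear predictor; under separation it falls back to an equal-weight
standardized sum, flagged. In-sample combination cannot rank below the
best single marker beyond estimation noise; no cross-validation is
attempted (out of scope).

# The synthetic cohort

The generator exists to give every stage inputs with the statistical
structure the methods assume, at desk scale; it is a stand-in, not a
model of any particular instrument.

* **Genotypes**: per locus, two independent haplotypes per individual,
  each allele a thresholded latent Gaussian — so Hardy–Weinberg holds by
  construction at the specified effect-allele frequency. Within an LD
  block every dependent locus shares the anchor's latent variable with a
  correlation calibrated (by `uniroot` on the analytic thresholded-
  bivariate-normal correlation, computed by one-dimensional integration)
  so the realized dosage r² matches `target_r2`. Blocks are mutually
  independent.
* **Phenotype**: P(case) = logistic(intercept + Σ log-OR·dosage +
  age-effect·age), with a binary age group (≤60 / >60, matching the
  granularity at which such cohorts report age) at 50% prevalence and an
  age log-OR of log 1.27 — the odds contrast implied by ~52% vs ~46%
  over-60 fractions in cases vs controls of the motivating cohort.
  Case-control sampling is by rejection from the population model,
  bounded at 100× the requested cohort; odds ratios are invariant to this
  outcome-dependent sampling, which is why the simple scheme suffices.
* **Proteomics**: log2 abundance = baseline + role shift·1[case/tumor] +
  β·dosage + N(0, noise_sd); tissue pairs share a subject-level random
  effect and freshly drawn genotypes (an independent subject set, as in a
  separate tissue study). Planted shifts are ±1 log2 unit at noise 1 —
  comfortably detectable at the default sample sizes, by design.
* **Determinism**: each generator stage seeds the RNG from the single
  configuration seed plus a fixed offset; identical configurations give
  byte-identical files.

What the generator does **not** emulate: LC–MS/MS missingness and batch
structure, population stratification, genotyping error, X-chromosome
dosage, haplotype-level (EM) LD. Passing tests on synthetic data
therefore demonstrate correctness of the statistics and plumbing, not
robustness to those real-data pathologies.

## Default scale and test problem sizes

The default configuration is 500 cases / 500 controls, 65 tissue pairs,
50 loci (six planted pQTL loci, five two-locus LD blocks at r² 0.5) and
200 proteins — large enough that planted unit effects are detected with
near-certain power, small enough for interactive use. Calibration checks
use larger, targeted sizes: allele-frequency/HWE and LD calibration at
n = 20,000; per-allele OR recovery at n = 20,000; pQTL-β recovery at
n = 5,000; type-I error of the additive flag over 1,000 replicate null
cohorts of 500/500; end-to-end recovery of three planted concordant
(and two planted discordant) SNPs over 20 seeds.

# The bundled worked example

The seven-SNP fixture ships the published FLCCA genotype counts, catalog
β signs and suppressor role labels. Two choices deserve a note. First,
the published odds ratios are age-adjusted but individual ages are not
released; the crude cross-product ORs reproduce most published contrasts
at two decimals, and the additive OR **direction** (what the concordance
rule consumes) agrees for all seven SNPs, so directions are refit at run
time from the counts. Second, the unadjusted additive *p*-values of two
SNPs sit marginally above 0.05 where the published age-adjusted values
sit at 0.049; the fixture therefore carries the published adjusted
*p*-values as the significance gate, treating the printed table as the
input it is. Catalog *p*-values below the double floating-point range
(e.g. 10⁻⁵²²) are clamped to 1e−300; only the sign of β enters the rule.

```{r fixture}
fc <- flcca_candidates()
fc$verdicts[, c("snp_id", "protein_id", "beta_sign", "or_direction", "verdict")]
```

# Known limitations

* The cis window, like the MAF and r² thresholds, is a convention, not an
  inference; sensitivity to it is the user's to explore (`filter_cis()`
  takes any window).
* Crude and age-adjusted ORs differ in the second decimal for some
  contrasts; without individual covariates the package cannot reproduce
  adjusted values exactly.
* Greedy LD pruning is not an optimal independent-set solver; it
  guarantees the pairwise bound, not maximal retention.
* The concordance rule uses signs only; effect magnitudes and mediation
  strength are out of scope (no Mendelian randomization).
* In-sample AUCs for combined markers are optimistic; they are reported
  as such and not cross-validated.
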