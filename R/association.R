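# Case-control association under codominant, dominant, recessive and
# additive genetic models. Crude odds ratios come from contingency-table
# cross-products with Wald confidence intervals; adjusted odds ratios from
# a logistic regression fitted here by iteratively reweighted least
# squares (Newton scoring).

#' Genotype-by-status contingency counts per SNP
#'
#' @param genotypes A [genotype_data()] with `status` assigned for every
#'   sample.
#' @return data.frame with one row per SNP: `snp_id`, `case_ref`,
#'   `case_het`, `case_hom`, `ctrl_ref`, `ctrl_het`, `ctrl_hom`,
#'   `n_missing`. Reference is the zero-dosage genotype (homozygous for the
#'   non-effect allele). SNPs with all genotypes missing are excluded with
#'   a warning.
#' @export
genotype_counts <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_data"))
  status <- genotypes$samples$status
  if (anyNA(status)) stop("status must be defined for all samples")
  cnt <- function(dos, st) {
    vapply(0:2, function(g) sum(dos == g & status == st, na.rm = TRUE), 0L)
  }
  rows <- lapply(seq_len(nrow(genotypes$dosage)), function(i) {
    d <- genotypes$dosage[i, ]
    c(cnt(d, 1L), cnt(d, 0L), sum(is.na(d)))
  })
  m <- do.call(rbind, rows)
  out <- data.frame(snp_id = genotypes$snp_info$snp_id,
                    case_ref = m[, 1L], case_het = m[, 2L], case_hom = m[, 3L],
                    ctrl_ref = m[, 4L], ctrl_het = m[, 5L], ctrl_hom = m[, 6L],
                    n_missing = m[, 7L], stringsAsFactors = FALSE)
  all_missing <- out$n_missing == ncol(genotypes$dosage)
  if (any(all_missing)) {
    warning("excluding SNP(s) with all genotypes missing: ",
            paste(out$snp_id[all_missing], collapse = ", "))
    out <- out[!all_missing, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

.assoc_models <- c("het_vs_ref", "hom_vs_ref", "dominant", "recessive",
                   "additive")

# Four contrast cells (exposed-case a, exposed-control b, unexposed-case c,
# unexposed-control d) for a single counts row and model.
.contrast_cells <- function(row, model) {
  switch(model,
    het_vs_ref = c(a = row$case_het, b = row$ctrl_het,
                   c = row$case_ref, d = row$ctrl_ref),
    hom_vs_ref = c(a = row$case_hom, b = row$ctrl_hom,
                   c = row$case_ref, d = row$ctrl_ref),
    dominant = c(a = row$case_het + row$case_hom,
                 b = row$ctrl_het + row$ctrl_hom,
                 c = row$case_ref, d = row$ctrl_ref),
    recessive = c(a = row$case_hom, b = row$ctrl_hom,
                  c = row$case_ref + row$case_het,
                  d = row$ctrl_ref + row$ctrl_het),
    stop("crude odds ratios are defined for 2x2 contrasts, not '", model, "'"))
}

#' Crude cross-product odds ratio with Wald confidence interval
#'
#' `OR = (a*d)/(b*c)` with `CI = exp(log(OR) +/- 1.96 * SE)`,
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and a two-sided Wald p from
#' `z = log(OR)/SE`. If any contrast cell is zero the Haldane-Anscombe
#' correction (+0.5 to all four cells) is applied and the result flagged.
#'
#' @param table Counts data.frame from [genotype_counts()] (one or more
#'   rows).
#' @param model One of `"het_vs_ref"`, `"hom_vs_ref"`, `"dominant"`,
#'   `"recessive"`.
#' @return data.frame with columns `snp_id`, `model`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `haldane`.
#' @export
crude_or <- function(table, model = c("het_vs_ref", "hom_vs_ref",
                                      "dominant", "recessive")) {
  model <- match.arg(model)
  res <- lapply(seq_len(nrow(table)), function(i) {
    cells <- .contrast_cells(table[i, ], model)
    haldane <- any(cells == 0)
    if (haldane) cells <- cells + 0.5
    or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
    se <- sqrt(sum(1 / cells))
    z <- log(or) / se
    data.frame(snp_id = table$snp_id[i], model = model,
               or = unname(or),
               ci_low = unname(exp(log(or) - 1.96 * se)),
               ci_high = unname(exp(log(or) + 1.96 * se)),
               p_value = unname(2 * pnorm(-abs(z))),
               haldane = haldane, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `P(y = 1) = plogis(X beta)` by Newton scoring,
#' iterated until the maximum absolute score (gradient) component falls
#' below `tol` or `max_iter` iterations. Standard errors come from the
#' inverse observed information; p-values are two-sided Wald.
#'
#' @param design Numeric design matrix including the intercept column.
#' @param outcome 0/1 response vector.
#' @param max_iter,tol Iteration cap and gradient-norm tolerance.
#' @return list with `coef`, `se`, `z`, `p_value`, `vcov`, `converged`,
#'   `iterations`.
#' @section Errors: a diverging coefficient (absolute value above 15 on the
#'   log-odds scale) raises a condition of class `pqtl_separation_error`;
#'   a rank-deficient design is a validation error.
#' @export
logistic_fit <- function(design, outcome, max_iter = 100L, tol = 1e-8) {
  x <- as.matrix(design)
  y <- as.numeric(outcome)
  if (length(y) != nrow(x)) stop("outcome length must match design rows")
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  if (qr(x)$rank < ncol(x)) stop("rank-deficient design matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  # fit on mean-centered predictors so the divergence check is scale-free
  # (an uncentered covariate can push the intercept past any fixed bound
  # without any separation); coefficients are unchanged by centering, the
  # intercept is mapped back afterwards
  is_const <- apply(x, 2L, function(col) all(col == col[1L]))
  ctr <- colMeans(x)
  ctr[is_const] <- 0
  if (!any(is_const)) ctr[] <- 0  # no intercept to absorb a shift: fit raw
  xc <- sweep(x, 2L, ctr, "-")
  beta <- numeric(ncol(x))
  converged <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(xc %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(xc, y - mu))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(xc * w, xc)
    step <- solve(info, grad)
    beta <- beta + step
    iter <- iter + 1L
    # near the optimum the Newton step bounds the remaining error, so a
    # vanishing step is also convergence (the raw gradient can stall at
    # floating-point noise for very tight tolerances)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (any(abs(beta) > 15)) {
      cond <- simpleError(paste0(
        "perfect separation detected (|coefficient| > 15 for ",
        paste(colnames(x)[abs(beta) > 15], collapse = ", "), ")"))
      class(cond) <- c("pqtl_separation_error", class(cond))
      stop(cond)
    }
  }
  if (!converged)
    warning("IRLS did not reach gradient tolerance in ", max_iter, " iterations")
  # undo the centering: slopes are unchanged, constant columns absorb the
  # shift (beta_const -= sum(beta_j * mean_j) / const_value)
  if (any(is_const) && any(!is_const)) {
    j <- which(is_const)[1L]
    beta[j] <- beta[j] - sum(beta[!is_const] * ctr[!is_const]) / x[1L, j]
  }
  mu <- plogis(drop(x %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  vc <- solve(crossprod(x * w, x))
  se <- sqrt(diag(vc))
  z <- beta / se
  list(coef = setNames(beta, colnames(x)), se = setNames(se, colnames(x)),
       z = z, p_value = 2 * pnorm(-abs(z)), vcov = vc,
       converged = converged, iterations = iter)
}

# Model-specific genotype encoding columns for the design matrix.
.encode_genotype <- function(dos, model) {
  switch(model,
    codominant = cbind(het = as.numeric(dos == 1L), hom = as.numeric(dos == 2L)),
    dominant = cbind(dominant = as.numeric(dos >= 1L)),
    recessive = cbind(recessive = as.numeric(dos == 2L)),
    additive = cbind(additive = as.numeric(dos)))
}

#' Association scan across SNPs and genetic models
#'
#' Fits, per SNP, logistic regressions of case status on the genotype under
#' the requested models (codominant via two dummy variables yielding the
#' `het_vs_ref` and `hom_vs_ref` rows; `dominant` = any effect allele;
#' `recessive` = two effect alleles; `additive` = dosage 0/1/2), optionally
#' adjusted for covariates from the sample table. Samples with a missing
#' genotype or covariate are dropped for that SNP. The per-SNP significance
#' flag is bound to the additive-model p-value; a Bonferroni-adjusted
#' additive p is reported for transparency but not used for selection.
#' Separation or other fit failures are recorded in the `note` column
#' without aborting the scan.
#'
#' @param genotypes A [genotype_data()] with `status` set.
#' @param models Subset of `c("het_vs_ref", "hom_vs_ref", "dominant",
#'   "recessive", "additive")`.
#' @param adjust Character vector of covariate column names in
#'   `genotypes$samples` (e.g. `"age_group"`), or empty for crude fits.
#' @param alpha Significance level for the additive-model flag.
#' @return data.frame with columns `snp_id`, `model`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `adjusted`, `covariates`, `significant`,
#'   `or_direction` (sign of the additive log OR), `p_bonferroni`, `note`.
#' @export
association_scan <- function(genotypes, models = .assoc_models,
                             adjust = character(0), alpha = 0.05) {
  stopifnot(inherits(genotypes, "genotype_data"))
  models <- match.arg(models, .assoc_models, several.ok = TRUE)
  samples <- genotypes$samples
  if (anyNA(samples$status)) stop("status must be defined for all samples")
  miss_cov <- setdiff(adjust, names(samples))
  if (length(miss_cov))
    stop("covariate(s) not present: ", paste(miss_cov, collapse = ", "))
  fits <- c(if (any(models %in% c("het_vs_ref", "hom_vs_ref"))) "codominant",
            intersect(models, c("dominant", "recessive", "additive")))

  scan_one <- function(i) {
    dos <- genotypes$dosage[i, ]
    rows <- list()
    note <- NA_character_
    add_p <- NA_real_
    add_dir <- NA_character_
    for (enc in fits) {
      gx <- .encode_genotype(dos, enc)
      keep <- stats::complete.cases(cbind(gx, samples[adjust], samples$status))
      X <- cbind(`(Intercept)` = 1, gx,
                 as.matrix(samples[adjust]))[keep, , drop = FALSE]
      fit <- tryCatch(logistic_fit(X, samples$status[keep]),
                      error = function(e) e)
      emit <- if (enc == "codominant") {
        intersect(models, c("het_vs_ref", "hom_vs_ref"))
      } else enc
      for (m in emit) {
        term <- switch(m, het_vs_ref = "het", hom_vs_ref = "hom", m)
        if (inherits(fit, "error")) {
          note <- conditionMessage(fit)
          rows[[length(rows) + 1L]] <- data.frame(
            snp_id = genotypes$snp_info$snp_id[i], model = m,
            or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
            p_value = NA_real_, stringsAsFactors = FALSE)
        } else {
          b <- fit$coef[term]; s <- fit$se[term]
          rows[[length(rows) + 1L]] <- data.frame(
            snp_id = genotypes$snp_info$snp_id[i], model = m,
            or = exp(unname(b)),
            ci_low = exp(unname(b - 1.96 * s)),
            ci_high = exp(unname(b + 1.96 * s)),
            p_value = unname(fit$p_value[match(term, names(fit$coef))]),
            stringsAsFactors = FALSE)
          if (m == "additive") {
            add_p <- unname(fit$p_value[match(term, names(fit$coef))])
            add_dir <- if (b > 0) "risk" else if (b < 0) "protective" else "flat"
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    out$adjusted <- length(adjust) > 0L
    out$covariates <- paste(adjust, collapse = ";")
    out$significant <- !is.na(add_p) & add_p < alpha
    out$or_direction <- add_dir
    out$additive_p <- add_p
    out$note <- note
    out
  }

  res <- do.call(rbind, lapply(seq_len(nrow(genotypes$dosage)), scan_one))
  if (any(!is.na(res$note)))
    message("fit failure for SNP(s): ",
            paste(unique(res$snp_id[!is.na(res$note)]), collapse = ", "))
  n_snp <- length(unique(res$snp_id))
  res$p_bonferroni <- pmin(res$additive_p * n_snp, 1)
  res$additive_p <- NULL
  rownames(res) <- NULL
  res
}
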