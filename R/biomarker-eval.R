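# Validation-phase biomarker statistics: group comparison of marker
# levels, Mann-Whitney (rank) AUC with a stratified bootstrap CI, and an
# in-sample logistic combination of several markers.

#' Compare marker levels between cases and controls
#'
#' Student's pooled-variance two-sample t test on per-sample marker values.
#'
#' @param levels Numeric vector of marker values.
#' @param status 0/1 vector (1 = case).
#' @return list with `mean_diff` (case - control), `t_stat`, `p_value`.
#' @export
group_compare <- function(levels, status) {
  stopifnot(length(levels) == length(status), all(status %in% c(0, 1)))
  r <- .pooled_t(levels[status == 1], levels[status == 0])
  list(mean_diff = r$fc, t_stat = r$t, p_value = r$p)
}

# Rank (Mann-Whitney) AUC with midrank tie handling:
# AUC = (R1 - n1(n1+1)/2) / (n1 n2), R1 = case rank sum.
.auc_rank <- function(scores, status) {
  n1 <- sum(status == 1)
  n2 <- sum(status == 0)
  r <- rank(scores)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC area under the curve by the Mann-Whitney rank formula
#'
#' AUC is the probability that a random case scores above a random control
#' (ties counted half, via midranks). With `direction = "auto"` the scores
#' are oriented so that AUC >= 0.5 and the chosen orientation is recorded;
#' `"lower_in_cases"` negates the scores first. The confidence interval is
#' a stratified percentile bootstrap (cases and controls resampled
#' separately).
#'
#' @param scores Numeric marker values or classifier scores.
#' @param status 0/1 vector (1 = case); both groups must be non-empty.
#' @param direction `"higher_in_cases"`, `"lower_in_cases"` or `"auto"`.
#' @param marker Label carried into the result.
#' @param n_boot Bootstrap replicates for the CI (0 skips the CI).
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap, making the CI reproducible.
#' @return list of class `roc_result`: `marker`, `auc`, `ci_low`,
#'   `ci_high`, `n_cases`, `n_controls`, `direction`.
#' @export
auc_mann_whitney <- function(scores, status,
                             direction = c("auto", "higher_in_cases",
                                           "lower_in_cases"),
                             marker = "marker", n_boot = 2000L,
                             conf = 0.95, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(status), all(status %in% c(0, 1)))
  if (!any(status == 1) || !any(status == 0))
    stop("both groups must be non-empty")
  if (direction == "auto")
    direction <- if (.auc_rank(scores, status) >= 0.5)
      "higher_in_cases" else "lower_in_cases"
  s <- if (direction == "lower_in_cases") -scores else scores
  auc <- .auc_rank(s, status)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    ic <- which(status == 1)
    in_ <- which(status == 0)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ic, length(ic), replace = TRUE),
               sample(in_, length(in_), replace = TRUE))
      .auc_rank(s[idx], status[idx])
    }, 0)
    ci <- unname(quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(marker = marker, auc = auc,
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_cases = sum(status == 1), n_controls = sum(status == 0),
                 direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC %s: AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls, %s\n",
              x$marker, x$auc, x$ci_low, x$ci_high,
              x$n_cases, x$n_controls, x$direction))
  invisible(x)
}

#' Empirical ROC curve points
#'
#' False/true positive rates at every distinct score threshold (scores
#' oriented so that higher means more case-like), suitable for plotting or
#' trapezoidal integration.
#'
#' @param scores,status As in [auc_mann_whitney()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_points <- function(scores, status) {
  stopifnot(length(scores) == length(status))
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(status == 1)
  n2 <- sum(status == 0)
  tpr <- vapply(th, function(t) sum(scores >= t & status == 1) / n1, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & status == 0) / n2, 0)
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Combine several markers into one ROC score by in-sample logistic
#' regression
#'
#' Fits case status on the marker levels with [logistic_fit()] and
#' evaluates the ROC of the resulting linear predictor. Under perfect
#' separation the fit falls back to an equal-weight sum of standardized
#' markers, flagged in the result.
#'
#' @param level_matrix Markers x samples numeric matrix (no missing
#'   values); rownames are marker ids.
#' @param status 0/1 vector per sample.
#' @param ... Passed to [auc_mann_whitney()] (e.g. `n_boot`, `seed`).
#' @return A `roc_result` with extra elements `weights` and `fallback`.
#' @export
combined_score <- function(level_matrix, status, ...) {
  stopifnot(is.matrix(level_matrix), ncol(level_matrix) == length(status))
  if (anyNA(level_matrix)) stop("missing marker values not supported")
  X <- cbind(`(Intercept)` = 1, t(level_matrix))
  fit <- tryCatch(logistic_fit(X, status), pqtl_separation_error = identity)
  fallback <- inherits(fit, "condition")
  if (fallback) {
    z <- scale(t(level_matrix))
    score <- rowSums(z)
    weights <- setNames(rep(1, nrow(level_matrix)), rownames(level_matrix))
    warning("separation in the combined fit; using equal-weight standardized sum")
  } else {
    score <- drop(X %*% fit$coef)
    weights <- fit$coef[-1L]
  }
  res <- auc_mann_whitney(score, status, direction = "higher_in_cases",
                          marker = "combined", ...)
  res$weights <- weights
  res$fallback <- fallback
  res
}
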