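# Differential protein expression: per-sample normalization, Student's
# pooled-variance t in the unpaired plasma design, paired t in tissue, and
# a direction-consistent intersection that assigns protein roles.

#' Normalize a protein matrix
#'
#' `log2_median_center` takes log2 of the raw abundances and subtracts each
#' sample column's median, so every column has median zero afterwards;
#' `none` returns the matrix unchanged. Protein order is preserved.
#'
#' @param matrix A [protein_matrix()].
#' @param method `"log2_median_center"` or `"none"`.
#' @return A [protein_matrix()] of the same shape.
#' @export
normalize_matrix <- function(matrix, method = c("log2_median_center", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "protein_matrix"))
  if (method == "none") return(matrix)
  v <- matrix$values
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive abundance at protein '%s', sample '%s': log2 undefined",
                 rownames(v)[bad[1L, 1L]], colnames(v)[bad[1L, 2L]]))
  v <- log2(v)
  if (ncol(v) > 0L && nrow(v) > 0L)
    v <- sweep(v, 2L, apply(v, 2L, median), "-")
  matrix$values <- v
  matrix
}

# Direction label implied by the DEResult invariant.
.de_direction <- function(fc, p, alpha) {
  ifelse(p < alpha & fc > 0, "up", ifelse(p < alpha & fc < 0, "down", "flat"))
}

# Student's pooled-variance two-sample t via stats::t.test, with the
# degenerate zero-variance convention: equal means -> t = 0, p = 1;
# unequal means with zero pooled variance -> infinite t, p = 0.
.pooled_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 samples per group")
  fc <- mean(x) - mean(y)
  if (var(x) == 0 && var(y) == 0) {
    if (fc == 0) return(list(fc = 0, t = 0, p = 1, degenerate = TRUE))
    return(list(fc = fc, t = sign(fc) * Inf, p = 0, degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = TRUE)
  list(fc = fc, t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Unpaired differential-expression test (case vs control)
#'
#' Per protein, Student's pooled-variance two-sample t statistic on the
#' case-minus-control difference of log2 abundances, with a two-sided p
#' from the t distribution on `n1 + n2 - 2` degrees of freedom.
#'
#' @param matrix A [protein_matrix()] with groups `case`/`control`.
#' @param alpha Significance level used only to label `direction`.
#' @return data.frame with columns `protein_id`, `log2_fc` (case - control),
#'   `t_stat`, `p_value`, `direction` (`up`/`down`/`flat`).
#' @export
de_test_unpaired <- function(matrix, alpha = 0.05) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (!setequal(unique(matrix$group), c("case", "control")))
    stop("unpaired test requires groups 'case' and 'control'")
  ca <- matrix$values[, matrix$group == "case", drop = FALSE]
  co <- matrix$values[, matrix$group == "control", drop = FALSE]
  res <- lapply(seq_len(nrow(ca)), function(i) .pooled_t(ca[i, ], co[i, ]))
  if (any(vapply(res, `[[`, TRUE, "degenerate")))
    warning("zero pooled variance for ",
            sum(vapply(res, `[[`, TRUE, "degenerate")),
            " protein(s); p set by the degenerate-variance rule")
  fc <- vapply(res, `[[`, 0, "fc")
  p <- vapply(res, `[[`, 0, "p")
  data.frame(protein_id = .protein_ids(matrix$values),
             log2_fc = fc,
             t_stat = vapply(res, `[[`, 0, "t"),
             p_value = p,
             direction = .de_direction(fc, p, alpha),
             stringsAsFactors = FALSE)
}

#' Paired differential-expression test (tumor vs adjacent)
#'
#' Per protein, a paired t test on the tumor-minus-adjacent differences.
#'
#' @param matrix A [protein_matrix()] with groups `tumor`/`adjacent` and
#'   `pair_id` set.
#' @param alpha Significance level used only to label `direction`.
#' @return data.frame as in [de_test_unpaired()] with `log2_fc` = mean
#'   tumor - adjacent difference.
#' @export
de_test_paired <- function(matrix, alpha = 0.05) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (is.null(matrix$pair_id)) stop("paired test requires pair_id")
  if (!setequal(unique(matrix$group), c("tumor", "adjacent")))
    stop("paired test requires groups 'tumor' and 'adjacent'")
  tab <- table(matrix$pair_id, matrix$group)
  bad <- rownames(tab)[apply(tab, 1L, function(r) any(r != 1L))]
  if (length(bad))
    stop("pair(s) missing a mate: ", paste(bad, collapse = ", "))
  pairs <- unique(matrix$pair_id)
  if (length(pairs) < 2L) stop("need >= 2 pairs")
  tum <- matrix$values[, match(paste0(pairs, ".tumor"),
                               paste0(matrix$pair_id, ".", matrix$group)),
                       drop = FALSE]
  adj <- matrix$values[, match(paste0(pairs, ".adjacent"),
                               paste0(matrix$pair_id, ".", matrix$group)),
                       drop = FALSE]
  d <- tum - adj
  res <- lapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ]
    if (var(di) == 0) {
      if (mean(di) == 0) return(list(fc = 0, t = 0, p = 1, degenerate = TRUE))
      return(list(fc = mean(di), t = sign(mean(di)) * Inf, p = 0,
                  degenerate = TRUE))
    }
    ht <- t.test(di)
    list(fc = mean(di), t = unname(ht$statistic), p = ht$p.value,
         degenerate = FALSE)
  })
  if (any(vapply(res, `[[`, TRUE, "degenerate")))
    warning("zero-variance difference for ",
            sum(vapply(res, `[[`, TRUE, "degenerate")), " protein(s)")
  fc <- vapply(res, `[[`, 0, "fc")
  p <- vapply(res, `[[`, 0, "p")
  data.frame(protein_id = .protein_ids(matrix$values),
             log2_fc = fc,
             t_stat = vapply(res, `[[`, 0, "t"),
             p_value = p,
             direction = .de_direction(fc, p, alpha),
             stringsAsFactors = FALSE)
}

#' Intersect plasma and tissue differential proteins requiring consistent
#' direction
#'
#' Keeps proteins significant (`p < alpha`) in both compartments with the
#' same direction of change, and labels the role: `suppressor` when down in
#' both (lower in cases and in tumors), `oncogenic` when up in both. No
#' multiple-testing correction is applied at this screening stage.
#'
#' @param plasma,tissue DE result data.frames from [de_test_unpaired()] /
#'   [de_test_paired()].
#' @param alpha Per-compartment significance threshold.
#' @return data.frame with columns `protein_id`, `role`, `plasma_log2_fc`,
#'   `tissue_log2_fc`, `plasma_p`, `tissue_p`; attribute `counts` holds the
#'   number of up- and down-regulated proteins retained.
#' @export
intersect_consistent <- function(plasma, tissue, alpha = 0.05) {
  shared <- intersect(plasma$protein_id, tissue$protein_id)
  pl <- plasma[match(shared, plasma$protein_id), ]
  ti <- tissue[match(shared, tissue$protein_id), ]
  keep <- pl$p_value < alpha & ti$p_value < alpha &
    pl$direction == ti$direction & pl$direction != "flat"
  out <- data.frame(protein_id = shared[keep],
                    role = ifelse(pl$direction[keep] == "down",
                                  "suppressor", "oncogenic"),
                    plasma_log2_fc = pl$log2_fc[keep],
                    tissue_log2_fc = ti$log2_fc[keep],
                    plasma_p = pl$p_value[keep],
                    tissue_p = ti$p_value[keep],
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(up = sum(out$role == "oncogenic"),
                           down = sum(out$role == "suppressor"))
  out
}
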