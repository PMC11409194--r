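# Regulation-pattern concordance: a pQTL-SNP is biologically plausible
# when the sign of its effect on the target protein, the protein's role
# (tumor suppressor vs oncogenic) and the direction of its disease odds
# ratio are mutually consistent. E.g. an allele that lowers a tumor
# suppressor should raise risk (OR > 1); an allele that raises a tumor
# suppressor should lower it (OR < 1).

#' Classify one regulation pattern
#'
#' The rule is a pure function of three signs: with `s = -1` for a
#' suppressor role and `+1` for an oncogenic role, the pattern is plausible
#' iff `sign(log OR) == s * sign(beta)`; the plausible verdict is
#' `plausible_risk` when OR > 1 and `plausible_protective` when OR < 1,
#' otherwise `discordant`.
#'
#' @param role `"suppressor"` or `"oncogenic"` (vectorized).
#' @param beta_sign pQTL effect sign: `"+"`/`"-"` or a nonzero numeric.
#' @param or_direction `"risk"`/`"protective"`, or an odds ratio (numeric,
#'   not exactly 1).
#' @return Character vector of verdicts.
#' @export
concordance_rule <- function(role, beta_sign, or_direction) {
  if (!all(role %in% c("suppressor", "oncogenic")))
    stop("role must be 'suppressor' or 'oncogenic'")
  bs <- if (is.numeric(beta_sign)) sign(beta_sign) else
    ifelse(beta_sign == "+", 1, ifelse(beta_sign == "-", -1, NA))
  if (anyNA(bs) || any(bs == 0))
    stop("undefined beta sign (beta = 0 or unrecognized label)")
  od <- if (is.numeric(or_direction)) sign(log(or_direction)) else
    ifelse(or_direction == "risk", 1,
           ifelse(or_direction == "protective", -1, NA))
  if (anyNA(od) || any(od == 0))
    stop("undefined OR direction (OR = 1 or unrecognized label)")
  n <- max(length(role), length(bs), length(od))
  role <- rep_len(role, n); bs <- rep_len(bs, n); od <- rep_len(od, n)
  s <- ifelse(role == "suppressor", -1, 1)
  ifelse(od == s * bs,
         ifelse(od > 0, "plausible_risk", "plausible_protective"),
         "discordant")
}

#' Select biologically plausible candidate pQTL-SNPs
#'
#' Evaluates [concordance_rule()] on every SNP whose additive-model
#' association p-value is below `alpha`, joining the pQTL effect sign from
#' the merged catalog and the protein role from the differential-expression
#' labels. SNPs lacking a catalog record, a role, or a defined direction
#' (beta = 0 or OR = 1) are reported as `unevaluable`, never silently
#' dropped.
#'
#' @param assoc Association results from [association_scan()] (must contain
#'   `additive` rows), or any data.frame with columns `snp_id`, `model`,
#'   `or`, `p_value`.
#' @param pqtl Merged catalog from [merge_catalogs()].
#' @param roles data.frame with columns `protein_id`, `role` (e.g. the
#'   output of [intersect_consistent()]).
#' @param alpha Significance threshold on the additive p-value.
#' @return list with `verdicts` (one row per significant SNP x target
#'   protein: `snp_id`, `protein_id`, `role`, `beta_sign`, `or`,
#'   `or_direction`, `p_value`, `verdict`) and `candidates` (the plausible
#'   subset).
#' @export
select_candidates <- function(assoc, pqtl, roles, alpha = 0.05) {
  add <- assoc[assoc$model == "additive", , drop = FALSE]
  if (nrow(add) == 0L) stop("assoc contains no additive-model rows")
  sig <- add[!is.na(add$p_value) & add$p_value < alpha, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    id <- sig$snp_id[i]
    recs <- pqtl[pqtl$snp_id == id, , drop = FALSE]
    if (nrow(recs) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = id, protein_id = NA_character_, role = NA_character_,
        beta_sign = NA_character_, or = sig$or[i],
        or_direction = NA_character_, p_value = sig$p_value[i],
        verdict = "unevaluable", note = "no pQTL record",
        stringsAsFactors = FALSE)
      next
    }
    for (p in unique(recs$protein_id)) {
      betas <- recs$beta[recs$protein_id == p]
      role <- roles$role[match(p, roles$protein_id)]
      bs <- if (length(unique(sign(betas))) > 1L) NA_character_ else
        if (sign(betas[1L]) > 0) "+" else if (sign(betas[1L]) < 0) "-" else
          NA_character_
      od <- if (is.na(sig$or[i]) || sig$or[i] == 1) NA_character_ else
        if (sig$or[i] > 1) "risk" else "protective"
      evaluable <- !is.na(role) && role %in% c("suppressor", "oncogenic") &&
        !is.na(bs) && !is.na(od)
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = id, protein_id = p,
        role = if (is.na(role)) NA_character_ else role,
        beta_sign = bs, or = sig$or[i], or_direction = od,
        p_value = sig$p_value[i],
        verdict = if (evaluable) concordance_rule(role, bs, od) else
          "unevaluable",
        note = if (evaluable) NA_character_ else
          if (is.na(bs)) "conflicting or zero beta sign" else
          if (is.na(role) || !role %in% c("suppressor", "oncogenic"))
            "missing protein role" else "OR direction undefined",
        stringsAsFactors = FALSE)
    }
  }
  verdicts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), protein_id = character(0),
               role = character(0), beta_sign = character(0),
               or = numeric(0), or_direction = character(0),
               p_value = numeric(0), verdict = character(0),
               note = character(0), stringsAsFactors = FALSE)
  list(verdicts = verdicts,
       candidates = verdicts[verdicts$verdict %in%
                               c("plausible_risk", "plausible_protective"),
                             , drop = FALSE])
}

#' Render the concordance truth table and per-SNP assignments
#'
#' @param verdicts The `verdicts` element of [select_candidates()].
#' @param dir Optional directory; when given, writes `verdicts.tsv` and
#'   `verdict_report.json`.
#' @return list with `truth_table` (the 8 role/beta/OR combinations and
#'   their verdicts) and `assignments` (`verdicts` with unevaluable rows
#'   retained).
#' @export
verdict_report <- function(verdicts, dir = NULL) {
  grid <- expand.grid(role = c("suppressor", "oncogenic"),
                      beta_sign = c("+", "-"),
                      or_direction = c("risk", "protective"),
                      stringsAsFactors = FALSE)
  grid$verdict <- concordance_rule(grid$role, grid$beta_sign,
                                   grid$or_direction)
  key <- function(d) paste(d$role, d$beta_sign, d$or_direction)
  grid$n_snps <- vapply(key(grid), function(k) {
    ok <- verdicts$verdict != "unevaluable"
    sum(key(verdicts[ok, , drop = FALSE]) == k)
  }, 0L)
  out <- list(truth_table = grid, assignments = verdicts)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(verdicts, file.path(dir, "verdicts.tsv"))
    jsonlite::write_json(out, file.path(dir, "verdict_report.json"),
                         dataframe = "rows", na = "null", digits = NA,
                         pretty = TRUE)
  }
  out
}
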