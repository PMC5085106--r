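#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness-of-fit test of observed genotype counts against the p^2 / 2pq /
#' q^2 expectation at the sample allele frequency (1 df). Used on control
#' genotypes to flag genotyping artefacts.
#'
#' @param counts genotype counts as `c(n0, n1, n2)`: carriers of 0, 1 and 2
#'   copies of one allele.
#' @return list with `statistic`, `p_value`, `df` (1), and `degenerate`
#'   (`TRUE` for a monomorphic sample, where the statistic is 0 by
#'   convention).
#' @examples
#' hwe_chi_square(c(25, 50, 25)) # exact HWE proportions: statistic 0
#' @export
hwe_chi_square <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0)) {
    stop("counts must be three non-negative genotype counts c(n0, n1, n2)")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped subject is required")
  p_hat <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p_hat == 0 || p_hat == 1) {
    return(list(statistic = 0, p_value = 1, df = 1L, degenerate = TRUE))
  }
  expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, degenerate = FALSE)
}

#' Genotype counts of one SNP in a subject subset
#'
#' @param ds a [cohort()] whose panel has risk alleles set.
#' @param snp rs-id.
#' @param keep optional logical/integer subject index (default: all).
#' @return `c(n0, n1, n2)` counts of risk-allele dose among genotyped
#'   subjects.
#' @export
genotype_counts <- function(ds, snp, keep = NULL) {
  doses <- snp_doses(ds, snp)
  if (!is.null(keep)) doses <- doses[keep]
  doses <- doses[!is.na(doses)]
  c(n0 = sum(doses == 0L), n1 = sum(doses == 1L), n2 = sum(doses == 2L))
}

snp_doses <- function(ds, snp) {
  j <- match(snp, ds$snps$rs_id)
  if (is.na(j)) stop("SNP not in panel: ", snp)
  dose_matrix(ds)[, j]
}

#' 2x2 contingency table
#'
#' @param a exposed cases
#' @param b unexposed cases
#' @param c exposed controls
#' @param d unexposed controls
#' @return a `contingency_table` (named numeric vector).
#' @export
contingency_table <- function(a, b, c, d) {
  tab <- c(a = a, b = b, c = c, d = d)
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers")
  }
  structure(as.numeric(tab), names = c("a", "b", "c", "d"),
            class = "contingency_table")
}

# Pearson chi-square (1 df, no continuity correction) on a 2x2 table,
# via the shortcut n(ad-bc)^2 / (row1 row2 col1 col2). Vectorized.
pearson_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(denom == 0, NA_real_, n * (a * d - b * c)^2 / denom)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Odds ratio with Woolf confidence interval and chi-square p-value
#'
#' Cross-product odds ratio ad/bc, 95% Woolf interval
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)), and the two-sided
#' p-value from the uncorrected Pearson chi-square (1 df) on the table.
#' With `correction = "haldane"`, 0.5 is added to every cell for the point
#' estimate and interval whenever any cell is zero (the p-value always uses
#' the uncorrected counts).
#'
#' @param tab a [contingency_table()].
#' @param correction zero-cell policy, `"none"` (error on a zero cell) or
#'   `"haldane"`.
#' @param conf_level confidence level (default 0.95).
#' @return an [assoc_result()].
#' @examples
#' odds_ratio(contingency_table(69, 12, 57, 29)) # OR 2.93, p 0.0046
#' @export
odds_ratio <- function(tab, correction = c("none", "haldane"),
                       conf_level = 0.95) {
  stopifnot(inherits(tab, "contingency_table"))
  correction <- match.arg(correction)
  a <- tab[["a"]]; b <- tab[["b"]]; c <- tab[["c"]]; d <- tab[["d"]]
  chisq <- pearson_chisq_2x2(a, b, c, d)
  has_zero <- any(c(a, b, c, d) == 0)
  if (has_zero) {
    if (correction == "none") {
      stop("zero cell in 2x2 table; use correction = 'haldane'")
    }
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  assoc_result(
    or = exp(log_or),
    ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se),
    p_value = chisq$p_value,
    statistic = chisq$statistic,
    model = "contingency",
    effective_n = sum(tab),
    note = if (has_zero) "haldane-corrected" else NA_character_
  )
}

#' Association result record
#'
#' One row of a results table: point odds ratio, confidence bounds,
#' p-value, the genetic model and adjustment set that produced it, and the
#' effective (complete-case) sample size. `degenerate = TRUE` marks strata
#' where no estimate is available (zero cell, separation, monomorphic).
#'
#' @param or,ci_low,ci_high odds ratio and confidence bounds.
#' @param p_value two-sided p-value.
#' @param statistic test statistic behind `p_value` (chi-square or Wald z).
#' @param model label: allelic, codominant, dominant, recessive,
#'   combined-genotype, contingency.
#' @param term coefficient label for multi-term models (e.g. codominant
#'   "dose1"/"dose2").
#' @param adjusted_for character vector of covariate names (empty = crude).
#' @param effective_n complete-case sample size used.
#' @param degenerate flag: no estimate available.
#' @param note free-text annotation.
#' @return an object of class `assoc_result`.
#' @export
assoc_result <- function(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                         p_value = NA_real_, statistic = NA_real_,
                         model = NA_character_, term = NA_character_,
                         adjusted_for = character(),
                         effective_n = NA_integer_, degenerate = FALSE,
                         note = NA_character_) {
  if (!degenerate && !anyNA(c(ci_low, or, ci_high))) {
    stopifnot(ci_low <= or + 1e-12, or <= ci_high + 1e-12)
  }
  if (!is.na(p_value)) stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(or = or, ci_low = ci_low, ci_high = ci_high, p_value = p_value,
         statistic = statistic, model = model, term = term,
         adjusted_for = adjusted_for,
         effective_n = as.integer(effective_n),
         degenerate = degenerate, note = note),
    class = "assoc_result"
  )
}

#' @export
print.assoc_result <- function(x, ...) {
  adj <- if (length(x$adjusted_for)) {
    paste0(" | adj: ", paste(x$adjusted_for, collapse = ","))
  } else ""
  if (x$degenerate) {
    cat(sprintf("<assoc_result> %s: degenerate (%s), n=%d\n",
                x$model, x$note, x$effective_n))
  } else {
    cat(sprintf("<assoc_result> %s%s: OR %.2f (95%% CI %.2f-%.2f), p=%.4f, n=%d%s\n",
                x$model, ifelse(is.na(x$term), "", paste0("/", x$term)),
                x$or, x$ci_low, x$ci_high, x$p_value, x$effective_n, adj))
  }
  invisible(x)
}

#' @export
as.data.frame.assoc_result <- function(x, ...) {
  data.frame(
    model = x$model, term = x$term, or = x$or,
    ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, statistic = x$statistic,
    adjusted_for = paste(x$adjusted_for, collapse = ","),
    effective_n = x$effective_n, degenerate = x$degenerate,
    note = x$note, stringsAsFactors = FALSE
  )
}

#' Collapse a list of association results to a data frame
#' @param results list of [assoc_result()] objects (possibly named).
#' @return data frame, one row per result.
#' @export
assoc_table <- function(results) {
  out <- do.call(rbind, lapply(results, as.data.frame))
  if (!is.null(names(results))) out <- cbind(label = names(results), out)
  rownames(out) <- NULL
  out
}

#' Encode risk-allele doses under a genetic model
#'
#' Translates a dose vector (0/1/2 risk-allele copies) into the exposure
#' encoding of a genetic model: `allelic` counts each subject's two alleles
#' separately and returns risk/non-risk allele totals; `dominant` is the
#' carrier indicator (dose >= 1); `recessive` the homozygote indicator
#' (dose == 2); `codominant` a two-column indicator matrix (dose == 1,
#' dose == 2) against the dose-0 reference.
#'
#' @param dose integer vector with values in \{0, 1, 2\}; missing doses must
#'   be removed by the caller.
#' @param model one of `"allelic"`, `"codominant"`, `"dominant"`,
#'   `"recessive"`.
#' @return for `allelic`, `c(risk = , nonrisk = )` allele counts; for
#'   `dominant`/`recessive`, a 0/1 vector; for `codominant`, a 2-column 0/1
#'   matrix with columns `dose1`, `dose2`.
#' @export
encode_model <- function(dose,
                         model = c("allelic", "codominant",
                                   "dominant", "recessive")) {
  model <- match.arg(model)
  if (anyNA(dose)) stop("missing doses must be removed before encoding")
  if (!all(dose %in% 0:2)) stop("doses must be 0, 1 or 2")
  switch(model,
    allelic = c(risk = sum(dose), nonrisk = sum(2L - dose)),
    dominant = as.integer(dose >= 1L),
    recessive = as.integer(dose == 2L),
    codominant = cbind(dose1 = as.integer(dose == 1L),
                       dose2 = as.integer(dose == 2L))
  )
}

#' Allelic (per-allele) contingency test for one SNP
#'
#' Each subject contributes two alleles; the 2x2 table of risk vs non-risk
#' allele counts by group yields the crude per-allele odds ratio.
#'
#' @param dose_g1,dose_g2 dose vectors (NA allowed; dropped) for the two
#'   groups, group 1 in the numerator.
#' @param correction zero-cell policy, see [odds_ratio()].
#' @return an [assoc_result()] with model `"allelic"`; `effective_n` is the
#'   number of genotyped subjects.
#' @export
allelic_test <- function(dose_g1, dose_g2, correction = "haldane") {
  dose_g1 <- dose_g1[!is.na(dose_g1)]
  dose_g2 <- dose_g2[!is.na(dose_g2)]
  e1 <- encode_model(dose_g1, "allelic")
  e2 <- encode_model(dose_g2, "allelic")
  res <- odds_ratio(
    contingency_table(e1[["risk"]], e1[["nonrisk"]],
                      e2[["risk"]], e2[["nonrisk"]]),
    correction = correction)
  res$model <- "allelic"
  res$effective_n <- length(dose_g1) + length(dose_g2)
  res
}
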