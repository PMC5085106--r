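#' Combined-genotype (multi-SNP) risk stratification
#'
#' Cross-classifies subjects by their genotype tuple over a chosen SNP
#' subset and computes, for each observed combination, an unadjusted odds
#' ratio against a reference combination — the engine behind published
#' combined-genotype risk tables. Complete-case: subjects missing any of
#' the chosen genotypes are dropped from that table (so column totals can
#' fall below enrolment; displayed percentages nevertheless use the full
#' group denominators, matching the published convention).
#'
#' Odds ratios are crude cross-product ratios with Woolf 95% intervals and
#' uncorrected Pearson chi-square p-values. Strata with fewer than
#' `min_count` subjects in any compared group are reported with their
#' counts but no estimate (`filtered = TRUE`) rather than silently dropped.
#'
#' @param ds a [cohort()] with risk alleles set.
#' @param snps character vector of 2+ rs-ids (no duplicates).
#' @param comparisons list of [comparison_design()]s; default cases vs
#'   controls.
#' @param reference `"lowest-dose"` (the observed combination with the
#'   smallest total risk-allele dose; ties broken by label order) or
#'   `"explicit"` with `ref_combo`.
#' @param ref_combo explicit reference label, e.g. `"AG-GG"` (genotypes in
#'   panel order, alphabetical allele order, joined by "-").
#' @param min_count minimum per-group stratum count for an estimate
#'   (default 4).
#' @return data frame of class `combo_table`: one row per combination and
#'   comparison, with per-group counts and percentages, total risk-allele
#'   dose, `reference` flag, OR/CI/p (NA for the reference and filtered
#'   strata), and `effective_n`.
#' @examples
#' # two-SNP stratification, cases vs controls
#' # combine(ds, c("rs4072037", "rs9841504"))
#' @export
combine <- function(ds, snps,
                    comparisons = list(comparison_design("all-cases",
                                                         "controls")),
                    reference = c("lowest-dose", "explicit"),
                    ref_combo = NULL, min_count = 4L) {
  stopifnot(inherits(ds, "cohort"))
  reference <- match.arg(reference)
  if (inherits(comparisons, "comparison_design")) {
    comparisons <- list(comparisons)
  }
  if (anyDuplicated(snps)) stop("duplicate rs-ids in SNP subset")
  j <- match(snps, ds$snps$rs_id)
  if (anyNA(j)) stop("SNP(s) not in panel: ",
                     paste(snps[is.na(j)], collapse = ", "))
  if (length(snps) < 2L) {
    # single-SNP degenerate case: equivalent to a codominant table
    if (length(snps) < 1L) stop("at least one SNP is required")
  }
  doses <- dose_matrix(ds)[, j, drop = FALSE]
  geno <- ds$genotypes[, j, drop = FALSE]
  complete <- !apply(is.na(geno), 1L, any)
  labels <- apply(geno, 1L, paste, collapse = "-")
  labels[!complete] <- NA_character_
  total_dose <- rowSums(doses)

  groups <- unique(unlist(lapply(comparisons,
                                 function(d) c(d$group1, d$group2))))
  masks <- lapply(groups, function(g) group_mask(ds, g))
  names(masks) <- groups

  observed <- sort(unique(labels[complete &
                                   Reduce(`|`, masks, rep(FALSE, nrow(geno)))]))
  if (!length(observed)) stop("no complete-case subjects in any group")
  combo_dose <- vapply(observed, function(lb) {
    total_dose[complete & labels == lb][1]
  }, numeric(1))

  if (reference == "explicit") {
    if (is.null(ref_combo)) stop("reference = 'explicit' needs ref_combo")
    ref_combo <- normalize_combo_label(ref_combo, ds$snps[j, , drop = FALSE])
    if (!ref_combo %in% observed) {
      stop("reference combination '", ref_combo,
           "' not observed; observed combinations: ",
           paste(observed, collapse = ", "))
    }
  } else {
    ref_combo <- observed[order(combo_dose, observed)][1]
  }

  counts <- vapply(groups, function(g) {
    vapply(observed, function(lb) {
      sum(masks[[g]] & complete & labels == lb)
    }, numeric(1))
  }, numeric(length(observed)))
  counts <- matrix(counts, nrow = length(observed),
                   dimnames = list(observed, groups))
  group_sizes <- vapply(masks, sum, numeric(1))  # full enrolment denominators

  rows <- list()
  for (d in comparisons) {
    cmp_label <- paste0(d$group1, "_vs_", d$group2)
    n1_ref <- counts[ref_combo, d$group1]
    n2_ref <- counts[ref_combo, d$group2]
    for (lb in observed) {
      n1 <- counts[lb, d$group1]; n2 <- counts[lb, d$group2]
      row <- data.frame(
        comparison = cmp_label, combination = lb,
        total_dose = combo_dose[[lb]],
        n_group1 = n1, pct_group1 = 100 * n1 / group_sizes[[d$group1]],
        n_group2 = n2, pct_group2 = 100 * n2 / group_sizes[[d$group2]],
        reference = lb == ref_combo,
        filtered = FALSE, or = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_,
        effective_n = NA_integer_, stringsAsFactors = FALSE
      )
      if (lb == ref_combo) {
        row$or <- 1  # reference stratum: OR identically 1, no interval
      } else if (min(n1, n2, n1_ref, n2_ref) < min_count) {
        row$filtered <- TRUE
      } else {
        res <- odds_ratio(contingency_table(n1, n1_ref, n2, n2_ref),
                          correction = "haldane")
        row$or <- res$or; row$ci_low <- res$ci_low
        row$ci_high <- res$ci_high; row$p_value <- res$p_value
        row$effective_n <- res$effective_n
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "snps") <- snps
  attr(out, "reference") <- ref_combo
  attr(out, "min_count") <- min_count
  class(out) <- c("combo_table", "data.frame")
  out
}

# Normalize a user combination label ("GA-GG") to internal allele order.
normalize_combo_label <- function(label, panel) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) != nrow(panel)) {
    stop("combination label '", label, "' has ", length(parts),
         " genotypes; expected ", nrow(panel))
  }
  norm <- vapply(seq_along(parts), function(i) {
    al <- sort(strsplit(toupper(parts[i]), "")[[1]])
    paste(al, collapse = "")
  }, character(1))
  paste(norm, collapse = "-")
}

#' Order combined-genotype strata into a risk ladder
#'
#' Sorts the estimable strata of one comparison by ascending odds ratio and
#' annotates fold-increase vs the reference. Warns (does not error) when
#' the OR ordering disagrees with the total risk-allele dose ordering —
#' non-monotone ladders occur in real data.
#'
#' @param results a `combo_table` from [combine()].
#' @param by comparison label to ladder (default: the first present).
#' @return data frame sorted by OR with a `fold_increase` column
#'   (reference first).
#' @export
risk_ladder <- function(results, by = NULL) {
  stopifnot(inherits(results, "combo_table"))
  if (is.null(by)) by <- results$comparison[1]
  rows <- results[results$comparison == by & !results$filtered &
                    !is.na(results$or), , drop = FALSE]
  if (!nrow(rows)) stop("no estimable strata for comparison '", by, "'")
  rows <- rows[order(rows$or), , drop = FALSE]
  rows$fold_increase <- rows$or
  if (is.unsorted(rows$total_dose, strictly = FALSE)) {
    warning("risk ladder is not monotone in total risk-allele dose")
  }
  rownames(rows) <- NULL
  rows
}
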