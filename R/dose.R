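#' Risk-allele dose matrix
#'
#' Counts copies of each SNP's risk allele per subject: 0, 1 or 2, `NA` for
#' missing genotypes. Requires every SNP in the panel to have its risk
#' allele set.
#'
#' @param ds a [cohort()].
#' @return integer matrix, subjects x SNPs, entries in \{0, 1, 2, NA\}.
#' @seealso [assign_risk_alleles()]
#' @export
dose_matrix <- function(ds) {
  stopifnot(inherits(ds, "cohort"))
  unset <- is.na(ds$snps$risk_allele)
  if (any(unset)) {
    stop("risk allele unset for ",
         paste(ds$snps$rs_id[unset], collapse = ", "),
         "; call assign_risk_alleles() first")
  }
  doses <- matrix(NA_integer_, nrow(ds$genotypes), ncol(ds$genotypes),
                  dimnames = dimnames(ds$genotypes))
  for (j in seq_len(nrow(ds$snps))) {
    g <- ds$genotypes[, j]
    risk <- ds$snps$risk_allele[j]
    doses[, j] <- (substr(g, 1, 1) == risk) + (substr(g, 2, 2) == risk)
  }
  doses
}

#' Assign risk alleles to a cohort's SNP panel
#'
#' Either declares the minor allele among genotyped controls the risk allele
#' (`"minor-in-controls"`, the usual convention for a per-allele
#' minor-vs-major comparison), or applies a user-supplied map
#' (`"fixed-map"`). A control allele frequency of exactly 0.5 is broken
#' toward the lexicographically smaller allele, with a warning.
#'
#' @param ds a [cohort()].
#' @param rule `"minor-in-controls"` or `"fixed-map"`.
#' @param map named character vector `c(rs_id = allele, ...)` for
#'   `"fixed-map"`; SNPs absent from the map keep their current assignment.
#' @return the cohort with `risk_allele` filled in on its panel.
#' @export
assign_risk_alleles <- function(ds,
                                rule = c("minor-in-controls", "fixed-map"),
                                map = NULL) {
  stopifnot(inherits(ds, "cohort"))
  rule <- match.arg(rule)
  snps <- ds$snps
  if (rule == "fixed-map") {
    if (is.null(map) || is.null(names(map))) {
      stop("rule 'fixed-map' requires a named map c(rs_id = allele, ...)")
    }
    unknown <- setdiff(names(map), snps$rs_id)
    if (length(unknown)) {
      stop("fixed map names SNP(s) not in the panel: ",
           paste(unknown, collapse = ", "))
    }
    for (rs in names(map)) {
      j <- match(rs, snps$rs_id)
      al <- toupper(map[[rs]])
      if (!al %in% c(snps$allele_a[j], snps$allele_b[j])) {
        stop(sprintf("allele '%s' is not an allele of %s (%s/%s)",
                     al, rs, snps$allele_a[j], snps$allele_b[j]))
      }
      snps$risk_allele[j] <- al
    }
  } else {
    is_ctrl <- ds$subjects$status == "control"
    for (j in seq_len(nrow(snps))) {
      g <- ds$genotypes[is_ctrl, j]
      g <- g[!is.na(g)]
      if (!length(g)) {
        stop("no genotyped control for ", snps$rs_id[j],
             "; cannot apply minor-in-controls")
      }
      a <- snps$allele_a[j]
      freq_a <- mean(c(substr(g, 1, 1), substr(g, 2, 2)) == a)
      if (freq_a == 0.5) {
        minor <- min(a, snps$allele_b[j])
        warning(sprintf(
          "%s: control allele frequency exactly 0.5; tie broken toward '%s'",
          snps$rs_id[j], minor))
      } else {
        minor <- if (freq_a < 0.5) a else snps$allele_b[j]
      }
      snps$risk_allele[j] <- minor
    }
  }
  ds$snps <- validate_snp_panel(snps)
  ds
}
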