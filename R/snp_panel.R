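#' Define a SNP panel
#'
#' A SNP panel is the locus metadata table every cohort carries: one row per
#' biallelic SNP with its rs identifier, a gene label, the two alleles, and
#' (once assigned) the risk allele used to count allele doses.
#'
#' @param rs_id character vector of rs identifiers; must be unique.
#' @param gene_label character vector of gene symbols (display only).
#' @param allele_a,allele_b single-character alleles (A/C/G/T); must differ
#'   within each SNP.
#' @param risk_allele per-SNP risk allele, each entry one of the SNP's two
#'   alleles or `NA` for "unset". Doses cannot be computed until set (see
#'   [assign_risk_alleles()]).
#' @return A `snp_panel`: a data frame with columns `rs_id`, `gene_label`,
#'   `allele_a`, `allele_b`, `risk_allele`.
#' @examples
#' snp_panel("rs4072037", "MUC1", "A", "G", risk_allele = "A")
#' @export
snp_panel <- function(rs_id, gene_label, allele_a, allele_b,
                      risk_allele = NA_character_) {
  n <- length(rs_id)
  risk_allele <- rep_len(as.character(risk_allele), n)
  panel <- data.frame(
    rs_id = as.character(rs_id),
    gene_label = rep_len(as.character(gene_label), n),
    allele_a = toupper(as.character(allele_a)),
    allele_b = toupper(as.character(allele_b)),
    risk_allele = toupper(risk_allele),
    stringsAsFactors = FALSE
  )
  validate_snp_panel(panel)
}

validate_snp_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  needed <- c("rs_id", "gene_label", "allele_a", "allele_b", "risk_allele")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols)) {
    stop("snp_panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$rs_id)) {
    stop("duplicate rs_id in SNP panel: ",
         paste(unique(panel$rs_id[duplicated(panel$rs_id)]), collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  if (!all(panel$allele_a %in% bases) || !all(panel$allele_b %in% bases)) {
    stop("alleles must be single bases A/C/G/T")
  }
  if (any(panel$allele_a == panel$allele_b)) {
    stop("allele_a and allele_b must differ (SNP ",
         panel$rs_id[panel$allele_a == panel$allele_b][1], ")")
  }
  bad_risk <- !is.na(panel$risk_allele) &
    panel$risk_allele != panel$allele_a & panel$risk_allele != panel$allele_b
  if (any(bad_risk)) {
    stop("risk_allele not among the SNP's alleles for ",
         paste(panel$rs_id[bad_risk], collapse = ", "))
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Default six-SNP gastric-cancer susceptibility panel
#'
#' The candidate loci studied for early-onset gastric carcinoma in Han
#' Chinese: MUC1 rs4072037, ZBTB20 rs9841504, PSCA rs2294008, PLCE1
#' rs2274223, PTGER4/PRKAA1 rs13361707, and TYMS rs2790. Risk alleles follow
#' the published combined-genotype tables (the higher-risk homozygote at
#' each locus carries two copies of the listed risk allele).
#'
#' Note: gene labels follow the per-locus results tables; the source
#' abstract transposes the MUC1/ZBTB20 labels, a known inconsistency.
#'
#' @param risk_alleles set risk alleles (default) or leave unset with
#'   `risk_alleles = FALSE` (e.g. to exercise [assign_risk_alleles()]).
#' @return A [snp_panel()] of six SNPs.
#' @export
gc_snp_panel <- function(risk_alleles = TRUE) {
  panel <- snp_panel(
    rs_id = c("rs4072037", "rs9841504", "rs2294008",
              "rs2274223", "rs13361707", "rs2790"),
    gene_label = c("MUC1", "ZBTB20", "PSCA", "PLCE1", "PTGER4/PRKAA1", "TYMS"),
    allele_a = c("A", "C", "C", "A", "A", "A"),
    allele_b = c("G", "G", "T", "G", "G", "G"),
    risk_allele = if (isTRUE(risk_alleles)) {
      c("A", "C", "T", "G", "G", "G")
    } else {
      NA_character_
    }
  )
  panel
}
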