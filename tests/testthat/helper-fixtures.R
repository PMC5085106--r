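# Fixtures are built in code. The published combined-genotype tables give
# per-combination counts; combo_cohort() reconstitutes a cohort with exactly
# those counts so the stratification engine can be checked against print.

# Published combined-genotype counts (cases / controls, or three groups).
# Combination labels use internal alphabetical allele order.
table4_counts <- data.frame(
  rs4072037 = c("AG", "AG", "AA", "AA"),
  rs9841504 = c("GG", "CG", "GG", "CG"),
  cases =    c(12, 7, 69, 23),
  controls = c(29, 5, 57, 9),
  stringsAsFactors = FALSE
)

table5_counts <- data.frame(
  rs2274223  = c("AA", "AA", "AG", "AG"),
  rs13361707 = c("AA", "AG", "AA", "AG"),
  casesA =   c(7, 19, 6, 19),
  casesB =   c(11, 17, 2, 4),
  controls = c(18, 33, 7, 16),
  stringsAsFactors = FALSE
)

table6_counts <- data.frame(
  rs4072037 = c("AG", "AA", "AA", "AA", "AA"),
  rs9841504 = c("GG", "GG", "GG", "CG", "CG"),
  rs2790    = c("AA", "AA", "AG", "AA", "AG"),
  cases =    c(3, 24, 36, 9, 11),
  controls = c(9, 26, 22, 4, 4),
  stringsAsFactors = FALSE
)

# Build a cohort whose genotype combinations over `snp_ids` occur with the
# given group counts. `counts` is a data.frame: one column per rs-id, then
# one count column per group among cases / casesA / casesB / controls.
combo_cohort <- function(counts, snp_ids) {
  panel <- gc_snp_panel()
  panel <- validate_panel_subset(panel, snp_ids)
  group_cols <- setdiff(names(counts), snp_ids)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (g in group_cols) {
      n <- counts[i, g]
      if (n == 0) next
      status <- if (g == "controls") "control" else "case"
      hered <- switch(g, casesA = TRUE, casesB = FALSE,
                      cases = FALSE, controls = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        status = status, hereditary = hered,
        geno = I(matrix(rep(unlist(counts[i, snp_ids]), n),
                        nrow = n, byrow = TRUE)),
        stringsAsFactors = FALSE
      )
    }
  }
  all <- do.call(rbind, rows)
  n <- nrow(all)
  subjects <- data.frame(
    id = sprintf("X%04d", seq_len(n)),
    status = all$status,
    sex = rep_len(c("male", "female"), n),
    age = rep_len(c(35L, 45L), n),
    hereditary = all$hereditary,
    location = ifelse(all$status == "case", "noncardia", NA),
    lauren = ifelse(all$status == "case", "diffuse", NA),
    stringsAsFactors = FALSE
  )
  geno <- matrix(unclass(all$geno), nrow = n)
  colnames(geno) <- snp_ids
  cohort(subjects, geno, panel)
}

validate_panel_subset <- function(panel, snp_ids) {
  panel <- panel[match(snp_ids, panel$rs_id), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

# A tiny hand-written 3-subject cohort exercising every phenotype field.
tiny_cohort <- function() {
  subjects <- data.frame(
    id = c("P1", "P2", "C1"),
    status = c("case", "case", "control"),
    sex = c("male", "female", "male"),
    age = c(38L, 45L, 40L),
    hereditary = c(TRUE, FALSE, NA),
    location = c("cardia", "noncardia", NA),
    lauren = c("diffuse", "intestinal", NA),
    stringsAsFactors = FALSE
  )
  geno <- rbind(
    c("AA", "GG", "CT", "AG", "AA", "AG"),
    c("GA", "GC", "TT", "AA", "GA", "GG"),
    c("AA", "GG", "CC", "AG", "AA", "AA")
  )
  colnames(geno) <- gc_snp_panel()$rs_id
  cohort(subjects, geno)
}
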