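test_that("two-SNP stratification reproduces the published MUC1-ZBTB20 table", {
  ds <- combo_cohort(table4_counts, c("rs4072037", "rs9841504"))
  tab <- combine(ds, c("rs4072037", "rs9841504"), min_count = 4)
  expect_equal(attr(tab, "reference"), "AG-GG")  # lowest observed dose
  ref <- tab[tab$reference, ]
  expect_equal(ref$or, 1)
  expect_true(is.na(ref$ci_low))

  get_or <- function(combo) round(tab$or[tab$combination == combo], 2)
  expect_equal(get_or("AG-CG"), 3.38)
  expect_equal(get_or("AA-GG"), 2.93)
  expect_equal(get_or("AA-CG"), 6.18)
  expect_equal(round(tab$p_value[tab$combination == "AA-GG"], 4), 0.0046)
  expect_equal(round(tab$p_value[tab$combination == "AA-CG"], 4), 0.0003)
})

test_that("three-group stratification reproduces the PLCE1-PRKAA1 table", {
  ds <- combo_cohort(table5_counts, c("rs2274223", "rs13361707"))
  tab <- combine(
    ds, c("rs2274223", "rs13361707"),
    comparisons = list(
      comparison_design("hereditary-cases", "controls"),
      comparison_design("hereditary-cases", "sporadic-cases")),
    min_count = 2)
  vs_ctrl <- tab[tab$comparison == "hereditary-cases_vs_controls", ]
  vs_b <- tab[tab$comparison == "hereditary-cases_vs_sporadic-cases", ]
  expect_equal(round(vs_ctrl$or[vs_ctrl$combination == "AG-AG"], 2), 3.05)
  expect_equal(round(vs_b$or[vs_b$combination == "AG-AG"], 2), 7.46)
  expect_equal(round(vs_ctrl$p_value[vs_ctrl$combination == "AG-AG"], 4),
               0.0428)
  expect_equal(round(vs_b$p_value[vs_b$combination == "AG-AG"], 4), 0.0039)
})

test_that("stratum counts partition the complete-case group totals", {
  cfg <- synthetic_config(missing_rate = 0.05, seed = 17)
  ds <- generate_cohort(cfg)
  snps <- c("rs4072037", "rs9841504")
  tab <- combine(ds, snps)
  one_cmp <- tab[tab$comparison == tab$comparison[1], ]
  j <- match(snps, ds$snps$rs_id)
  complete <- !apply(is.na(ds$genotypes[, j]), 1, any)
  expect_equal(sum(one_cmp$n_group1),
               sum(complete & ds$subjects$status == "case"))
  expect_equal(sum(one_cmp$n_group2),
               sum(complete & ds$subjects$status == "control"))
})

test_that("single-SNP stratification degenerates to the codominant analysis", {
  cfg <- synthetic_config(missing_rate = 0, seed = 23)
  ds <- generate_cohort(cfg)
  tab <- combine(ds, "rs2274223", min_count = 1)
  # codominant single-locus oracle from genotype counts
  d_case <- genotype_counts(ds, "rs2274223",
                            ds$subjects$status == "case")
  d_ctrl <- genotype_counts(ds, "rs2274223",
                            ds$subjects$status == "control")
  het <- odds_ratio(contingency_table(d_case[["n1"]], d_case[["n0"]],
                                      d_ctrl[["n1"]], d_ctrl[["n0"]]),
                    correction = "haldane")
  hom <- odds_ratio(contingency_table(d_case[["n2"]], d_case[["n0"]],
                                      d_ctrl[["n2"]], d_ctrl[["n0"]]),
                    correction = "haldane")
  expect_equal(tab$or[tab$combination == "AG"], het$or)
  expect_equal(tab$or[tab$combination == "GG"], hom$or)
})

test_that("SNP order permutes labels but leaves counts and ORs unchanged", {
  ds <- combo_cohort(table4_counts, c("rs4072037", "rs9841504"))
  t1 <- combine(ds, c("rs4072037", "rs9841504"), min_count = 1)
  t2 <- combine(ds, c("rs9841504", "rs4072037"), min_count = 1)
  flip <- function(lbl) {
    parts <- strsplit(lbl, "-")
    vapply(parts, function(p) paste(rev(p), collapse = "-"), character(1))
  }
  t2$combination <- flip(t2$combination)
  t2 <- t2[match(t1$combination, t2$combination), ]
  expect_equal(t1$or, t2$or)
  expect_equal(t1$n_group1, t2$n_group1)
  expect_equal(t1$p_value, t2$p_value)
})

test_that("small strata keep their counts but lose the estimate", {
  counts <- table4_counts
  counts$cases[2] <- 2  # push AG-CG under the default threshold
  ds <- combo_cohort(counts, c("rs4072037", "rs9841504"))
  tab <- combine(ds, c("rs4072037", "rs9841504"), min_count = 4)
  row <- tab[tab$combination == "AG-CG", ]
  expect_true(row$filtered)
  expect_equal(row$n_group1, 2)
  expect_true(is.na(row$or))
})

test_that("reference selection is validated", {
  ds <- combo_cohort(table4_counts, c("rs4072037", "rs9841504"))
  expect_error(
    combine(ds, c("rs4072037", "rs9841504"), reference = "explicit",
            ref_combo = "GG-CC"),
    "observed combinations")
  tab <- combine(ds, c("rs4072037", "rs9841504"), reference = "explicit",
                 ref_combo = "GA-GG")  # order-insensitive label
  expect_equal(attr(tab, "reference"), "AG-GG")
  expect_error(combine(ds, c("rs4072037", "rs4072037")), "duplicate")
})

test_that("risk ladder orders strata by ascending odds ratio", {
  ds4 <- combo_cohort(table4_counts, c("rs4072037", "rs9841504"))
  ladder <- risk_ladder(combine(ds4, c("rs4072037", "rs9841504"),
                                min_count = 4))
  expect_equal(ladder$combination,
               c("AG-GG", "AA-GG", "AG-CG", "AA-CG"))

  ds6 <- combo_cohort(table6_counts,
                      c("rs4072037", "rs9841504", "rs2790"))
  ladder6 <- risk_ladder(combine(ds6,
                                 c("rs4072037", "rs9841504", "rs2790"),
                                 min_count = 3))
  expect_equal(ladder6$combination[nrow(ladder6)], "AA-CG-AG")
  expect_equal(round(ladder6$fold_increase[nrow(ladder6)], 2), 8.25)

  # a deliberately dose-inverted table warns but still ladders
  counts <- data.frame(
    rs4072037 = c("GG", "AG", "AA"), rs9841504 = c("GG", "GG", "GG"),
    cases = c(10, 5, 30), controls = c(10, 20, 10))
  dsx <- combo_cohort(counts, c("rs4072037", "rs9841504"))
  expect_warning(
    risk_ladder(combine(dsx, c("rs4072037", "rs9841504"), min_count = 1)),
    "monotone")
})
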