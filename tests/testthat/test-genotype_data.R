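test_that("TSV round-trip is the identity on valid cohorts", {
  ds <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(ds, path)
  ds2 <- read_cohort(path, format = "tsv")
  expect_equal(ds2$subjects, ds$subjects)
  expect_equal(ds2$genotypes, ds$genotypes)
  expect_equal(ds2$snps, ds$snps)
})

test_that("ped/map parse equals the TSV parse of the same subjects", {
  ds <- tiny_cohort()
  prefix <- withr::local_tempfile()
  # write ped/map by hand from the cohort
  panel <- ds$snps
  ped <- cbind(
    "FAM", ds$subjects$id, "0", "0",
    ifelse(ds$subjects$sex == "male", "1", "2"),
    ifelse(ds$subjects$status == "case", "2", "1"))
  for (j in seq_len(nrow(panel))) {
    g <- ds$genotypes[, j]
    ped <- cbind(ped, substr(g, 1, 1), substr(g, 2, 2))
  }
  write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(
    data.frame(chrom = "1", rs = panel$rs_id, cm = "0",
               bp = seq_len(nrow(panel))),
    paste0(prefix, ".map"), quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  side <- withr::local_tempfile(fileext = ".tsv")
  write.table(
    data.frame(id = ds$subjects$id, age = ds$subjects$age,
               hereditary = as.integer(ds$subjects$hereditary),
               location = ds$subjects$location,
               lauren = ds$subjects$lauren),
    side, sep = "\t", quote = FALSE, row.names = FALSE)
  ds2 <- read_cohort(paste0(prefix, ".ped"), format = "ped-map",
                     sidecar = side)
  expect_equal(ds2$subjects, ds$subjects)
  expect_equal(ds2$genotypes, ds$genotypes)
})

test_that("invalid genotypes and duplicate ids are rejected with context", {
  ds <- tiny_cohort()
  geno <- ds$genotypes
  geno[2, "rs4072037"] <- "TT"   # rs4072037 is A/G
  expect_error(cohort(ds$subjects, geno, ds$snps), "rs4072037")
  expect_error(cohort(ds$subjects, geno, ds$snps), "P2")

  subj <- ds$subjects
  subj$id <- c("P1", "P1", "C1")
  expect_error(cohort(subj, ds$genotypes, ds$snps), "duplicate")

  subj <- ds$subjects
  subj$age[1] <- 57L             # outside the early-onset window
  expect_error(cohort(subj, ds$genotypes, ds$snps), "age")
})

test_that("controls may not carry tumour fields or hereditary flags", {
  ds <- tiny_cohort()
  subj <- ds$subjects
  subj$location[3] <- "cardia"
  expect_error(cohort(subj, ds$genotypes, ds$snps), "controls")
  subj <- ds$subjects
  subj$hereditary[3] <- TRUE
  expect_error(cohort(subj, ds$genotypes, ds$snps), "hereditary")
})

test_that("dose counting follows the risk allele and ignores allele order", {
  ds <- tiny_cohort()
  dm <- dose_matrix(ds)
  expect_identical(dm["P1", "rs4072037"], 2L)  # AA, risk A
  expect_identical(dm["P1", "rs9841504"], 0L)  # GG, risk C
  expect_identical(dm["P2", "rs4072037"], 1L)  # GA == AG
  expect_identical(dm["P2", "rs2294008"], 2L)  # TT, risk T

  # allele-order permutation changes nothing: "GA" was normalized to "AG"
  expect_identical(ds$genotypes["P2", "rs4072037"], "AG")

  geno <- ds$genotypes
  geno[1, "rs2294008"] <- NA
  ds2 <- cohort(ds$subjects, geno, ds$snps)
  expect_true(is.na(dose_matrix(ds2)["P1", "rs2294008"]))
})

test_that("dose_matrix demands assigned risk alleles", {
  ds <- tiny_cohort()
  ds$snps$risk_allele <- NA_character_
  expect_error(dose_matrix(ds), "assign_risk_alleles")
})

test_that("risk-allele assignment rules behave as documented", {
  # 10 controls at rs4072037: 7 AA, 3 AG -> A freq 0.85, minor is G
  subjects <- data.frame(
    id = sprintf("C%02d", 1:10), status = "control",
    sex = "male", age = 40L, hereditary = NA,
    location = NA, lauren = NA, stringsAsFactors = FALSE)
  geno <- matrix("AA", 10, 6,
                 dimnames = list(NULL, gc_snp_panel()$rs_id))
  geno[, 2] <- "GG"; geno[, 3] <- "CC"; geno[, 4] <- "AA"
  geno[, 5] <- "AA"; geno[, 6] <- "AA"
  geno[1:3, 1] <- "AG"
  ds <- cohort(subjects, geno, gc_snp_panel(risk_alleles = FALSE))
  ds2 <- assign_risk_alleles(ds, rule = "minor-in-controls")
  expect_identical(ds2$snps$risk_allele[1], "G")

  # fixed map wins regardless of frequency
  ds3 <- assign_risk_alleles(ds, rule = "fixed-map",
                             map = c(rs4072037 = "A"))
  expect_identical(ds3$snps$risk_allele[1], "A")
  expect_error(
    assign_risk_alleles(ds, rule = "fixed-map", map = c(rs4072037 = "T")),
    "not an allele")

  # exact 50% frequency: lexicographically smaller allele, with warning
  geno[, 1] <- rep(c("AA", "GG"), 5)
  ds4 <- cohort(subjects, geno, gc_snp_panel(risk_alleles = FALSE))
  expect_warning(ds5 <- assign_risk_alleles(ds4, "minor-in-controls"),
                 "tie")
  expect_identical(ds5$snps$risk_allele[1], "A")
})

test_that("complete-case and missing counts partition the cohort", {
  cfg <- synthetic_config(n_cases_hered = 20, n_cases_sporadic = 20,
                          n_controls = 40, missing_rate = 0.15, seed = 11)
  ds <- generate_cohort(cfg)
  miss <- missingness(ds)
  expect_equal(miss$n_missing + miss$n_complete,
               rep(nrow(ds$subjects), nrow(ds$snps)))
  expect_gt(sum(miss$n_missing), 0)
})
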