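test_that("HWE chi-square matches hand-computed values", {
  res <- hwe_chi_square(c(25, 50, 25))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$degenerate)

  # p_hat = 0.5, expected (25, 50, 25)
  res <- hwe_chi_square(c(30, 40, 30))
  expect_equal(res$statistic, 4.0)
  expect_equal(res$p_value, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # p_hat = 0.6, expected (36, 48, 16): 196/36 + 784/48 + 196/16
  res <- hwe_chi_square(c(50, 20, 30))
  expect_equal(res$statistic, 196 / 36 + 784 / 48 + 196 / 16,
               tolerance = 1e-12)

  expect_true(hwe_chi_square(c(40, 0, 0))$degenerate)
  expect_error(hwe_chi_square(c(1, 2)), "three")
})

test_that("HWE statistic is invariant under dose relabeling 0 <-> 2", {
  set.seed(42)
  for (i in 1:25) {
    counts <- as.numeric(rmultinom(1, 80, prob = runif(3, 0.05, 1)))
    a <- hwe_chi_square(counts)
    b <- hwe_chi_square(rev(counts))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  }
})

test_that("odds_ratio reproduces cross-product, Woolf CI and chi-square p", {
  res <- odds_ratio(contingency_table(69, 12, 57, 29))
  expect_equal(round(res$or, 2), 2.93)
  expect_equal(round(res$p_value, 4), 0.0046)
  # hand-computed Woolf interval: ln OR 1.0733, SE 0.3871
  expect_equal(round(res$ci_low, 2), 1.37)
  expect_equal(round(res$ci_high, 2), 6.25)
  expect_equal(res$effective_n, 167L)

  res <- odds_ratio(contingency_table(10, 10, 10, 10))
  expect_equal(res$or, 1.0)
  expect_equal(res$p_value, 1.0)
})

test_that("swapping groups inverts the odds ratio exactly", {
  set.seed(7)
  for (i in 1:50) {
    cells <- sample(1:40, 4, replace = TRUE)
    r1 <- odds_ratio(contingency_table(cells[1], cells[2],
                                       cells[3], cells[4]))
    r2 <- odds_ratio(contingency_table(cells[3], cells[4],
                                       cells[1], cells[2]))
    expect_equal(r1$or * r2$or, 1, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  }
})

test_that("zero-cell policy: error by default, Haldane on request", {
  tab <- contingency_table(0, 10, 5, 5)
  expect_error(odds_ratio(tab, correction = "none"), "haldane")
  res <- odds_ratio(tab, correction = "haldane")
  expect_equal(res$or, (0.5 * 5.5) / (10.5 * 5.5))
  expect_identical(res$note, "haldane-corrected")
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("genetic-model encodings match their definitions", {
  # group counts (n0, n1, n2) = (10, 20, 30): 2*30+20 risk, 2*10+20 non-risk
  dose <- rep(0:2, c(10, 20, 30))
  expect_equal(encode_model(dose, "allelic"), c(risk = 80, nonrisk = 40))
  expect_equal(encode_model(c(0, 1, 2), "dominant"), c(0L, 1L, 1L))
  expect_equal(encode_model(c(0, 1, 2), "recessive"), c(0L, 0L, 1L))
  cod <- encode_model(c(0, 1, 2), "codominant")
  expect_equal(cod[, "dose1"], c(0L, 1L, 0L))
  expect_equal(cod[, "dose2"], c(0L, 0L, 1L))
  expect_error(encode_model(c(0, NA), "dominant"), "missing")
  expect_error(encode_model(c(0, 3), "dominant"), "0, 1 or 2")
})

test_that("saturated logistic fit equals the cross-product odds ratio", {
  # binary exposure, no covariates: MLE is analytic
  a <- 69; b <- 12; c <- 57; d <- 29
  y <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  x <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  fit <- fit_logistic(cbind(1, exposure = x), y)
  expect_equal(exp(fit$coef[["exposure"]]), a * d / (b * c),
               tolerance = 1e-6)
})

test_that("adjusted logistic OR matches a brute-force likelihood oracle", {
  cfg <- synthetic_config(
    n_cases_hered = 0, n_cases_sporadic = 200, n_controls = 200,
    loci = data.frame(rs_id = "rsX", p_risk = 0.3, or = 2.0),
    sex_logit = 0.8, missing_rate = 0, seed = 303)
  ds <- generate_cohort(cfg)
  res <- fit_logistic_or(ds, "rsX", model = "allelic",
                         covariates = "sex")
  # independent oracle: direct maximization of the log-likelihood over
  # (intercept, dose, sex) with optim, no IRLS involved
  dose <- dose_matrix(ds)[, "rsX"]
  y <- as.numeric(ds$subjects$status == "case")
  sex <- as.integer(ds$subjects$sex == "male")
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * dose + beta[3] * sex
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(res$or, exp(opt$par[2]), tolerance = 1e-4)
})

test_that("complete separation raises a separation error", {
  y <- rep(c(1, 0), c(20, 20))
  x <- rep(c(1, 0), c(20, 20))
  expect_error(fit_logistic(cbind(1, x), y), class = "separation_error")
})

test_that("the three standard comparisons report the enrolled group sizes", {
  cfg <- synthetic_config(missing_rate = 0, seed = 5)  # 65/51/102 world
  ds <- generate_cohort(cfg)
  res <- run_comparisons(ds, "rs4072037")
  expect_equal(res$cases_vs_controls$effective_n, 116L + 102L)
  expect_equal(res$casesA_vs_controls$effective_n, 65L + 102L)
  expect_equal(res$casesA_vs_casesB$effective_n, 65L + 51L)
  expect_equal(res$cases_vs_controls$adjusted_for, c("sex", "age"))
})

test_that("cohorts without controls or hereditary cases are handled", {
  cfg <- synthetic_config(n_cases_hered = 10, n_cases_sporadic = 10,
                          n_controls = 0, seed = 8,
                          loci = data.frame(rs_id = "rsX", p_risk = 0.3,
                                            or = 1.5))
  expect_error(run_comparisons(generate_cohort(cfg), "rsX"),
               "no controls")

  cfg <- synthetic_config(n_cases_hered = 0, n_cases_sporadic = 40,
                          n_controls = 40, seed = 9, missing_rate = 0,
                          loci = data.frame(rs_id = "rsX", p_risk = 0.3,
                                            or = 1.5))
  res <- run_comparisons(generate_cohort(cfg), "rsX")
  expect_false(res$cases_vs_controls$degenerate)
  expect_true(res$casesA_vs_controls$degenerate)
  expect_true(res$casesA_vs_casesB$degenerate)
})

test_that("casesA vs casesB is null-centered when subgroups share effects", {
  # identical generative effects in both case subgroups -> OR centered on 1
  cfg0 <- synthetic_config(
    n_cases_hered = 60, n_cases_sporadic = 60, n_controls = 20,
    loci = data.frame(rs_id = "rsX", p_risk = 0.35, or = 1.8),
    missing_rate = 0, seed = 0)
  log_ors <- vapply(1:200, function(r) {
    cfg <- cfg0; cfg$seed <- 1000L + r
    ds <- generate_cohort(cfg)
    res <- fit_logistic_or(ds, "rsX", model = "allelic",
                           design = comparison_design("hereditary-cases",
                                                      "sporadic-cases"))
    log(res$or)
  }, numeric(1))
  se_mean <- sd(log_ors) / sqrt(length(log_ors))
  expect_lt(abs(mean(log_ors)), 3.5 * se_mean + 0.01)
})

test_that("subgroup strata partition the effective sample", {
  cfg <- synthetic_config(missing_rate = 0.05, seed = 21)
  ds <- generate_cohort(cfg)
  res <- subgroup_analysis(ds, "rs2294008", factor = "sex",
                           design = comparison_design("all-cases",
                                                      "controls"))
  full <- fit_logistic_or(ds, "rs2294008",
                          design = comparison_design("all-cases",
                                                     "controls"),
                          covariates = "age")
  expect_equal(res$male$effective_n + res$female$effective_n,
               full$effective_n)
  expect_equal(res$male$adjusted_for, "age")
})

test_that("degenerate strata are flagged, not estimated", {
  # all cardia cases homozygous: separation within the stratum
  counts <- data.frame(
    rs4072037 = c("AA", "AG"), rs9841504 = c("GG", "GG"),
    cases = c(15, 0), controls = c(10, 10))
  ds <- combo_cohort(counts, c("rs4072037", "rs9841504"))
  ds$subjects$location[ds$subjects$status == "case"] <- "cardia"
  res <- subgroup_analysis(ds, "rs4072037", factor = "location",
                           design = comparison_design("all-cases",
                                                      "controls"))
  expect_true(res$cardia$degenerate)
  expect_true(is.na(res$cardia$or))
})

test_that("sex-specific effects are detected in the right stratum", {
  # true male-only effect: OR 3 in males, 1 in females
  cfg0 <- synthetic_config(
    n_cases_hered = 0, n_cases_sporadic = 2000, n_controls = 2000,
    loci = data.frame(rs_id = "rsX", p_risk = 0.3, or = 3.0,
                      or_female = 1.0),
    missing_rate = 0, seed = 0)
  hits <- vapply(1:100, function(r) {
    cfg <- cfg0; cfg$seed <- 5000L + r
    ds <- generate_cohort(cfg)
    res <- subgroup_analysis(ds, "rsX", factor = "sex",
                             design = comparison_design("all-cases",
                                                        "controls"))
    (res$male$ci_low > 1) && (res$female$ci_low <= 1) &&
      (res$female$ci_high >= 1)
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})
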