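#' Logistic regression by iteratively reweighted least squares
#'
#' In-house maximum-likelihood fit of a binomial GLM with logit link. This
#' is the package's core estimation routine (deliberately not delegated to
#' `glm()`): Newton scoring with weights p(1-p), declared converged when
#' the largest absolute component of the score vector X'(y - p) falls
#' below `tol`.
#'
#' @param X numeric design matrix (include the intercept column yourself).
#' @param y 0/1 response vector.
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 50); exceeding it is an error
#'   carrying the iteration trace.
#' @param sep_threshold absolute coefficient bound beyond which complete or
#'   quasi-complete separation is declared (default 15 on the log-odds
#'   scale; e^15 ~ 3.3e6, far outside any epidemiological effect).
#' @return list with `coef`, `vcov` (inverse observed information), `se`,
#'   `loglik`, `iterations`, `converged`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 50L,
                         sep_threshold = 15) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  beta <- rep(0, ncol(X))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) < tol) {
      info <- crossprod(X * (p * (1 - p)), X)
      vcov <- solve(info)
      dimnames(vcov) <- list(colnames(X), colnames(X))
      names(beta) <- colnames(X)
      return(list(coef = beta, vcov = vcov, se = sqrt(diag(vcov)),
                  loglik = sum(y * eta - log1p(exp(eta))),
                  iterations = iter - 1L, converged = TRUE))
    }
    w <- p * (1 - p)
    w <- pmax(w, 1e-10)            # guard against exact 0/1 fitted values
    info <- crossprod(X * w, X)
    beta <- beta + drop(solve(info, score))
    trace <- c(trace, max(abs(score)))
    if (any(abs(beta) > sep_threshold)) {
      stop(structure(
        class = c("separation_error", "error", "condition"),
        list(message = paste0(
          "separation detected: |coefficient| exceeded ", sep_threshold,
          " at iteration ", iter,
          " (term ", colnames(X)[which.max(abs(beta))], ")"),
          call = NULL)))
    }
  }
  stop("IRLS did not converge in ", max_iter,
       " iterations; max |score| trace: ",
       paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
}

#' Comparison design: which two subject groups to contrast
#'
#' The three designs of the per-allele comparisons are cases vs controls,
#' hereditary-background cases (cases with >= 1 direct lineal relative with
#' digestive-tract or breast/ovarian cancer, "cases A") vs controls, and
#' hereditary vs non-hereditary cases ("cases A" vs "cases B").
#'
#' @param group1,group2 each one of `"all-cases"`, `"hereditary-cases"`,
#'   `"sporadic-cases"`, `"controls"` (aliases `"casesA"`, `"casesB"`).
#'   Group 1 is the numerator (coded 1 in the logistic response).
#' @return a `comparison_design` object.
#' @export
comparison_design <- function(group1, group2) {
  canon <- function(g) {
    aliases <- c("casesA" = "hereditary-cases",
                 "casesB" = "sporadic-cases", "cases" = "all-cases")
    if (g %in% names(aliases)) g <- aliases[[g]]
    match.arg(g, c("all-cases", "hereditary-cases", "sporadic-cases",
                   "controls"))
  }
  group1 <- canon(group1); group2 <- canon(group2)
  if (group1 == group2 ||
      (group1 %in% c("hereditary-cases", "sporadic-cases") &&
       group2 == "all-cases") ||
      (group2 %in% c("hereditary-cases", "sporadic-cases") &&
       group1 == "all-cases")) {
    stop("comparison groups must be disjoint: ", group1, " vs ", group2)
  }
  structure(list(group1 = group1, group2 = group2),
            class = "comparison_design")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

group_mask <- function(ds, group) {
  s <- ds$subjects
  switch(group,
    "all-cases" = s$status == "case",
    "hereditary-cases" = s$status == "case" & s$hereditary %in% TRUE,
    "sporadic-cases" = s$status == "case" & s$hereditary %in% FALSE,
    "controls" = s$status == "control",
    stop("unknown group: ", group))
}

# Build response/masks for a design; errors on empty groups.
design_response <- function(ds, design) {
  stopifnot(inherits(design, "comparison_design"))
  m1 <- group_mask(ds, design$group1)
  m2 <- group_mask(ds, design$group2)
  if (!any(m1)) stop("no subjects in group '", design$group1, "'")
  if (!any(m2)) stop("no subjects in group '", design$group2, "'")
  list(mask = m1 | m2, y = ifelse(m1, 1, 0)[m1 | m2])
}

#' Covariate-adjusted odds ratio for one SNP via in-house logistic fit
#'
#' Fits an unconditional logistic regression of group membership on the
#' genetic term implied by `model`, optionally adjusted for sex and/or age,
#' and reports exp(coefficient) with a Wald 95% interval. The `allelic`
#' model enters the dose linearly (log-additive per-allele effect, the
#' regression analogue of the per-allele contingency comparison);
#' `dominant`/`recessive` enter carrier/homozygote indicators; `codominant`
#' enters both indicators and returns one result per term. Complete-case:
#' subjects missing the genotype or any requested covariate are dropped.
#'
#' @param ds a [cohort()] with risk alleles set.
#' @param snp rs-id.
#' @param model genetic model, see [encode_model()].
#' @param design a [comparison_design()] (default cases vs controls).
#' @param covariates subset of `c("sex", "age")`.
#' @param age_coding `"continuous"` (years, default) or `"band"`
#'   (indicator of age > 40, mirroring the <=40 / >40 reporting bands).
#' @return an [assoc_result()]; for `codominant`, a list of two (terms
#'   `dose1`, `dose2`).
#' @export
fit_logistic_or <- function(ds, snp,
                            model = c("allelic", "codominant",
                                      "dominant", "recessive"),
                            design = comparison_design("all-cases",
                                                       "controls"),
                            covariates = character(),
                            age_coding = c("continuous", "band")) {
  model <- match.arg(model)
  age_coding <- match.arg(age_coding)
  stopifnot(all(covariates %in% c("sex", "age")))
  resp <- design_response(ds, design)
  doses <- snp_doses(ds, snp)[resp$mask]
  y <- resp$y
  s <- ds$subjects[resp$mask, , drop = FALSE]

  keep <- !is.na(doses)
  covs <- NULL
  if ("sex" %in% covariates) {
    sex <- as.integer(s$sex == "male")
    keep <- keep & !is.na(s$sex)
    covs <- cbind(covs, sex = sex)
  }
  if ("age" %in% covariates) {
    age <- if (age_coding == "band") as.integer(s$age > 40) else s$age
    keep <- keep & !is.na(s$age)
    covs <- cbind(covs, age = age)
  }
  doses <- doses[keep]; y <- y[keep]
  covs <- covs[keep, , drop = FALSE]
  if (!length(y) || length(unique(y)) < 2L) {
    stop("a comparison group is empty after complete-case filtering")
  }

  gen <- switch(model,
    allelic = cbind(dose = doses),
    dominant = cbind(dominant = encode_model(doses, "dominant")),
    recessive = cbind(recessive = encode_model(doses, "recessive")),
    codominant = encode_model(doses, "codominant"))
  X <- cbind(`(Intercept)` = 1, gen, covs)
  fit <- fit_logistic(X, y)
  terms <- colnames(gen)
  out <- lapply(terms, function(tm) {
    b <- fit$coef[[tm]]; se <- fit$se[[tm]]
    z <- b / se
    assoc_result(
      or = exp(b),
      ci_low = exp(b - 1.96 * se),
      ci_high = exp(b + 1.96 * se),
      p_value = 2 * stats::pnorm(-abs(z)),
      statistic = z,
      model = model, term = tm,
      adjusted_for = covariates,
      effective_n = length(y)
    )
  })
  if (model == "codominant") out else out[[1]]
}

#' Run the three standard comparisons for one SNP
#'
#' All cases vs controls, hereditary-background cases vs controls, and
#' hereditary vs non-hereditary cases, each sex- and age-adjusted.
#'
#' @inheritParams fit_logistic_or
#' @param covariates adjustment set applied to every comparison (default
#'   sex and age).
#' @return named list of three [assoc_result()]s (`cases_vs_controls`,
#'   `casesA_vs_controls`, `casesA_vs_casesB`). If no case has a recorded
#'   hereditary background, only the first is estimated and the others are
#'   returned as degenerate placeholders.
#' @export
run_comparisons <- function(ds, snp, model = "allelic",
                            covariates = c("sex", "age"),
                            age_coding = "continuous") {
  if (!any(ds$subjects$status == "control")) {
    stop("cohort contains no controls")
  }
  designs <- list(
    cases_vs_controls = comparison_design("all-cases", "controls"),
    casesA_vs_controls = comparison_design("hereditary-cases", "controls"),
    casesA_vs_casesB = comparison_design("hereditary-cases",
                                         "sporadic-cases")
  )
  has_hered <- any(ds$subjects$status == "case" &
                   ds$subjects$hereditary %in% TRUE)
  lapply(designs, function(dsgn) {
    if (!has_hered && dsgn$group1 == "hereditary-cases") {
      return(assoc_result(model = model, degenerate = TRUE,
                          note = "no hereditary-background cases",
                          effective_n = 0L))
    }
    fit_logistic_or(ds, snp, model = model, design = dsgn,
                    covariates = covariates, age_coding = age_coding)
  })
}

#' Subgroup (stratified) analysis for one SNP
#'
#' Stratifies by a subject factor and re-estimates the association within
#' each level. Controls carry no tumour location or Lauren type, so those
#' two factors stratify the case group only, each level being compared
#' against the full control group. Adjustment follows the stratification:
#' sex strata adjust for age only, age-band strata adjust for sex only,
#' location and Lauren strata adjust for both.
#'
#' @inheritParams fit_logistic_or
#' @param factor one of `"sex"`, `"age-band"` (<=40 vs >40), `"location"`,
#'   `"lauren"`.
#' @param design comparison design; defaults to hereditary cases vs
#'   controls, the usual subgroup contrast.
#' @return named list of [assoc_result()]s, one per factor level; levels
#'   where the fit is degenerate (separation, empty stratum) carry the
#'   degenerate flag instead of an estimate.
#' @export
subgroup_analysis <- function(ds, snp,
                              factor = c("sex", "age-band", "location",
                                         "lauren"),
                              design = comparison_design("hereditary-cases",
                                                         "controls"),
                              model = "allelic") {
  factor <- match.arg(factor)
  s <- ds$subjects
  case_only <- factor %in% c("location", "lauren")
  strata <- switch(factor,
    "sex" = list(male = s$sex == "male", female = s$sex == "female"),
    "age-band" = list(`<=40` = !is.na(s$age) & s$age <= 40,
                      `>40` = !is.na(s$age) & s$age > 40),
    "location" = list(noncardia = s$location == "noncardia",
                      cardia = s$location == "cardia"),
    "lauren" = list(intestinal = s$lauren == "intestinal",
                    diffuse = s$lauren == "diffuse",
                    mixed = s$lauren == "mixed"))
  covariates <- switch(factor,
    "sex" = "age", "age-band" = "sex", c("sex", "age"))
  out <- lapply(strata, function(in_level) {
    keep <- if (case_only) in_level | s$status == "control" else in_level
    sub <- subset_cohort(ds, keep)
    res <- tryCatch(
      fit_logistic_or(sub, snp, model = model, design = design,
                      covariates = covariates),
      error = function(e) {
        assoc_result(model = model, adjusted_for = covariates,
                     degenerate = TRUE, note = conditionMessage(e),
                     effective_n = sum(keep))
      })
    res
  })
  names(out) <- names(strata)
  out
}
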