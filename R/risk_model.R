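#' Per-locus effects for the multiplicative polygenic model
#'
#' @param rs_id locus identifiers.
#' @param p_risk risk-allele frequency in the reference population, each in
#'   \[0, 1\].
#' @param rr per-allele relative risk, each finite and > 0. Per-allele odds
#'   ratios are accepted as rare-disease approximations of relative risks;
#'   a message flags any value above 3, where the approximation degrades.
#' @return data frame of class `locus_effects`.
#' @export
locus_effects <- function(rs_id, p_risk, rr) {
  p_risk <- as.numeric(p_risk); rr <- as.numeric(rr)
  if (any(p_risk < 0 | p_risk > 1, na.rm = FALSE) || anyNA(p_risk)) {
    stop("p_risk must lie in [0, 1]")
  }
  if (anyNA(rr) || any(!is.finite(rr)) || any(rr <= 0)) {
    stop("rr must be finite and positive")
  }
  if (any(rr > 3)) {
    message("per-allele OR > 3 treated as relative risk; ",
            "rare-disease approximation may be poor")
  }
  structure(
    data.frame(rs_id = as.character(rs_id), p_risk = p_risk, rr = rr,
               stringsAsFactors = FALSE),
    class = c("locus_effects", "data.frame"))
}

#' Per-locus contribution to the variance of log relative risk
#'
#' Under Hardy-Weinberg genotype frequencies and a multiplicative
#' per-allele effect, the log relative risk at a locus is (ln rr) * G with
#' G ~ Binomial(2, p), so its variance contribution is
#' 2 p (1 - p) (ln rr)^2. Null effects (rr = 1) and monomorphic loci
#' (p = 0 or 1) contribute 0.
#'
#' @param p_risk risk-allele frequency (vectorized).
#' @param rr per-allele relative risk (vectorized).
#' @return numeric vector of variance contributions.
#' @examples
#' locus_variance(0.25, 2) # 2 * .25 * .75 * log(2)^2 ~ 0.1802
#' @export
locus_variance <- function(p_risk, rr) {
  if (any(rr <= 0) || anyNA(rr)) stop("rr must be positive")
  if (any(p_risk < 0 | p_risk > 1) || anyNA(p_risk)) {
    stop("p_risk must lie in [0, 1]")
  }
  2 * p_risk * (1 - p_risk) * log(rr)^2
}

#' Polygenic model specification
#'
#' Bundles the per-locus effects with the familial relative risk lambda
#' (risk to first-degree relatives of cases relative to population risk)
#' that anchors the total polygenic variance, and the assumed proportional
#' risk reduction achieved by endoscopic screening.
#'
#' @param loci a [locus_effects()] data frame.
#' @param lambda_familial familial relative risk, must exceed 1 for any
#'   variance to be apportioned.
#' @param screening_reduction assumed fractional risk reduction under
#'   screening, in \[0, 1\] (default 0.40, the gastroscopy assumption).
#' @return an object of class `polygenic_model_spec`.
#' @export
polygenic_model_spec <- function(loci, lambda_familial,
                                 screening_reduction = 0.40) {
  stopifnot(inherits(loci, "locus_effects"))
  if (!is.numeric(lambda_familial) || length(lambda_familial) != 1L) {
    stop("lambda_familial must be a single number")
  }
  if (screening_reduction < 0 || screening_reduction > 1) {
    stop("screening_reduction must lie in [0, 1]")
  }
  structure(list(loci = loci, lambda_familial = lambda_familial,
                 screening_reduction = screening_reduction),
            class = "polygenic_model_spec")
}

#' Fraction of familial (polygenic) risk explained by the modelled loci
#'
#' In the log-normal polygenic model, first-degree relatives share half the
#' log-risk variance, so a familial relative risk lambda implies a total
#' polygenic variance V = 2 ln(lambda). The fraction explained is the sum
#' of per-locus contributions ([locus_variance()]) over V, capped at 1
#' (with a warning) since the modelled loci are a subset of total genetic
#' risk.
#'
#' @param spec a [polygenic_model_spec()]; `lambda_familial` must be > 1.
#' @return fraction in \[0, 1\]. An empty locus list returns 0.
#' @export
fraction_explained <- function(spec) {
  stopifnot(inherits(spec, "polygenic_model_spec"))
  if (spec$lambda_familial <= 1) {
    stop("lambda_familial must exceed 1: no familial excess to apportion")
  }
  if (!nrow(spec$loci)) return(0)
  total_v <- 2 * log(spec$lambda_familial)
  frac <- sum(locus_variance(spec$loci$p_risk, spec$loci$rr)) / total_v
  if (frac > 1) {
    warning("locus contributions exceed the total polygenic variance; ",
            "fraction capped at 1")
    frac <- 1
  }
  frac
}

#' Relative risk at a percentile of the polygenic risk distribution
#'
#' With log relative risk ~ Normal(-V/2, V) (the mean-one convention, so
#' relative risk averages 1 over the population), the risk at percentile q
#' relative to the population median is exp(z_q sqrt(V)).
#'
#' @param V variance of log relative risk, >= 0.
#' @param q percentile in (0, 1); 0.5 returns 1 for every V.
#' @return relative risk vs the population median.
#' @export
risk_percentile_ratio <- function(V, q) {
  if (any(V < 0)) stop("V must be non-negative")
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  exp(stats::qnorm(q) * sqrt(V))
}

#' Expected yield of screening the top risk percentiles
#'
#' Under the mean-one log-normal risk model, computes the share of all
#' cases that arise in the top `top_fraction` of the risk distribution (by
#' adaptive quadrature of the risk-weighted normal density over the upper
#' tail, absolute tolerance 1e-9), and the absolute risk averted when
#' screening that group reduces risk by `reduction`.
#'
#' @param V variance of log relative risk, >= 0.
#' @param top_fraction screened share of the population, in (0, 1\].
#' @param reduction fractional risk reduction achieved by screening, in
#'   \[0, 1\] (default 0.40).
#' @param baseline_risk population absolute risk, in \[0, 1\].
#' @return list with `screened_share`, `case_share` (share of cases in the
#'   screened group; equals `top_fraction` when V = 0), and
#'   `risk_averted` = reduction x case_share x baseline_risk.
#' @export
screening_benefit <- function(V, top_fraction, reduction = 0.40,
                              baseline_risk = 0.01) {
  stopifnot(length(V) == 1L, length(top_fraction) == 1L)
  if (V < 0) stop("V must be non-negative")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  if (reduction < 0 || reduction > 1) stop("reduction must lie in [0, 1]")
  if (baseline_risk < 0 || baseline_risk > 1) {
    stop("baseline_risk must lie in [0, 1]")
  }
  case_share <- if (top_fraction == 1) {
    1
  } else if (V == 0) {
    top_fraction
  } else {
    # share of mean-one risk mass above the (1 - f) quantile:
    # integral over z > z0 of exp(-V/2 + sqrt(V) z) phi(z) dz, with the
    # exponentials combined so the integrand underflows (never overflows)
    # in the far tail
    z0 <- stats::qnorm(1 - top_fraction)
    stats::integrate(
      function(z) exp(-V / 2 + sqrt(V) * z - z^2 / 2) / sqrt(2 * pi),
      lower = z0, upper = Inf, abs.tol = 1e-9)$value
  }
  list(screened_share = top_fraction,
       case_share = case_share,
       risk_averted = reduction * case_share * baseline_risk)
}
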