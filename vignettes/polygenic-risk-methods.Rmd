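---
title: "Methods: case-control association and polygenic risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control association and polygenic risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyassoc)
```

## Scope and model

`polyassoc` analyzes small candidate-SNP case-control studies of a binary
disease outcome — the motivating application is early-onset gastric
carcinoma in a Han Chinese population, genotyped at six susceptibility loci
(MUC1 rs4072037, ZBTB20 rs9841504, PSCA rs2294008, PLCE1 rs2274223,
PTGER4/PRKAA1 rs13361707, TYMS rs2790). The statistical machinery is
generic: any panel of biallelic SNPs with case/control status, sex, age,
and optional hereditary-background, tumour-location and Lauren-type labels.

Three layers build on each other:

1. **Single-locus association** — contingency-table odds ratios and
   covariate-adjusted logistic regression under four genetic-model
   encodings.
2. **Combined-genotype stratification** — odds ratios for multi-SNP
   genotype combinations against a low-risk reference stratum.
3. **Multiplicative polygenic model** — apportioning familial risk to the
   modelled loci and translating aggregate risk variance into percentile
   and screening arithmetic.

## Single-locus statistics

**Hardy–Weinberg testing.** `hwe_chi_square()` is the 1-df goodness-of-fit
χ² of observed genotype counts against p², 2pq, q² at the sample allele
frequency, applied to controls as a genotyping-quality check. Monomorphic
samples return statistic 0 with a degenerate flag rather than an error,
because panels legitimately contain near-fixed loci.

**Crude odds ratios.** The cross-product ratio with the Woolf log-OR
interval. The interval method is a deliberate choice: the published tables
we reproduce are consistent with Woolf intervals computed from their
printed counts, and Woolf is the standard closed form at these sample
sizes. Profile-likelihood intervals are not implemented. p-values are the
uncorrected Pearson χ² (1 df): with Yates' continuity correction the
printed 4-decimal p-values (e.g. 0.0046 and 0.0003 for the two-SNP
combination table) are *not* reproduced, so the uncorrected statistic is
pinned by tests. Zero cells error by default; the Haldane–Anscombe +0.5
correction is opt-in (`correction = "haldane"`) and annotated in the
result, never silent. The correction applies to the estimate and interval
only; the χ² is always computed from the uncorrected counts.

**Genetic models.** `encode_model()` maps risk-allele doses to the allelic
(two-alleles-per-subject counts), dominant, recessive, and codominant
encodings. The per-allele ("allelic") regression analogue enters dose
0/1/2 linearly, i.e. a log-additive effect per risk-allele copy.

**Adjusted odds ratios.** `fit_logistic()` is an in-house IRLS
(Newton-scoring) maximum-likelihood fit — the package's core estimation
path, kept independent of `glm()` so it can be validated against
independent oracles (a BFGS likelihood maximization in the tests, and the
analytic cross-product identity on saturated 2×2 designs). Numerical
choices: start at zero, converge when max |X′(y−p)| < 1e-8, cap at 50
iterations, declare separation when any coefficient passes 15 on the
log-odds scale during iteration (e^15 ≈ 3×10⁶ is far beyond any
epidemiological effect; hitting it means a zero-margin stratum). Wald 95%
intervals come from the inverse observed information. Age enters in years
by default; a banded ≤40/>40 coding is available (`age_coding = "band"`)
because the source study reports age in those bands and its exact coding
is unknowable — both are supported, neither changes any conclusion pinned
by tests.

**Comparisons and subgroups.** The three standard designs (all cases vs
controls; hereditary-background cases vs controls; hereditary vs
non-hereditary cases) are adjusted for sex and age. Subgroup analyses
follow the source convention: sex strata adjust for age only, age-band
strata for sex only, location/Lauren strata (cases only, vs all controls)
for both. Degenerate strata — separation, empty cells — return a flagged
placeholder rather than an estimate.

## Combined-genotype stratification

`combine()` enumerates *observed* genotype tuples over the chosen SNPs
(unphased genotype strings, heterozygotes normalized to alphabetical
order, so the published "GA" heterozygote is the internal "AG"). Odds
ratios are deliberately **unadjusted** cross-product ratios: the published
combination tables are exactly reproduced by crude ratios of their printed
counts, which pins the convention. Design choices:

- **Reference stratum**: the observed combination with the lowest total
  risk-allele dose (ties broken by label order), overridable via
  `reference = "explicit"`. This matches the published tables, which all
  use the lowest-risk observed combination as reference.
- **Complete-case counts, enrolled-denominator percentages**: subjects
  missing any of the table's genotypes are dropped from counts and ORs,
  but percentages are displayed over the full group sizes — that is the
  arithmetic behind the published percentages (e.g. 12/116 = 10.3%, not
  12/111), and the two conventions are intentionally distinct.
- **min_count**: the publications print only a subset of the possible
  combinations without stating a rule. Our explicit stand-in: strata with
  any compared count below `min_count` (default 4) keep their counts but
  get no estimate, and are never silently dropped. The default is a
  compromise — the smallest stratum granted an OR in the published tables
  has a count of 2, so exact table reproduction passes `min_count` of 1–3
  explicitly.

`risk_ladder()` sorts estimable strata by OR and warns (not errors) when
the ordering disagrees with total risk-allele dose: non-monotone ladders
are real data behavior at these sample sizes.

## Multiplicative polygenic model

Assumptions, stated plainly: loci are independent (linkage equilibrium),
in HWE, with multiplicative per-allele effects; per-allele odds ratios
stand in for relative risks (rare-disease approximation — inputs above 3
are flagged); and the aggregate of unmodelled polygenic risk is log-normal.

Under these assumptions the locus contribution to Var(ln R) is
`2·p(1−p)·(ln RR)²` (`locus_variance()`). A familial relative risk λ > 1
anchors the total: first-degree relatives share half the log-risk
variance, so `V_total = 2·ln λ` and the fraction of familial risk
explained is the ratio (`fraction_explained()`, capped at 1 with a
warning). **λ is a required user input and is never hard-coded**: the
motivating study's λ and exact allele frequencies live in a supplement
that is not available, so its headline "six variants explain 32% of the
genetic risk" is a documentation target here, not an asserted number. The
tests instead pin the mechanism: with the six published per-allele ORs and
frequencies backed out of the published control genotype counts, the λ
implied by a 32% fraction is ≈1.42 — comfortably inside the reported
familial-relative-risk range for gastric cancer — and the model returns
0.32 at that λ.

Risk percentiles use the mean-one convention `ln R ~ N(−V/2, V)`, so
"relative risk" statements are against the population average, while
`risk_percentile_ratio(V, q) = exp(z_q·√V)` is reported against the
median — the two normalizations are documented separately on purpose.
`screening_benefit()` integrates the risk-weighted normal density over the
upper tail (adaptive quadrature, absolute tolerance 1e-9, with the
exponentials fused so the integrand underflows rather than overflows) to
get the share of all cases arising in the screened top fraction; the
absolute risk averted multiplies that share by the baseline risk and the
assumed screening risk reduction (default 0.40, the gastroscopy
assumption). A seeded 10⁶-draw Monte-Carlo oracle and the closed form
Φ(√V − z₁₋f) validate the quadrature in the tests.

## Synthetic cohorts: what they emulate, and what they do not

`generate_cohort()` exists so every stage is testable without restricted
individual-level data. The generative world mirrors the motivating study's
composition: 65 hereditary-background cases, 51 sporadic cases, 102
controls; ~60% male; ages 25–49 with ~40% in the ≤40 band; case
location/Lauren distributions as published; 2% genotype missingness
(completely at random), which lands pairwise complete-case totals a few
percent below enrolment as in the published tables. Risk-allele
frequencies are backed out of the published control genotype counts
(0.83, 0.07, 0.30, 0.16, 0.33, 0.21); per-allele effects use the published
all-case ORs, with the hereditary-subgroup ORs as that subgroup's
generative truth — *illustrative*, because subgroup-specific effects are
not identifiable from the publication.

Mechanics: genotypes are drawn per-locus under HWE in linkage
equilibrium; each candidate's disease probability is
`plogis(baseline_logit + Σ dose·ln OR + sex/age terms)`; cases are
accepted with probability p and controls with 1−p. Sampling controls as
*disease-free* members of the population (rather than unconditionally) is
a deliberate choice: retrospective sampling from a logistic disease model
then leaves the dose coefficient exactly equal to the configured ln OR,
making parameter recovery a sharp test at any baseline. When all ORs are
1 the acceptance probability is constant, so controls are exactly HWE
draws and the HWE calibration tests apply unchanged. The default baseline
is `qlogis(0.01)` — a rare early-onset outcome; rejection sampling aborts
with guidance if the configured world makes acceptance vanish.

What a green test therefore does **not** establish: robustness to linkage
disequilibrium between panel SNPs (the motivating panel treats its loci as
independent; one known LD pair is represented by a single proxy),
population stratification, informative missingness, or genotyping error —
none of which the generator emulates.

## Numerical and degenerate-input conventions

- Genotype strings are unphased and order-insensitive; heterozygotes are
  normalized alphabetically on construction.
- Risk-allele assignment: minor-in-controls by default; an exact 0.5
  control frequency breaks the tie toward the alphabetically smaller
  allele with a warning; a fixed map always wins.
- Complete-case deletion is per analysis (each table uses the subjects
  complete for the SNPs it touches) and the effective N is always
  reported.
- Presentation rounding (OR 2 dp, p 4 dp, percentages 1 dp, significance
  markers at 0.05/0.01/0.001) is applied only at output; the pipeline's
  JSON sidecar carries unrounded values, and re-rounding the sidecar
  reproduces the tables byte-for-byte. No multiplicity adjustment is
  applied to headline p-values (matching the source convention of a flat
  5% threshold); a Bonferroni column is emitted for information.
- All simulation entry points require a seed; the pipeline itself is
  deterministic given input and configuration.

## Known limitations

No VCF input, imputation, phasing or haplotype estimation; no conditional
logistic regression (the motivating design is frequency-matched, not
paired); no Fisher exact variant on the headline path; no estimation of λ
from pedigree data; screening arithmetic is a static yield calculation,
not a life-table model of absolute risk over time.
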