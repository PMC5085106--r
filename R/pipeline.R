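#' Analysis configuration for the full reporting pipeline
#'
#' @param input path to a cohort TSV (see [read_cohort()]) or a [cohort()]
#'   object.
#' @param snps SNP subset to analyze (default: the whole panel).
#' @param combination_sets list of character vectors of rs-ids, one per
#'   combined-genotype table.
#' @param combination_comparisons list of [comparison_design()]s applied to
#'   every combination table.
#' @param subgroup_factors factors for the stratified analysis (subset of
#'   sex, age-band, location, lauren).
#' @param covariates adjustment set for the per-allele comparisons.
#' @param lambda_familial optional familial relative risk; when supplied, a
#'   polygenic risk summary is produced from the crude per-allele ORs and
#'   control allele frequencies.
#' @param top_fraction,screening_reduction,baseline_risk screening-benefit
#'   parameters (see [screening_benefit()]).
#' @param alpha significance threshold (default 0.05).
#' @param min_count stratum-count filter for combination tables.
#' @param bonferroni also emit Bonferroni-adjusted p-values (default TRUE;
#'   informational only — the headline convention applies no multiplicity
#'   adjustment).
#' @param out_dir output directory (created if needed); `NULL` for no file
#'   output.
#' @return an `analysis_config` object.
#' @export
analysis_config <- function(input, snps = NULL,
                            combination_sets = list(),
                            combination_comparisons =
                              list(comparison_design("all-cases",
                                                     "controls")),
                            subgroup_factors = c("sex", "age-band",
                                                 "location", "lauren"),
                            covariates = c("sex", "age"),
                            lambda_familial = NULL,
                            top_fraction = 0.10,
                            screening_reduction = 0.40,
                            baseline_risk = 0.01,
                            alpha = 0.05, min_count = 4L,
                            bonferroni = TRUE, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(
    list(input = input, snps = snps, combination_sets = combination_sets,
         combination_comparisons = combination_comparisons,
         subgroup_factors = subgroup_factors, covariates = covariates,
         lambda_familial = lambda_familial, top_fraction = top_fraction,
         screening_reduction = screening_reduction,
         baseline_risk = baseline_risk, alpha = alpha,
         min_count = as.integer(min_count), bonferroni = bonferroni,
         out_dir = out_dir),
    class = "analysis_config")
}

#' Run the full association + polygenic reporting pipeline
#'
#' Produces the publication-style tables: per-allele odds ratios for the
#' three standard comparisons, the subgroup grid, one combined-genotype
#' table per requested SNP set, and (when a familial relative risk is
#' supplied) the polygenic risk summary. Presentation rounding (ORs to 2
#' decimals, p-values to 4) is applied only when writing; the JSON sidecar
#' carries every number unrounded, so the pipeline is byte-deterministic
#' given (input, config).
#'
#' @param cfg an [analysis_config()].
#' @return a report bundle (list with `per_allele`, `subgroups`,
#'   `combinations`, `risk_model`, `missingness`, `log`), invisibly when
#'   files are written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  ds <- if (inherits(cfg$input, "cohort")) cfg$input else
    read_cohort(cfg$input)
  snps <- cfg$snps %||% ds$snps$rs_id
  unknown <- setdiff(snps, ds$snps$rs_id)
  if (length(unknown)) {
    stop("pipeline: configured SNP(s) not in input: ",
         paste(unknown, collapse = ", "))
  }
  if (!length(snps)) stop("pipeline: empty SNP panel")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  per_allele <- stage("per-allele comparisons", {
    do.call(rbind, lapply(snps, function(rs) {
      res <- run_comparisons(ds, rs, model = "allelic",
                             covariates = cfg$covariates)
      cbind(rs_id = rs, assoc_table(res))
    }))
  })
  if (cfg$bonferroni) {
    per_allele$p_bonferroni <- pmin(1, per_allele$p_value *
                                      sum(!is.na(per_allele$p_value)))
  }

  subgroups <- stage("subgroup analysis", {
    do.call(rbind, lapply(snps, function(rs) {
      do.call(rbind, lapply(cfg$subgroup_factors, function(f) {
        res <- subgroup_analysis(ds, rs, factor = f)
        cbind(rs_id = rs, factor = f, level = names(res), assoc_table(res))
      }))
    }))
  })

  combinations <- stage("combined-genotype tables", {
    lapply(cfg$combination_sets, function(set) {
      combine(ds, set, comparisons = cfg$combination_comparisons,
              min_count = cfg$min_count)
    })
  })
  names(combinations) <- vapply(cfg$combination_sets, paste,
                                character(1), collapse = "+")

  risk_model <- if (!is.null(cfg$lambda_familial)) {
    stage("polygenic risk model", {
      crude <- per_allele[per_allele$label == "cases_vs_controls", ]
      ctrl <- subset_cohort(ds, ds$subjects$status == "control")
      freqs <- vapply(snps, function(rs) {
        d <- snp_doses(ctrl, rs)
        mean(d, na.rm = TRUE) / 2
      }, numeric(1))
      eff <- locus_effects(snps, freqs, crude$or[match(snps, crude$rs_id)])
      spec <- polygenic_model_spec(eff, cfg$lambda_familial,
                                   cfg$screening_reduction)
      V <- sum(locus_variance(eff$p_risk, eff$rr))
      sb <- screening_benefit(V, cfg$top_fraction,
                              cfg$screening_reduction, cfg$baseline_risk)
      list(effects = eff, lambda_familial = cfg$lambda_familial,
           explained_variance = V,
           fraction_explained = fraction_explained(spec),
           top_decile_rr = risk_percentile_ratio(V, 0.9),
           screening = sb)
    })
  } else NULL

  log <- list(
    package_version = as.character(utils::packageVersion("polyassoc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_subjects = nrow(ds$subjects),
    snps = snps,
    config_hash = config_hash(cfg),
    timestamp = NA_character_  # deliberately unset: outputs are
                               # byte-deterministic given (input, config)
  )
  bundle <- list(per_allele = per_allele, subgroups = subgroups,
                 combinations = combinations, risk_model = risk_model,
                 missingness = missingness(ds), log = log)
  if (!is.null(cfg$out_dir)) {
    write_bundle(bundle, cfg)
    return(invisible(bundle))
  }
  bundle
}

config_hash <- function(cfg) {
  plain <- unclass(cfg)
  plain$out_dir <- NULL  # hash the analytic config, not output locations
  plain <- rapply(plain, function(x) {
    if (inherits(x, "cohort")) "<cohort>" else x
  }, how = "replace")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(bundle, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$out_dir, name)
  utils::write.table(round_assoc(bundle$per_allele, cfg$alpha),
                     out("per_allele.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round_assoc(bundle$subgroups, cfg$alpha),
                     out("subgroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$combinations)) {
    tab <- as.data.frame(bundle$combinations[[nm]])
    tab$pct_group1 <- round(tab$pct_group1, 1)
    tab$pct_group2 <- round(tab$pct_group2, 1)
    tab <- round_assoc(tab, cfg$alpha)
    utils::write.table(
      tab, out(paste0("combination_", gsub("[^A-Za-z0-9+]", "_", nm), ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sidecar <- bundle
  sidecar$combinations <- lapply(bundle$combinations, as.data.frame)
  jsonlite::write_json(sidecar, out("report.json"), auto_unbox = TRUE,
                       force = TRUE, digits = NA, na = "null")
  invisible(NULL)
}

# Presentation rounding: OR/CI 2 dp, p-values 4 dp, significance markers.
round_assoc <- function(tab, alpha = 0.05) {
  for (col in intersect(c("or", "ci_low", "ci_high", "fold_increase"),
                        names(tab))) {
    tab[[col]] <- round(tab[[col]], 2)
  }
  for (col in intersect(c("p_value", "p_bonferroni"), names(tab))) {
    tab[[col]] <- round(tab[[col]], 4)
  }
  if ("p_value" %in% names(tab)) {
    tab$signif <- significance_marker(tab$p_value)
  }
  tab
}

#' Significance markers for table footnotes
#'
#' `*` for p < 0.05, dagger for p < 0.01, double dagger for p < 0.001
#' (ASCII: "*", "+", "++").
#'
#' @param p numeric p-values.
#' @return character vector of markers ("" when not significant).
#' @export
significance_marker <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "+"
  out[!is.na(p) & p < 0.001] <- "++"
  out
}
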