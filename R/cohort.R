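#' Construct a case-control cohort dataset
#'
#' The single container all analyses consume: a subject table, a SNP panel,
#' and a subject-by-SNP genotype matrix of unphased two-letter genotype
#' strings. Heterozygotes are normalized to alphabetical allele order on
#' construction ("GA" becomes "AG"), so genotype strings are
#' order-insensitive. Missing genotypes are `NA`.
#'
#' @param subjects data frame with columns `id` (unique), `status`
#'   ("case"/"control"), `sex` ("male"/"female"), `age` (whole years,
#'   `NA` allowed), `hereditary` (logical; `NA` for controls), `location`
#'   ("cardia"/"noncardia"/"unknown"; controls must be "unknown"), `lauren`
#'   ("intestinal"/"diffuse"/"mixed"/"unknown"; controls must be "unknown").
#' @param genotypes character matrix, `nrow(subjects)` x `nrow(snps)`,
#'   entries two-letter genotype strings of each SNP's alleles, or `NA`.
#' @param snps a [snp_panel()].
#' @param age_max exclusive upper bound of the age-inclusion window
#'   (default 50, the early-onset criterion). Non-missing ages at or above
#'   it are a validation error.
#' @return A `cohort` object (list with elements `subjects`, `snps`,
#'   `genotypes`).
#' @seealso [read_cohort()], [write_cohort()], [dose_matrix()]
#' @export
cohort <- function(subjects, genotypes, snps = gc_snp_panel(), age_max = 50) {
  snps <- validate_snp_panel(snps)
  subjects <- validate_subjects(subjects, age_max = age_max)
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(subjects) || ncol(genotypes) != nrow(snps)) {
    stop(sprintf(
      "genotype matrix is %d x %d but cohort has %d subjects and %d SNPs",
      nrow(genotypes), ncol(genotypes), nrow(subjects), nrow(snps)))
  }
  rownames(genotypes) <- subjects$id
  colnames(genotypes) <- snps$rs_id
  genotypes <- normalize_genotypes(genotypes, snps, subjects$id)
  structure(
    list(subjects = subjects, snps = snps, genotypes = genotypes),
    class = "cohort"
  )
}

validate_subjects <- function(subjects, age_max = 50) {
  stopifnot(is.data.frame(subjects))
  needed <- c("id", "status", "sex", "age", "hereditary", "location", "lauren")
  missing_cols <- setdiff(needed, names(subjects))
  if (length(missing_cols)) {
    stop("subjects table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  subjects <- as.data.frame(subjects[needed], stringsAsFactors = FALSE)
  subjects$id <- as.character(subjects$id)
  if (anyDuplicated(subjects$id)) {
    stop("duplicate subject id: ",
         paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "))
  }
  chk_levels <- function(x, levels, what) {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                   paste(unique(x[bad]), collapse = ", "),
                   paste(levels, collapse = ", ")))
    }
    x
  }
  subjects$status <- chk_levels(subjects$status, c("case", "control"), "status")
  if (anyNA(subjects$status)) stop("status may not be missing")
  subjects$sex <- chk_levels(subjects$sex, c("male", "female"), "sex")
  subjects$age <- as.integer(subjects$age)
  bad_age <- !is.na(subjects$age) &
    (subjects$age < 0 | subjects$age >= age_max)
  if (any(bad_age)) {
    stop("age outside the inclusion window [0, ", age_max, ") for subject(s): ",
         paste(subjects$id[bad_age], collapse = ", "))
  }
  subjects$hereditary <- as.logical(subjects$hereditary)
  subjects$location <- chk_levels(
    subjects$location, c("cardia", "noncardia", "unknown"), "location")
  subjects$lauren <- chk_levels(
    subjects$lauren, c("intestinal", "diffuse", "mixed", "unknown"), "lauren")
  is_ctrl <- subjects$status == "control"
  # tumour fields and family history are undefined for controls
  subjects$location[is_ctrl & is.na(subjects$location)] <- "unknown"
  subjects$lauren[is_ctrl & is.na(subjects$lauren)] <- "unknown"
  if (any(is_ctrl & (subjects$location != "unknown" |
                     subjects$lauren != "unknown"))) {
    stop("controls must have location and lauren 'unknown'")
  }
  if (any(is_ctrl & !is.na(subjects$hereditary))) {
    stop("hereditary background is not recorded for controls (use NA)")
  }
  subjects$location[is.na(subjects$location)] <- "unknown"
  subjects$lauren[is.na(subjects$lauren)] <- "unknown"
  rownames(subjects) <- NULL
  subjects
}

# Normalize genotype strings to sorted allele order and validate alleles.
normalize_genotypes <- function(genotypes, snps, ids) {
  miss_codes <- c("00", "NN", "--", "")
  for (j in seq_len(nrow(snps))) {
    g <- toupper(as.character(genotypes[, j]))
    g[g %in% miss_codes] <- NA_character_
    ok <- !is.na(g)
    if (any(nchar(g[ok]) != 2L)) {
      bad <- which(ok & nchar(g) != 2L)[1]
      stop(sprintf("malformed genotype '%s' for subject %s at %s",
                   g[bad], ids[bad], snps$rs_id[j]))
    }
    a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
    alleles <- c(snps$allele_a[j], snps$allele_b[j])
    bad <- ok & (!(a1 %in% alleles) | !(a2 %in% alleles))
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "genotype '%s' for subject %s uses allele(s) not defined for %s (%s/%s)",
        g[i], ids[i], snps$rs_id[j], alleles[1], alleles[2]))
    }
    swap <- ok & a1 > a2
    g[swap] <- paste0(a2[swap], a1[swap])
    genotypes[, j] <- g
  }
  genotypes
}

#' @export
print.cohort <- function(x, ...) {
  n_case <- sum(x$subjects$status == "case")
  n_ctrl <- sum(x$subjects$status == "control")
  n_hered <- sum(x$subjects$hereditary %in% TRUE)
  cat(sprintf(
    "<cohort> %d cases (%d with hereditary background), %d controls, %d SNPs\n",
    n_case, n_hered, n_ctrl, nrow(x$snps)))
  miss <- missingness(x)
  cat("per-SNP missingness: ",
      paste(sprintf("%s %.1f%%", miss$rs_id, 100 * miss$missing_rate),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-SNP missingness report
#'
#' @param ds a [cohort()].
#' @return data frame with `rs_id`, `n_missing`, `n_complete`,
#'   `missing_rate`.
#' @export
missingness <- function(ds) {
  stopifnot(inherits(ds, "cohort"))
  n_missing <- colSums(is.na(ds$genotypes))
  data.frame(
    rs_id = ds$snps$rs_id,
    n_missing = as.integer(n_missing),
    n_complete = nrow(ds$genotypes) - as.integer(n_missing),
    missing_rate = n_missing / nrow(ds$genotypes),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select subjects of a cohort
#'
#' @param ds a [cohort()].
#' @param keep logical or integer index over subjects.
#' @return the subsetted [cohort()].
#' @export
subset_cohort <- function(ds, keep) {
  stopifnot(inherits(ds, "cohort"))
  sub <- ds$subjects[keep, , drop = FALSE]
  rownames(sub) <- NULL
  structure(
    list(subjects = sub, snps = ds$snps,
         genotypes = ds$genotypes[keep, , drop = FALSE]),
    class = "cohort"
  )
}
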