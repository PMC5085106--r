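#' Read a cohort from disk
#'
#' Two dialects are supported. The canonical TSV has one row per subject and
#' columns `id`, `status` (case/control), `sex` (M/F), `age`, `hereditary`
#' (1/0/NA), `location` (cardia/noncardia/unknown/NA), `lauren`
#' (intestinal/diffuse/mixed/unknown/NA), followed by one two-letter
#' genotype column per rs-id in the panel ("00", "NN" or empty for
#' missing). The PLINK-style `ped-map` dialect reads a whitespace-delimited
#' `.ped` (famid, id, pat, mat, sex with 1=male/2=female, phenotype with
#' 1=control/2=case, then two allele columns per SNP, "0" = missing) plus a
#' `.map` (chrom, rs-id, cM, bp); the extra phenotype columns can be
#' supplied in a side-car TSV with columns `id`, `age`, `hereditary`,
#' `location`, `lauren`.
#'
#' @param path file path. For `ped-map`, either the `.ped` file or the
#'   common prefix of the `.ped`/`.map` pair.
#' @param format `"tsv"` or `"ped-map"`.
#' @param snps the [snp_panel()] the genotype columns refer to, or `NULL`
#'   to infer the panel: TSV genotype columns matching the default
#'   six-SNP panel use its locus definitions; other columns get their
#'   alleles from the observed genotypes with the risk allele left unset.
#' @param sidecar optional side-car phenotype TSV path (ped-map only).
#' @param age_max exclusive age-window bound, passed to [cohort()].
#' @return A validated [cohort()].
#' @export
read_cohort <- function(path, format = c("tsv", "ped-map"),
                        snps = NULL, sidecar = NULL, age_max = 50) {
  format <- match.arg(format)
  if (!is.null(snps)) snps <- validate_snp_panel(snps)
  if (format == "tsv") {
    read_cohort_tsv(path, snps, age_max)
  } else {
    read_cohort_pedmap(path, snps, sidecar, age_max)
  }
}

read_cohort_tsv <- function(path, snps, age_max) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, na.strings = c("NA", ""))
  pheno_cols <- c("id", "status", "sex", "age", "hereditary",
                  "location", "lauren")
  if (is.null(snps)) snps <- infer_panel(raw, pheno_cols)
  missing_cols <- setdiff(c(pheno_cols, snps$rs_id), names(raw))
  if (length(missing_cols)) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n_bad <- which(is.na(raw$id) | is.na(raw$status))
  if (length(n_bad)) {
    stop("malformed row at line ", n_bad[1] + 1L, " of ", path,
         " (missing id or status)")
  }
  subjects <- data.frame(
    id = raw$id,
    status = raw$status,
    sex = c(M = "male", F = "female", male = "male", female = "female")[raw$sex],
    age = suppressWarnings(as.integer(raw$age)),
    hereditary = as.logical(suppressWarnings(as.integer(raw$hereditary))),
    location = raw$location,
    lauren = raw$lauren,
    stringsAsFactors = FALSE
  )
  genotypes <- as.matrix(raw[, snps$rs_id, drop = FALSE])
  cohort(subjects, genotypes, snps, age_max = age_max)
}

# Infer a panel from a TSV's genotype columns: known rs-ids reuse the
# default panel's locus definitions, others take their alleles from data.
infer_panel <- function(raw, pheno_cols) {
  geno_cols <- setdiff(names(raw), pheno_cols)
  if (!length(geno_cols)) stop("input has no genotype columns")
  gc <- gc_snp_panel()
  rows <- lapply(geno_cols, function(rs) {
    j <- match(rs, gc$rs_id)
    if (!is.na(j)) return(gc[j, , drop = FALSE])
    g <- toupper(raw[[rs]])
    g <- g[!is.na(g) & !(g %in% c("00", "NN", "--", ""))]
    alleles <- sort(unique(strsplit(paste(g, collapse = ""), "")[[1]]))
    if (length(alleles) != 2L) {
      stop("cannot infer alleles for column '", rs,
           "' (observed: ", paste(alleles, collapse = "/"),
           "); supply a snp_panel()")
    }
    data.frame(rs_id = rs, gene_label = rs, allele_a = alleles[1],
               allele_b = alleles[2], risk_allele = NA_character_,
               stringsAsFactors = FALSE)
  })
  validate_snp_panel(do.call(rbind, rows))
}

read_cohort_pedmap <- function(path, snps, sidecar, age_max) {
  if (is.null(snps)) snps <- gc_snp_panel()
  prefix <- sub("\\.ped$", "", path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character",
                           col.names = c("chrom", "rs_id", "cm", "bp"))
  unknown <- setdiff(map$rs_id, snps$rs_id)
  if (length(unknown)) {
    stop("map file lists SNP(s) not in the panel: ",
         paste(unknown, collapse = ", "))
  }
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  n_geno_cols <- 2L * nrow(map)
  if (ncol(ped) != 6L + n_geno_cols) {
    stop(sprintf("ped file has %d columns; expected 6 + %d allele columns",
                 ncol(ped), n_geno_cols))
  }
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(nrow(map)) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(nrow(map)), drop = FALSE])
  g <- matrix(paste0(a1, a2), nrow = nrow(ped))
  g[a1 == "0" | a2 == "0"] <- NA_character_
  colnames(g) <- map$rs_id
  # panel SNPs absent from the map are all-missing
  genotypes <- matrix(NA_character_, nrow(ped), nrow(snps),
                      dimnames = list(NULL, snps$rs_id))
  genotypes[, map$rs_id] <- g
  subjects <- data.frame(
    id = ped[[2]],
    status = c("1" = "control", "2" = "case")[ped[[6]]],
    sex = c("1" = "male", "2" = "female")[ped[[5]]],
    age = NA_integer_,
    hereditary = NA,
    location = NA_character_,
    lauren = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(sidecar)) {
    side <- utils::read.delim(sidecar, header = TRUE, sep = "\t",
                              colClasses = "character",
                              na.strings = c("NA", ""))
    idx <- match(subjects$id, side$id)
    if (anyNA(idx)) {
      stop("side-car TSV lacks subject(s): ",
           paste(subjects$id[is.na(idx)], collapse = ", "))
    }
    subjects$age <- suppressWarnings(as.integer(side$age[idx]))
    subjects$hereditary <-
      as.logical(suppressWarnings(as.integer(side$hereditary[idx])))
    subjects$location <- side$location[idx]
    subjects$lauren <- side$lauren[idx]
  }
  is_case <- subjects$status %in% "case"
  subjects$hereditary[!is_case] <- NA
  cohort(subjects, genotypes, snps, age_max = age_max)
}

#' Write a cohort to the canonical TSV format
#'
#' Inverse of [read_cohort()] (format `"tsv"`): `read_cohort(write_cohort(ds))`
#' reproduces `ds` up to genotype allele-order normalization.
#'
#' @param ds a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ds, path) {
  stopifnot(inherits(ds, "cohort"))
  out <- data.frame(
    id = ds$subjects$id,
    status = ds$subjects$status,
    sex = c(male = "M", female = "F")[ds$subjects$sex],
    age = ds$subjects$age,
    hereditary = as.integer(ds$subjects$hereditary),
    location = ds$subjects$location,
    lauren = ds$subjects$lauren,
    stringsAsFactors = FALSE
  )
  geno <- ds$genotypes
  geno[is.na(geno)] <- "00"
  out <- cbind(out, as.data.frame(geno, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
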