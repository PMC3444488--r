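## Domain containers and phenotype derivation for the resequencing cohort.
##
## A cohort is represented at one of two levels:
##   * subject level: a genotype_matrix (per-subject minor-allele dosages) plus
##     a subject table with phenotypes and covariates;
##   * count level: a long table of per-site, per-group minor-allele counts
##     n over sequenced chromosomes N, as printed in resequencing reports.

POPULATIONS <- c("AA", "EA")
REGIONS     <- c("5UTR", "CDS", "3UTR")
BMI_CLASSES <- c("UNDERWEIGHT", "NORMAL", "OVERWEIGHT", "OBESE")
SD_TRAITS   <- c("sd", "ad", "cd", "od", "mjd")

#' Assign population from model-based ancestry proportion
#'
#' Subjects with African ancestry proportion of at least 0.50 are grouped as
#' African American (AA); all others as European American (EA). Ties at
#' exactly 0.50 go to AA.
#'
#' @param ancestry_prop numeric vector of African ancestry proportions in
#'   \[0, 1\].
#' @return factor with levels `AA`, `EA`.
#' @export
#' @examples
#' assign_population(c(0.97, 0.50, 0.49))
assign_population <- function(ancestry_prop) {
  if (!is.numeric(ancestry_prop) || anyNA(ancestry_prop))
    stop_ctx("ancestry_prop must be numeric with no missing values")
  if (any(ancestry_prop < 0 | ancestry_prop > 1))
    stop_ctx("ancestry_prop out of [0, 1]: %s",
             paste(ancestry_prop[ancestry_prop < 0 | ancestry_prop > 1],
                   collapse = ", "))
  factor(ifelse(ancestry_prop >= 0.50, "AA", "EA"), levels = POPULATIONS)
}

#' Classify BMI into WHO categories
#'
#' Underweight below 18.5, normal weight 18.5 to below 25, overweight 25 to
#' below 30, obese 30 and above (kg/m^2). Intervals are half-open \[lo, hi);
#' the conventional 24.9/29.9 upper bounds are display conventions.
#'
#' @param bmi numeric vector of BMI values (kg/m^2), strictly positive.
#' @return factor with levels `UNDERWEIGHT`, `NORMAL`, `OVERWEIGHT`, `OBESE`.
#' @export
#' @examples
#' classify_bmi(c(18.4, 22.4, 27.1, 35.5))
classify_bmi <- function(bmi) {
  if (!is.numeric(bmi) || anyNA(bmi)) stop_ctx("bmi must be numeric, non-missing")
  if (any(bmi <= 0)) stop_ctx("bmi must be positive")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), labels = BMI_CLASSES,
      right = FALSE)
}

#' Derive substance-dependence case status
#'
#' A subject is an SD case if affected with alcohol, cocaine, opioid and/or
#' marijuana dependence. Unaffected subjects are controls only if screened;
#' unaffected, unscreened subjects are excluded from case-control contrasts.
#'
#' @param subjects data frame with logical (or 0/1) columns `ad`, `cd`, `od`,
#'   `mjd` and `screened`.
#' @return `subjects` with columns `sd_case` (logical) and `status` (factor
#'   `case`/`control`/`excluded`) added.
#' @export
derive_sd_status <- function(subjects) {
  need <- c("ad", "cd", "od", "mjd", "screened")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop_ctx("missing diagnosis columns: %s",
                             paste(miss, collapse = ", "))
  flags <- lapply(subjects[need], function(x) {
    if (anyNA(x)) stop_ctx("diagnosis flags must not be missing")
    as.logical(x)
  })
  sd_case <- flags$ad | flags$cd | flags$od | flags$mjd
  if (any(sd_case & flags$screened))
    stop_ctx("subjects labelled both SD case and screened control: %s",
             paste(subjects$subject_id[sd_case & flags$screened], collapse = ", "))
  subjects$sd_case <- sd_case
  subjects$status <- factor(
    ifelse(sd_case, "case", ifelse(flags$screened, "control", "excluded")),
    levels = c("case", "control", "excluded"))
  subjects
}

#' Construct a genotype matrix
#'
#' @param sites data frame with at least `site_id`, `exon`, `region`, `dbsnp`
#'   (NA when the variant is novel); optionally `effect`, `segment`, `pos`,
#'   `ref`, `alt`.
#' @param calls integer matrix, subjects x sites, of minor-allele dosages in
#'   `{0, 1, 2}` with `NA` for failed calls. For indel sites the dosage counts
#'   insertion alleles. Row names are subject ids; column order must match
#'   `sites$site_id`.
#' @param population optional factor/character of per-subject populations.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls, population = NULL) {
  sites <- validate_sites(sites)
  calls <- as.matrix(calls)
  if (ncol(calls) != nrow(sites))
    stop_ctx("calls has %d columns but sites has %d rows", ncol(calls), nrow(sites))
  if (is.null(colnames(calls))) colnames(calls) <- sites$site_id
  if (!identical(colnames(calls), sites$site_id))
    stop_ctx("calls column names do not match sites$site_id")
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%04d", seq_len(nrow(calls)))
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop_ctx("dosages must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  if (!is.null(population)) {
    stopifnot(length(population) == nrow(calls))
    population <- factor(as.character(population), levels = POPULATIONS)
  }
  structure(list(sites = sites, calls = calls, population = population),
            class = "genotype_matrix")
}

validate_sites <- function(sites) {
  need <- c("site_id", "exon", "region")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop_ctx("sites lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sites$site_id))
    stop_ctx("duplicate site ids: %s",
             paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  if (!all(sites$region %in% REGIONS))
    stop_ctx("region must be one of %s", paste(REGIONS, collapse = "/"))
  if (!all(sites$exon %in% 1:4)) stop_ctx("exon must be in 1..4")
  if (is.null(sites$dbsnp)) sites$dbsnp <- NA_character_
  sites$dbsnp[sites$dbsnp %in% c(".", "")] <- NA_character_
  sites$novel <- is.na(sites$dbsnp)
  rownames(sites) <- NULL
  sites
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d sites (%.1f%% missing calls)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Count minor alleles for one site in a subject group
#'
#' Each subject carries two copies of the chromosome, so the total `n_total`
#' is twice the number of group subjects with a non-missing call at the site;
#' subjects whose sequencing failed at the site contribute to neither count
#' (per-site, not listwise, exclusion).
#'
#' @param genotypes a [genotype_matrix()].
#' @param site_id a site identifier present in `genotypes$sites`.
#' @param subset logical vector, integer indices or subject ids selecting the
#'   group; defaults to all subjects.
#' @param group_id label stored in the result.
#' @return one-row data frame with `site_id`, `group_id`, `n_minor`,
#'   `n_total`, `freq` (NA when `n_total` is 0, a degenerate group) and
#'   `degenerate`.
#' @export
count_alleles <- function(genotypes, site_id, subset = NULL, group_id = "all") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!site_id %in% genotypes$sites$site_id)
    stop_ctx("unknown site: %s", site_id)
  calls <- genotypes$calls[, site_id]
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- match(subset, rownames(genotypes$calls))
    calls <- calls[subset]
  }
  ok <- !is.na(calls)
  n_total <- 2L * sum(ok)
  n_minor <- as.integer(sum(calls[ok]))
  data.frame(site_id = site_id, group_id = group_id,
             n_minor = n_minor, n_total = n_total,
             freq = if (n_total > 0) n_minor / n_total else NA_real_,
             degenerate = n_total == 0L)
}

#' Build the per-site, per-group count table from genotypes
#'
#' @param genotypes a [genotype_matrix()].
#' @param groups named list of subject selectors (logical vectors or ids), one
#'   per analysis group.
#' @return long data frame with one row per site x group.
#' @export
counts_from_genotypes <- function(genotypes, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(genotypes$sites$site_id, function(s)
      count_alleles(genotypes, s, groups[[g]], group_id = g)))
  }))
  rownames(out) <- NULL
  out
}

#' Pooled minor allele frequency
#'
#' Pools counts over groups: sum of minor alleles over sum of sequenced
#' chromosomes. Full precision is kept; report tables round to three decimals.
#'
#' @param counts data frame with columns `n_minor`, `n_total` (e.g. rows of a
#'   count table for one site across groups).
#' @return numeric frequency.
#' @export
#' @examples
#' compute_maf(data.frame(n_minor = c(66, 16), n_total = c(258, 242)))
compute_maf <- function(counts) {
  stopifnot(all(c("n_minor", "n_total") %in% names(counts)))
  tot <- sum(counts$n_total)
  if (tot <= 0) stop_ctx("zero total chromosomes: MAF undefined")
  sum(counts$n_minor) / tot
}

#' Carrier counts under the heterozygote assumption
#'
#' For rare variants essentially all carriers are heterozygous, so the number
#' of carriers of a site equals its total minor-allele count across groups.
#'
#' @param counts long count table (site_id, group_id, n_minor, n_total).
#' @param site_id optional site filter.
#' @return data frame with `site_id` and `carriers`.
#' @export
carrier_counts <- function(counts, site_id = NULL) {
  if (!is.null(site_id)) counts <- counts[counts$site_id %in% site_id, ]
  agg <- aggregate(n_minor ~ site_id, counts, sum)
  names(agg)[2] <- "carriers"
  agg[order(match(agg$site_id, unique(counts$site_id))), , drop = FALSE]
}

#' Assemble a cohort study
#'
#' @param genotypes a [genotype_matrix()] or NULL.
#' @param subjects subject table (see [load_phenotypes()]) or NULL.
#' @param counts long count table; when NULL and subject-level data are given
#'   it is derived from the genotypes via the four population x SD groups.
#' @param provenance `"SUBJECT_LEVEL"` or `"COUNT_ONLY"`.
#' @param group_n named vector of subject counts per group (count-only
#'   studies).
#' @return object of class `cohort_study`.
#' @export
cohort_study <- function(genotypes = NULL, subjects = NULL, counts = NULL,
                         provenance = c("SUBJECT_LEVEL", "COUNT_ONLY"),
                         group_n = NULL) {
  provenance <- match.arg(provenance)
  if (provenance == "SUBJECT_LEVEL") {
    stopifnot(inherits(genotypes, "genotype_matrix"), is.data.frame(subjects))
    if (nrow(subjects) != nrow(genotypes$calls))
      stop_ctx("subjects (%d) and genotype rows (%d) differ",
               nrow(subjects), nrow(genotypes$calls))
    if (!identical(subjects$subject_id, rownames(genotypes$calls)))
      stop_ctx("subject ids do not match genotype row names")
    if (is.null(counts))
      counts <- counts_from_genotypes(genotypes, study_groups(subjects))
    if (is.null(group_n)) {
      g <- study_groups(subjects)
      group_n <- vapply(g, sum, 0L)
    }
  } else {
    stopifnot(is.data.frame(counts))
  }
  structure(list(genotypes = genotypes, subjects = subjects, counts = counts,
                 provenance = provenance, group_n = group_n),
            class = "cohort_study")
}

## Standard four analysis groups (population x SD status) as logical selectors.
study_groups <- function(subjects) {
  grp <- list(
    aa_case = subjects$population == "AA" & subjects$status == "case",
    aa_ctrl = subjects$population == "AA" & subjects$status == "control",
    ea_case = subjects$population == "EA" & subjects$status == "case",
    ea_ctrl = subjects$population == "EA" & subjects$status == "control")
  lapply(grp, function(x) x & !is.na(x))
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("cohort_study [%s]: %d sites", x$provenance,
              length(unique(x$counts$site_id))))
  if (!is.null(x$group_n))
    cat(", groups:", paste(names(x$group_n), x$group_n, sep = "=", collapse = " "))
  cat("\n")
  invisible(x)
}

## group_id -> population / stratum metadata used by burden and report code.
parse_group_id <- function(group_id) {
  pop <- toupper(sub("_.*$", "", group_id))
  stratum <- sub("^[^_]*_", "", group_id)
  data.frame(group_id = group_id, population = pop, stratum = stratum)
}
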