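## Readers and writers for the study's on-disk formats:
##   * phenotype table: TSV, one row per subject;
##   * genotypes: VCF v4.2 subset (biallelic SNV/indel, GT field, "./."
##     missing), parsed with vcfR; site metadata round-trips through INFO;
##   * variant count table: TSV mirror of a published-style per-variant
##     count table, with group sizes in a "# groups" header line.

PHENO_COLS <- c("subject_id", "sex", "age", "ancestry_prop",
                "ad", "cd", "od", "mjd", "screened", "bmi")

#' Load a subject phenotype table
#'
#' Expects a TSV with header `subject_id sex age ancestry_prop ad cd od mjd
#' screened bmi` (booleans as 0/1, sex as M/F). Population, SD case status
#' and WHO BMI class are derived on load.
#'
#' @param path file path.
#' @return data frame of subject records.
#' @export
load_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(PHENO_COLS, names(df))
  if (length(miss))
    stop_ctx("%s: missing phenotype columns: %s", path, paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning(sprintf("%s: empty phenotype file", path), call. = FALSE)
    return(df)
  }
  if (anyDuplicated(df$subject_id))
    stop_ctx("%s: duplicate subject ids (e.g. row %d)", path,
             which(duplicated(df$subject_id))[1])
  if (!all(df$sex %in% c("M", "F")))
    stop_ctx("%s: sex must be M/F (row %d)", path, which(!df$sex %in% c("M", "F"))[1])
  for (b in c("ad", "cd", "od", "mjd", "screened")) {
    if (!all(df[[b]] %in% c(0, 1)))
      stop_ctx("%s: column %s must be 0/1 (row %d)", path, b,
               which(!df[[b]] %in% c(0, 1))[1])
    df[[b]] <- as.logical(df[[b]])
  }
  if (!is.numeric(df$bmi) || any(is.na(df$bmi) | df$bmi <= 0))
    stop_ctx("%s: bmi must be positive and non-missing", path)
  df$sex <- factor(df$sex, levels = c("M", "F"))
  df$population <- assign_population(df$ancestry_prop)
  df <- derive_sd_status(df)
  df$bmi_class <- classify_bmi(df$bmi)
  df
}

#' Write a subject phenotype table
#'
#' Inverse of [load_phenotypes()]: only the on-disk columns are written, so a
#' write-then-read round trip reproduces the derived fields.
#'
#' @param subjects subject table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(subjects, path) {
  out <- subjects[, PHENO_COLS]
  for (b in c("ad", "cd", "od", "mjd", "screened")) out[[b]] <- as.integer(out[[b]])
  out$sex <- as.character(out$sex)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a VCF v4.2 file
#'
#' Minimal deterministic plain-text writer. Site metadata (exon, region,
#' amplicon segment, dbSNP id) is stored in INFO so that
#' [load_genotypes()] recovers the full site table. Sites without explicit
#' `pos`/`ref`/`alt` get synthetic coordinates on chromosome 2 and generic
#' alleles (the site labels are the identifiers; coordinates are placeholders,
#' no liftover is attempted).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path (plain `.vcf`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  sites <- genotypes$sites
  n_sites <- nrow(sites)
  if (is.null(sites$pos)) sites$pos <- 25383722L + 50L * seq_len(n_sites)
  if (is.null(sites$ref) || is.null(sites$alt)) {
    ins <- grepl("ins", sites$site_id)
    del <- grepl("del", sites$site_id)
    sites$ref <- ifelse(del, "CT", "C")
    sites$alt <- ifelse(ins, paste0("C", sub(".*ins", "", sites$site_id)),
                        ifelse(del, "C", "T"))
  }
  seg <- if (!is.null(sites$segment)) sites$segment else sites$exon
  info <- sprintf("EXON=%d;REGION=%s;SEGMENT=%s;DBSNP=%s", sites$exon,
                  sites$region, seg,
                  ifelse(is.na(sites$dbsnp), ".", sites$dbsnp))
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=pomcvar",
    "##INFO=<ID=EXON,Number=1,Type=Integer,Description=\"Exon number\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"5UTR/CDS/3UTR\">",
    "##INFO=<ID=SEGMENT,Number=1,Type=String,Description=\"Amplicon segment\">",
    "##INFO=<ID=DBSNP,Number=1,Type=String,Description=\"dbSNP id or .\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes$calls)), collapse = "\t"))
  body <- vapply(seq_len(n_sites), function(j) {
    d <- genotypes$calls[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c("2", sites$pos[j], sites$site_id[j], sites$ref[j], sites$alt[j],
            ".", "PASS", info[j], "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Load genotypes from a VCF file
#'
#' Reads a VCF v4.2 subset (biallelic records with a GT field; missing calls
#' as "./.") and returns minor-allele dosages, counting ALT alleles. For
#' indel records the insertion allele is the ALT allele, so its dosage counts
#' insertion copies.
#'
#' @param path VCF path.
#' @param subjects optional subject table; when given, VCF sample ids must
#'   match `subjects$subject_id` exactly.
#' @return a [genotype_matrix()].
#' @export
load_genotypes <- function(path, subjects = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_ctx("%s: no GT field", path)
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0(key, "=[^;]+"), fix$INFO))
    val <- rep(NA_character_, nrow(fix))
    val[grepl(paste0(key, "="), fix$INFO)] <- sub(paste0(key, "="), "", m)
    val
  }
  sites <- data.frame(
    site_id = fix$ID,
    exon = as.integer(info_field("EXON")),
    region = info_field("REGION"),
    segment = info_field("SEGMENT"),
    dbsnp = info_field("DBSNP"),
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    stringsAsFactors = FALSE)
  if (anyNA(sites$exon) || anyNA(sites$region))
    stop_ctx("%s: EXON/REGION INFO tags required on every record", path)
  dose <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L || !all(al %in% c("0", "1")))
      stop_ctx("unsupported genotype '%s' (biallelic diploid GT expected)", g)
    sum(al == "1")
  }
  calls <- t(apply(gt, 1L, function(row) vapply(row, dose, integer(1))))
  if (nrow(gt) == 1L) calls <- matrix(calls, ncol = ncol(gt),
                                      dimnames = list(NULL, colnames(gt)))
  calls <- t(calls)  # subjects x sites
  colnames(calls) <- sites$site_id
  if (!is.null(subjects)) {
    if (!identical(sort(rownames(calls)), sort(subjects$subject_id)))
      stop_ctx("%s: VCF samples do not match phenotype subject ids", path)
    calls <- calls[subjects$subject_id, , drop = FALSE]
  }
  pop <- if (!is.null(subjects)) subjects$population else NULL
  genotype_matrix(sites, calls, population = pop)
}

FIXTURE_COLS <- c("site_id", "exon", "region", "dbsnp",
                  "aa_case_n", "aa_case_N", "ea_case_n", "ea_case_N",
                  "aa_ctrl_n", "aa_ctrl_N", "ea_ctrl_n", "ea_ctrl_N")
COUNT_GROUPS <- c("aa_case", "ea_case", "aa_ctrl", "ea_ctrl")

#' Load a variant count table
#'
#' Reads the TSV mirror of a per-variant count table (minor-allele count n and
#' sequenced-chromosome total N per population x SD stratum). The packaged
#' table `"pomc_exon_counts"` holds the 23 POMC exonic variants observed in
#' the 280 AA / 308 EA resequencing cohort.
#'
#' @param name packaged fixture name (e.g. `"pomc_exon_counts"`) or a path to
#'   a TSV in the same layout.
#' @return a `COUNT_ONLY` [cohort_study()].
#' @export
#' @examples
#' study <- load_count_fixture("pomc_exon_counts")
#' nrow(study$genotype_sites)
load_count_fixture <- function(name = "pomc_exon_counts") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".tsv"), package = "pomcvar")
  if (!nzchar(path) || !file.exists(path)) stop_ctx("count fixture not found: %s", name)
  raw_lines <- readLines(path)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(FIXTURE_COLS, names(df))
  if (length(miss))
    stop_ctx("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$site_id))
    stop_ctx("%s: duplicate site ids", path)
  for (g in COUNT_GROUPS) {
    n <- df[[paste0(g, "_n")]]; N <- df[[paste0(g, "_N")]]
    bad <- which(!is.finite(n) | !is.finite(N) | n < 0 | n > N)
    if (length(bad))
      stop_ctx("%s: invalid counts for %s at site %s", path, g, df$site_id[bad[1]])
  }
  bad_region <- which((df$region == "3UTR" & df$exon != 4) |
                      (df$region == "5UTR" & !df$exon %in% c(1, 3)) |
                      (df$region == "CDS" & !df$exon %in% 3:4))
  if (length(bad_region))
    stop_ctx("%s: region/exon inconsistent at site %s", path, df$site_id[bad_region[1]])
  sites <- validate_sites(df[, c("site_id", "exon", "region", "dbsnp",
                                 intersect("effect", names(df)))])
  counts <- do.call(rbind, lapply(COUNT_GROUPS, function(g)
    data.frame(site_id = df$site_id, group_id = g,
               n_minor = as.integer(df[[paste0(g, "_n")]]),
               n_total = as.integer(df[[paste0(g, "_N")]]),
               freq = ifelse(df[[paste0(g, "_N")]] > 0,
                             df[[paste0(g, "_n")]] / df[[paste0(g, "_N")]], NA_real_),
               degenerate = df[[paste0(g, "_N")]] == 0)))
  rownames(counts) <- NULL
  group_n <- NULL
  gl <- grep("^#\\s*groups\\b", raw_lines, value = TRUE)
  if (length(gl)) {
    kv <- regmatches(gl[1], gregexpr("[a-z_]+=[0-9]+", gl[1]))[[1]]
    group_n <- setNames(as.integer(sub(".*=", "", kv)), sub("=.*", "", kv))
  }
  st <- cohort_study(counts = counts, provenance = "COUNT_ONLY", group_n = group_n)
  st$genotype_sites <- sites
  st
}

#' Write a count table in the fixture layout
#'
#' Inverse of [load_count_fixture()]; a rendered table re-parsed by the
#' loader reproduces the source counts exactly.
#'
#' @param study a [cohort_study()] whose `counts` carry the four standard
#'   groups, or a long count table.
#' @param path output path.
#' @param sites site table (needed when a bare count table is given).
#' @return `path`, invisibly.
#' @export
write_count_fixture <- function(study, path, sites = NULL) {
  if (inherits(study, "cohort_study")) {
    counts <- study$counts
    if (is.null(sites))
      sites <- if (!is.null(study$genotype_sites)) study$genotype_sites
               else study$genotypes$sites
    group_n <- study$group_n
  } else {
    counts <- study; group_n <- NULL
  }
  stopifnot(is.data.frame(sites))
  wide <- sites[, c("site_id", "exon", "region", "dbsnp")]
  wide$dbsnp[is.na(wide$dbsnp)] <- "."
  for (g in COUNT_GROUPS) {
    sub <- counts[counts$group_id == g, ]
    ix <- match(wide$site_id, sub$site_id)
    wide[[paste0(g, "_n")]] <- sub$n_minor[ix]
    wide[[paste0(g, "_N")]] <- sub$n_total[ix]
  }
  wide$effect <- if (!is.null(sites$effect)) ifelse(is.na(sites$effect) |
    sites$effect == "", ".", sites$effect) else "."
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(group_n))
    writeLines(paste0("# groups ", paste(names(group_n), group_n, sep = "=",
                                         collapse = " ")), con)
  write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
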