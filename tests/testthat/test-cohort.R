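test_that("population assignment follows the 0.50 ancestry rule", {
  expect_equal(as.character(assign_population(c(0.50, 0.49, 1.0, 0.0))),
               c("AA", "EA", "AA", "EA"))
  expect_error(assign_population(1.2), "out of")
  expect_error(assign_population(NA_real_), "missing")
})

test_that("BMI classification is the WHO step function with half-open bins", {
  expect_equal(as.character(classify_bmi(c(18.4, 18.5, 22.4, 24.999, 25.0,
                                           27.1, 29.999, 30.0, 35.5))),
               c("UNDERWEIGHT", "NORMAL", "NORMAL", "NORMAL", "OVERWEIGHT",
                 "OVERWEIGHT", "OVERWEIGHT", "OBESE", "OBESE"))
  expect_error(classify_bmi(0), "positive")
  expect_error(classify_bmi(c(20, NA)), "non-missing")
  # total, monotone step function
  grid <- seq(10, 60, by = 0.01)
  cls <- as.integer(classify_bmi(grid))
  expect_false(anyNA(cls))
  expect_true(all(diff(cls) >= 0))
})

test_that("SD status is the OR of the four diagnoses; unscreened are excluded", {
  subj <- data.frame(subject_id = c("a", "b", "c"),
                     ad = c(1, 0, 0), cd = 0, od = 0, mjd = 0,
                     screened = c(0, 1, 0))
  out <- derive_sd_status(subj)
  expect_equal(out$sd_case, c(TRUE, FALSE, FALSE))
  expect_equal(as.character(out$status), c("case", "control", "excluded"))
  conflicted <- data.frame(subject_id = "x", ad = 1, cd = 0, od = 0, mjd = 0,
                           screened = 1)
  expect_error(derive_sd_status(conflicted), "both")
})

test_that("count_alleles equals a per-subject loop oracle on random matrices", {
  sites <- toy_sites()
  for (seed in 1:5) {
    set.seed(seed)
    gm <- random_calls(50, sites)
    grp <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    for (s in sample(sites$site_id, 3)) {
      got <- count_alleles(gm, s, grp, group_id = "g")
      # brute-force recount
      n_minor <- 0L; n_total <- 0L
      for (i in which(grp)) {
        v <- gm$calls[i, s]
        if (!is.na(v)) { n_minor <- n_minor + v; n_total <- n_total + 2L }
      }
      expect_identical(got$n_minor, n_minor)
      expect_identical(got$n_total, n_total)
    }
  }
  expect_error(count_alleles(random_calls(5, sites), "nope"), "unknown site")
})

test_that("group counts sum to the whole-cohort count for any partition", {
  set.seed(11)
  gm <- random_calls(60, toy_sites())
  part <- sample(1:3, 60, replace = TRUE)
  groups <- lapply(1:3, function(k) part == k)
  names(groups) <- paste0("g", 1:3)
  counts <- counts_from_genotypes(gm, groups)
  whole <- counts_from_genotypes(gm, list(all = rep(TRUE, 60)))
  for (s in toy_sites()$site_id) {
    sub <- counts[counts$site_id == s, ]
    expect_equal(sum(sub$n_minor), whole$n_minor[whole$site_id == s])
    expect_equal(sum(sub$n_total), whole$n_total[whole$site_id == s])
  }
})

test_that("a group with all calls missing is flagged degenerate", {
  sites <- toy_sites()
  calls <- matrix(NA_integer_, 4, nrow(sites),
                  dimnames = list(NULL, sites$site_id))
  gm <- genotype_matrix(sites, calls)
  got <- count_alleles(gm, "cmn1")
  expect_identical(got$n_total, 0L)
  expect_true(got$degenerate)
})

test_that("pooled MAF reproduces published cells of the packaged count table", {
  fx <- load_count_fixture("pomc_exon_counts")
  cc <- fx$counts
  pooled <- function(site, groups)
    compute_maf(cc[cc$site_id == site & cc$group_id %in% groups, ])
  cases <- c("aa_case", "ea_case"); ctrls <- c("aa_ctrl", "ea_ctrl")
  expect_equal(round(pooled("c.560_561insAGCAGCGGC", cases), 3), 0.164)
  expect_equal(round(pooled("c.61A>G", cases), 3), 0.011)
  expect_equal(round(pooled("c.1130C>T", ctrls), 3), 0.181)
  expect_equal(round(pooled("c.281C>T", ctrls), 3), 0.008)
  expect_error(compute_maf(data.frame(n_minor = 0, n_total = 0)), "zero total")
})

test_that("the packaged count table has the published structure", {
  fx <- load_count_fixture("pomc_exon_counts")
  expect_equal(length(unique(fx$counts$site_id)), 23)
  expect_equal(sum(fx$genotype_sites$novel), 12)
  expect_equal(fx$group_n,
               c(aa_case = 167L, aa_ctrl = 113L, ea_case = 144L, ea_ctrl = 164L))
  # spot-check cells against the published table
  cc <- fx$counts
  cell <- function(site, grp) unlist(
    cc[cc$site_id == site & cc$group_id == grp, c("n_minor", "n_total")],
    use.names = FALSE)
  expect_equal(cell("c.560_561insAGCAGCGGC", "aa_case"), c(66, 258))
  expect_equal(cell("c.560_561insAGCAGCGGC", "ea_ctrl"), c(14, 292))
  expect_equal(cell("c.61A>G", "aa_case"), c(6, 270))
  expect_equal(cell("c.1130C>T", "ea_ctrl"), c(68, 324))
  expect_equal(cell("c.281C>T", "ea_case"), c(4, 274))
})

test_that("phenotype and VCF round trips are identity", {
  st <- simulate_cohort(toy_config(31, n_case = 40, n_ctrl = 40))
  td <- withr::local_tempdir()
  pv <- file.path(td, "ph.tsv"); vcf <- file.path(td, "g.vcf")
  write_phenotypes(st$subjects, pv)
  write_genotypes_vcf(st$genotypes, vcf)
  s2 <- load_phenotypes(pv)
  expect_equal(s2$bmi, st$subjects$bmi)
  expect_equal(as.character(s2$status), as.character(st$subjects$status))
  expect_equal(as.character(s2$bmi_class), as.character(st$subjects$bmi_class))
  g2 <- load_genotypes(vcf, subjects = s2)
  expect_identical(unname(g2$calls), unname(st$genotypes$calls))
  expect_identical(g2$sites$site_id, st$genotypes$sites$site_id)
  expect_identical(g2$sites$segment, st$genotypes$sites$segment)
})

test_that("a single diploid het VCF record gives dosage 1", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "one.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EXON,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"r\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("2", "100", "site1", "A", "AAGCAGCGGC", ".", "PASS",
            "EXON=4;REGION=CDS", "GT", "0/1", "./."), collapse = "\t")), vcf)
  gm <- load_genotypes(vcf)
  expect_identical(gm$calls["S1", "site1"], 1L)
  expect_true(is.na(gm$calls["S2", "site1"]))
})

test_that("malformed or empty phenotype files are handled with context", {
  td <- withr::local_tempdir()
  empty <- file.path(td, "empty.tsv")
  writeLines(paste(c("subject_id", "sex", "age", "ancestry_prop", "ad", "cd",
                     "od", "mjd", "screened", "bmi"), collapse = "\t"), empty)
  expect_warning(out <- load_phenotypes(empty), "empty")
  expect_equal(nrow(out), 0)
  bad <- file.path(td, "bad.tsv")
  writeLines(c(paste(c("subject_id", "sex", "age", "ancestry_prop", "ad", "cd",
                       "od", "mjd", "screened", "bmi"), collapse = "\t"),
               paste(c("s1", "M", "40", "0.9", "2", "0", "0", "0", "0", "25"),
                     collapse = "\t")), bad)
  expect_error(load_phenotypes(bad), "0/1")
  dup <- file.path(td, "dup.tsv")
  writeLines(c(paste(c("subject_id", "sex", "age", "ancestry_prop", "ad", "cd",
                       "od", "mjd", "screened", "bmi"), collapse = "\t"),
               paste(c("s1", "M", "40", "0.9", "1", "0", "0", "0", "0", "25"),
                     collapse = "\t"),
               paste(c("s1", "F", "41", "0.8", "0", "0", "0", "0", "1", "22"),
                     collapse = "\t")), dup)
  expect_error(load_phenotypes(dup), "duplicate")
})

test_that("carrier accounting under the heterozygote assumption", {
  fx <- load_count_fixture("pomc_exon_counts")
  cc <- carrier_counts(fx$counts, "c.61A>G")
  expect_equal(cc$carriers, 9)
})
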