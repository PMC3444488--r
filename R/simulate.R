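## Synthetic cohort generator.
##
## Emulates the statistical structure the analysis assumes: two
## admixture-defined populations; two common sites drawn from a two-locus
## haplotype table (so LD is controllable); rare sites as independent
## heterozygous carriers; per-amplicon sequencing dropout producing variable
## per-variant chromosome totals; substance dependence from a logistic
## liability on the carried rare-allele count plus covariates; and WHO BMI
## categories whose elevated-weight odds respond to the 3'UTR-like common
## site in the EA population only.

#' Effect specification for the simulator
#'
#' @param burden_or_sd odds ratio of SD per rare minor allele carried.
#' @param common_or_bmi odds ratio of elevated weight (overweight or obese)
#'   per minor allele at the 3'UTR-like common site, EA subjects only.
#' @param sex_beta,age_beta,anc_beta baseline log-odds of SD for male sex,
#'   per decade of age (centred at 40), and per unit ancestry proportion
#'   (centred at 0.5).
#' @param base_sd_rate baseline SD probability at covariate centre.
#' @param base_elev_rate baseline probability of elevated weight class.
#' @param obese_given_elev probability an elevated-weight subject is obese.
#' @param underweight_rate marginal probability of the underweight class.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(burden_or_sd = 1, common_or_bmi = 1,
                        sex_beta = 0.2, age_beta = 0.1, anc_beta = 0.3,
                        base_sd_rate = 0.45, base_elev_rate = 0.7,
                        obese_given_elev = 0.45, underweight_rate = 0.005) {
  stopifnot(burden_or_sd > 0, common_or_bmi > 0,
            base_sd_rate > 0, base_sd_rate < 1,
            base_elev_rate > 0, base_elev_rate < 1)
  structure(as.list(environment()), class = "effect_spec")
}

#' Simulation configuration
#'
#' @param n_aa_case,n_aa_ctrl,n_ea_case,n_ea_ctrl target subject counts.
#' @param common_maf list with elements `aa` and `ea`, each a length-2 vector
#'   of minor allele frequencies for the two common sites (coding-indel-like
#'   site first, 3'UTR-SNP-like site second).
#' @param common_dprime signed D' between the *minor* alleles of the two
#'   common sites, per population (negative = repulsion, i.e. the 3'UTR
#'   minor allele rides on the major allele of the indel-like site).
#' @param rare_freqs list (`aa`, `ea`) of named per-site carrier
#'   frequencies: a subject carries the variant with probability f and a
#'   carrier is homozygous with probability f (so homozygotes occur at f^2).
#' @param sites site table for all simulated sites (defaults to the packaged
#'   variant panel); must contain the two common sites and every rare site.
#' @param segment_dropout matrix of per-subject amplicon failure
#'   probabilities, rows = segments (matching `sites$segment`), columns =
#'   `AA`/`EA`. A failed segment sets every call in it to missing.
#' @param common_sites ids of the two common sites within `sites`.
#' @param effects an [effect_spec()].
#' @param seed RNG seed giving full reproducibility.
#' @param pool_mult oversampling factor for the rejection-resampling pool.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_aa_case, n_aa_ctrl, n_ea_case, n_ea_ctrl,
                              common_maf, rare_freqs, sites, common_sites,
                              segment_dropout,
                              common_dprime = c(AA = -0.9, EA = -0.9),
                              effects = effect_spec(), seed = NULL,
                              pool_mult = 3) {
  counts <- c(n_aa_case, n_aa_ctrl, n_ea_case, n_ea_ctrl)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  stopifnot(is.list(common_maf), all(c("aa", "ea") %in% names(common_maf)))
  for (p in c("aa", "ea")) {
    stopifnot(length(common_maf[[p]]) == 2, all(common_maf[[p]] >= 0),
              all(common_maf[[p]] <= 1))
    stopifnot(all(rare_freqs[[p]] >= 0), all(rare_freqs[[p]] <= 1))
  }
  stopifnot(all(segment_dropout >= 0), all(segment_dropout < 1))
  stopifnot(inherits(effects, "effect_spec"))
  sites <- validate_sites(sites)
  if (is.null(sites$segment)) sites$segment <- paste0("E", sites$exon)
  stopifnot(all(common_sites %in% sites$site_id), length(common_sites) == 2)
  rare_sites <- setdiff(sites$site_id, common_sites)
  for (p in c("aa", "ea"))
    if (!all(rare_sites %in% names(rare_freqs[[p]])))
      stop_ctx("rare_freqs$%s must name every rare site", p)
  stopifnot(all(rownames(segment_dropout) %in% unique(sites$segment)) ||
            all(unique(sites$segment) %in% rownames(segment_dropout)))
  structure(list(n_aa_case = n_aa_case, n_aa_ctrl = n_aa_ctrl,
                 n_ea_case = n_ea_case, n_ea_ctrl = n_ea_ctrl,
                 common_maf = common_maf, common_dprime = common_dprime,
                 rare_freqs = rare_freqs, sites = sites,
                 common_sites = common_sites, rare_sites = rare_sites,
                 segment_dropout = segment_dropout,
                 effects = effects, seed = seed, pool_mult = pool_mult),
            class = "sim_config")
}

## Two-locus haplotype frequencies (counted-allele coding) from marginal
## minor allele frequencies and a signed D' between the minor alleles.
hap_freqs_from_dprime <- function(p1, p2, dprime) {
  d_max <- if (dprime >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
           else min(p1 * p2, (1 - p1) * (1 - p2))
  D <- dprime * d_max
  f <- c(f00 = (1 - p1) * (1 - p2) + D, f01 = (1 - p1) * p2 - D,
         f10 = p1 * (1 - p2) - D, f11 = p1 * p2 + D)
  if (any(f < -1e-12)) stop_ctx("invalid haplotype table (check D')")
  pmax(f, 0)
}

#' Simulate genotypes for the subject pool
#'
#' Common sites: two haplotypes per subject drawn from the population's
#' two-locus haplotype table (Hardy-Weinberg at the haplotype level). Rare
#' sites: independent carriers at the configured frequency. Per-amplicon
#' dropout then masks observed calls; the complete (pre-dropout) matrix is
#' kept alongside for phenotype simulation, since sequencing failure is a
#' measurement process, not a biological one.
#'
#' @param config a [simulation_config()].
#' @param n_pool named vector `c(AA = ..., EA = ...)` of pool sizes; defaults
#'   to `pool_mult` times the target totals.
#' @return a [genotype_matrix()] with attribute `"calls_complete"`.
#' @export
simulate_genotypes <- function(config, n_pool = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_pool))
    n_pool <- c(AA = ceiling(config$pool_mult * (config$n_aa_case + config$n_aa_ctrl)),
                EA = ceiling(config$pool_mult * (config$n_ea_case + config$n_ea_ctrl)))
  sites <- config$sites
  n_tot <- sum(n_pool)
  pop <- rep(c("AA", "EA"), n_pool[c("AA", "EA")])
  calls <- matrix(0L, n_tot, nrow(sites),
                  dimnames = list(sprintf("%s%05d", pop, seq_len(n_tot)),
                                  sites$site_id))
  for (p in c("AA", "EA")) {
    idx <- which(pop == p)
    if (!length(idx)) next
    pl <- tolower(p)
    ## common pair from the haplotype table
    hf <- hap_freqs_from_dprime(config$common_maf[[pl]][1],
                                config$common_maf[[pl]][2],
                                unname(config$common_dprime[[p]]))
    hap <- matrix(sample.int(4L, 2 * length(idx), replace = TRUE, prob = hf),
                  ncol = 2)
    allele1 <- matrix(c(0L, 0L, 1L, 1L)[hap], ncol = 2)  # minor at site 1
    allele2 <- matrix(c(0L, 1L, 0L, 1L)[hap], ncol = 2)  # minor at site 2
    calls[idx, config$common_sites[1]] <- rowSums(allele1)
    calls[idx, config$common_sites[2]] <- rowSums(allele2)
    ## rare sites: carrier w.p. f, homozygous carrier w.p. f within carriers
    for (s in config$rare_sites) {
      f <- unname(config$rare_freqs[[pl]][s])
      if (f <= 0) next
      carrier <- runif(length(idx)) < f
      hom <- carrier & (runif(length(idx)) < f)
      calls[idx, s] <- ifelse(hom, 2L, ifelse(carrier, 1L, 0L))
    }
  }
  complete <- calls
  ## per-amplicon dropout
  segs <- rownames(config$segment_dropout)
  for (p in c("AA", "EA")) {
    idx <- which(pop == p)
    if (!length(idx)) next
    for (sg in segs) {
      d <- config$segment_dropout[sg, p]
      if (d <= 0) next
      fail <- idx[runif(length(idx)) < d]
      calls[fail, sites$site_id[sites$segment == sg]] <- NA_integer_
    }
  }
  gm <- genotype_matrix(sites, calls, population = pop)
  attr(gm, "calls_complete") <- complete
  gm
}

#' Simulate phenotypes over a genotype pool and select the cohort
#'
#' SD status follows a logistic liability on the complete (pre-dropout)
#' rare-allele count plus sex, age and ancestry covariates. Elevated weight
#' (overweight or obese vs normal) follows an independent logistic model
#' whose odds respond to the 3'UTR-like common site in EA subjects; elevated
#' subjects split into overweight/obese independently of genotype, so all
#' three BMI contrasts share one generating odds ratio. BMI values are then
#' drawn from class-conditional truncated normals. Target case/control
#' counts per population are met by rejection resampling from the pool
#' (approximate retrospective sampling; adequate away from extreme effect
#' sizes).
#'
#' @param genotypes pool genotypes from [simulate_genotypes()].
#' @param config the same [simulation_config()].
#' @return subject table for the pool with logical column `selected`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  eff <- config$effects
  pop <- genotypes$population
  n <- length(pop)
  complete <- attr(genotypes, "calls_complete")
  if (is.null(complete)) complete <- genotypes$calls
  sex <- factor(ifelse(runif(n) < 0.6, "M", "F"), levels = c("M", "F"))
  age <- pmax(18, rnorm(n, 40, 10))
  ancestry <- numeric(n)
  aa <- pop == "AA"
  ## admixture proportions on the assigned side of the 0.5 rule
  ancestry[aa] <- 0.5 + 0.5 * rbeta(sum(aa), 4, 1.5)
  ancestry[!aa] <- 0.5 * rbeta(sum(!aa), 1.5, 4)
  rare_count <- rowSums(complete[, config$rare_sites, drop = FALSE])
  eta_sd <- qlogis(eff$base_sd_rate) + log(eff$burden_or_sd) * rare_count +
    eff$sex_beta * (sex == "M") + eff$age_beta * (age - 40) / 10 +
    eff$anc_beta * (ancestry - 0.5)
  sd_case <- runif(n) < plogis(eta_sd)
  traits <- matrix(FALSE, n, 4, dimnames = list(NULL, c("ad", "cd", "od", "mjd")))
  trait_rates <- list(AA = c(ad = 0.784, cd = 0.707, od = 0.144, mjd = 0.407),
                      EA = c(ad = 0.778, cd = 0.590, od = 0.347, mjd = 0.306))
  for (p in c("AA", "EA")) {
    idx <- which(sd_case & pop == p)
    if (!length(idx)) next
    r <- trait_rates[[p]]
    m <- matrix(runif(length(idx) * 4), ncol = 4) <
      matrix(r, length(idx), 4, byrow = TRUE)
    none <- rowSums(m) == 0
    while (any(none)) {  # condition on at least one specific dependence
      m[none, ] <- matrix(runif(sum(none) * 4), ncol = 4) <
        matrix(r, sum(none), 4, byrow = TRUE)
      none <- rowSums(m) == 0
    }
    traits[idx, ] <- m
  }
  ## BMI class: underweight rare and genotype-independent; elevated vs normal
  ## logistic in the 3'UTR-like dosage (EA only)
  snp_dose <- complete[, config$common_sites[2]]
  eta_bmi <- qlogis(eff$base_elev_rate) +
    log(eff$common_or_bmi) * snp_dose * (pop == "EA")
  underweight <- runif(n) < eff$underweight_rate
  elevated <- !underweight & (runif(n) < plogis(eta_bmi))
  obese <- elevated & (runif(n) < eff$obese_given_elev)
  bmi_class <- ifelse(underweight, "UNDERWEIGHT",
                ifelse(!elevated, "NORMAL",
                  ifelse(obese, "OBESE", "OVERWEIGHT")))
  rtnorm <- function(m, mu, sdv, lo, hi) {
    qnorm(runif(m, pnorm(lo, mu, sdv), pnorm(hi, mu, sdv)), mu, sdv)
  }
  bmi <- numeric(n)
  cls <- list(UNDERWEIGHT = c(18.4, 0.1, 15, 18.5 - 1e-6),
              NORMAL = c(22.4, 1.6, 18.5, 25 - 1e-6),
              OVERWEIGHT = c(27.1, 1.4, 25, 30 - 1e-6),
              OBESE = c(35.5, 5.1, 30, 65))
  for (cl in names(cls)) {
    idx <- which(bmi_class == cl)
    if (!length(idx)) next
    par <- cls[[cl]]
    bmi[idx] <- rtnorm(length(idx), par[1], par[2], par[3], par[4])
  }
  subjects <- data.frame(
    subject_id = rownames(genotypes$calls),
    sex = sex, age = round(age, 1), ancestry_prop = round(ancestry, 4),
    ad = traits[, "ad"], cd = traits[, "cd"], od = traits[, "od"],
    mjd = traits[, "mjd"], screened = !sd_case, bmi = round(bmi, 1),
    stringsAsFactors = FALSE)
  subjects$population <- assign_population(subjects$ancestry_prop)
  subjects <- derive_sd_status(subjects)
  subjects$bmi_class <- classify_bmi(subjects$bmi)
  ## rejection resampling to the target case/control counts
  want <- c(aa_case = config$n_aa_case, aa_ctrl = config$n_aa_ctrl,
            ea_case = config$n_ea_case, ea_ctrl = config$n_ea_ctrl)
  grp <- study_groups(subjects)
  subjects$selected <- FALSE
  for (g in names(want)) {
    avail <- which(grp[[g]])
    if (length(avail) < want[[g]])
      stop_ctx("pool yields only %d %s subjects but %d requested; raise pool_mult or adjust effects",
               length(avail), g, want[[g]])
    subjects$selected[avail[seq_len(want[[g]])]] <- TRUE
  }
  subjects
}

#' Simulate a complete cohort study
#'
#' Runs [simulate_genotypes()] and [simulate_phenotypes()] under the
#' config's seed and returns the selected cohort as a subject-level
#' [cohort_study()], with the count table derived from the observed
#' (post-dropout) calls. Identical seeds give identical cohorts.
#'
#' @param config a [simulation_config()].
#' @return a SUBJECT_LEVEL [cohort_study()].
#' @export
simulate_cohort <- function(config) {
  with_seed(config$seed, {
    gm <- simulate_genotypes(config)
    subjects <- simulate_phenotypes(gm, config)
    keep <- which(subjects$selected)
    calls <- gm$calls[keep, , drop = FALSE]
    subjects <- subjects[keep, setdiff(names(subjects), "selected"),
                         drop = FALSE]
    rownames(subjects) <- NULL
    gm2 <- genotype_matrix(gm$sites, calls,
                           population = subjects$population)
    cohort_study(genotypes = gm2, subjects = subjects,
                 provenance = "SUBJECT_LEVEL")
  })
}

#' Amplicon segments inferred from a count table
#'
#' Sites sequenced on the same amplicon share per-group chromosome totals;
#' grouping sites by their vector of denominators recovers the amplicon
#' structure from a published count table.
#'
#' @param counts long count table.
#' @return named character vector, site_id -> segment label (`S1`, `S2`, ...
#'   in order of first appearance).
#' @export
segments_from_counts <- function(counts) {
  sites <- unique(counts$site_id)
  key <- vapply(sites, function(s)
    paste(counts$n_total[counts$site_id == s], collapse = ","), character(1))
  setNames(paste0("S", as.integer(factor(key, levels = unique(key)))), sites)
}

#' Preset simulation matching the resequencing study design
#'
#' Group sizes 167/113 (AA cases/controls) and 144/164 (EA), minor allele
#' frequencies 0.284/0.048 (AA/EA) for the coding-indel-like common site and
#' 0.140/0.210 for the 3'UTR-SNP-like site (the control-sample estimates),
#' rare carrier frequencies recovered from the packaged count table per
#' population, and per-amplicon dropout fitted so that expected pooled
#' per-population chromosome totals match the packaged table exactly.
#' Default effects: SD odds ratio about 3.3 per rare allele (the allele-level
#' enrichment implied by the collapsed AA counts) and elevated-weight odds
#' ratio 2.0 per 3'UTR minor allele in EAs.
#'
#' @param effects an [effect_spec()]; defaults to the estimates above.
#' @param seed RNG seed stored in the config.
#' @param ... overrides passed to [simulation_config()].
#' @return a [simulation_config()].
#' @export
#' @examples
#' cfg <- pomc_preset(seed = 1)
#' cfg$n_aa_case + cfg$n_aa_ctrl + cfg$n_ea_case + cfg$n_ea_ctrl
pomc_preset <- function(effects = effect_spec(burden_or_sd = 3.3,
                                              common_or_bmi = 2.0),
                        seed = NULL, ...) {
  fx <- load_count_fixture("pomc_exon_counts")
  counts <- fx$counts
  sites <- fx$genotype_sites
  seg <- segments_from_counts(counts)
  sites$segment <- unname(seg[sites$site_id])
  common_sites <- c("c.560_561insAGCAGCGGC", "c.1130C>T")
  rare_sites <- setdiff(sites$site_id, common_sites)
  n_subj <- c(AA = 280L, EA = 308L)
  ## carrier frequency f from pooled allele frequency p: f(1+f)/2 = p
  carrier_from_p <- function(p) (-1 + sqrt(1 + 8 * p)) / 2
  rare_freqs <- lapply(c(aa = "aa", ea = "ea"), function(pl) {
    sub <- counts[counts$group_id %in% paste0(pl, c("_case", "_ctrl")) &
                  counts$site_id %in% rare_sites, ]
    p <- vapply(rare_sites, function(s)
      compute_maf(sub[sub$site_id == s, ]), numeric(1))
    setNames(carrier_from_p(p), rare_sites)
  })
  ## dropout per segment fitted to pooled per-population denominators
  segs <- unique(seg)
  segment_dropout <- matrix(0, length(segs), 2,
                            dimnames = list(segs, c("AA", "EA")))
  for (sg in segs) {
    s0 <- names(seg)[seg == sg][1]
    for (p in c("AA", "EA")) {
      pl <- tolower(p)
      obs <- sum(counts$n_total[counts$site_id == s0 &
                                counts$group_id %in% paste0(pl, c("_case", "_ctrl"))])
      segment_dropout[sg, p] <- 1 - obs / (2 * n_subj[[p]])
    }
  }
  simulation_config(
    n_aa_case = 167, n_aa_ctrl = 113, n_ea_case = 144, n_ea_ctrl = 164,
    common_maf = list(aa = c(0.284, 0.140), ea = c(0.048, 0.210)),
    rare_freqs = rare_freqs, sites = sites, common_sites = common_sites,
    segment_dropout = segment_dropout, effects = effects, seed = seed, ...)
}
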