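## Single-marker association for common variants: Hardy-Weinberg checks,
## allelic 2x2 chi-square with odds ratio and Woolf interval, permutation
## empirical p-values, and covariate-adjusted logistic regression.

#' Hardy-Weinberg equilibrium test
#'
#' Exact method: conditional on the observed allele counts, sums the
#' probabilities of all heterozygote configurations no more probable than the
#' observed one. Chi-square method: 1-df Pearson test against p^2/2pq/q^2
#' expectations. Monomorphic input returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @param method `"exact"` or `"chi2"`.
#' @return list with `p`, `method`, and for chi2 the `statistic`.
#' @export
#' @examples
#' hwe_test(25, 50, 25, method = "chi2")$p
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chi2")) {
  method <- match.arg(method)
  cnt <- c(n_AA, n_Aa, n_aa)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop_ctx("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0) stop_ctx("no genotypes")
  na <- 2 * n_aa + n_Aa          # minor allele copies
  nA <- 2 * n_AA + n_Aa
  if (na == 0 || nA == 0)
    return(list(p = 1, method = method, statistic = 0))
  if (method == "chi2") {
    p <- na / (2 * n)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((cnt - expd)^2 / expd)
    return(list(p = pchisq(stat, df = 1, lower.tail = FALSE),
                method = method, statistic = stat))
  }
  ## exact: support of heterozygote count given allele totals
  rare <- min(na, nA)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(na) + lfactorial(nA) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  list(p = min(1, sum(pr[pr <= obs * (1 + 1e-12)])), method = method,
       statistic = NA_real_)
}

## chi2 for a 2x2 table given as four cells; no Yates correction.
## Doubles throughout: n*(ad-bc)^2 overflows 32-bit integers easily.
chi2_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) <= 0) return(NA_real_)
  n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
}

#' Allelic 2x2 chi-square association test
#'
#' Pearson chi-square without continuity correction (the allelic-test
#' convention of standard association toolkits), odds ratio `ad/bc`, and the
#' Woolf log-interval `exp(ln OR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`. When any
#' cell is zero, the Haldane-Anscombe 0.5 correction is added to every cell
#' for the OR and interval (the chi-square uses the raw cells).
#'
#' @param a,b minor and major allele counts in group 1.
#' @param c,d minor and major allele counts in group 2.
#' @return object of class `allelic_test`: counts, `chi2`, `p_obs`, `or`,
#'   `ci95`, `p_emp` (NA until [permutation_empirical_p()] fills it).
#' @export
#' @examples
#' allelic_chi2(30, 70, 15, 85)
allelic_chi2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_ctx("cell counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) <= 0)
    stop_ctx("degenerate 2x2 table: zero margin")
  chi2 <- chi2_2x2(a, b, c, d)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  k <- if (any(cells == 0)) 0.5 else 0
  or <- ((a + k) * (d + k)) / ((b + k) * (c + k))
  se <- sqrt(sum(1 / (cells + k)))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  structure(list(counts = matrix(cells, 2, 2, byrow = TRUE,
                                 dimnames = list(c("group1", "group2"),
                                                 c("minor", "major"))),
                 chi2 = chi2, df = 1L, p_obs = p, or = or, ci95 = ci,
                 p_emp = NA_real_),
            class = "allelic_test")
}

#' @export
print.allelic_test <- function(x, ...) {
  cat(sprintf("allelic 2x2 test: chi2 = %.3f, p = %s, OR = %.3f (%.2f-%.2f)",
              x$chi2, format_pval(x$p_obs), x$or, x$ci95[1], x$ci95[2]))
  if (!is.na(x$p_emp)) cat(sprintf(", p_emp = %s", format_pval(x$p_emp)))
  cat("\n")
  invisible(x)
}

#' Permutation empirical p-value for the allelic test
#'
#' Permutes group labels over subjects (keeping per-subject dosages intact),
#' recomputes the allelic chi-square each time, and reports
#' `(1 + b) / (1 + n_perm)` where `b` counts permuted statistics at least as
#' large as the observed one; the +1 estimator avoids empirical p-values of
#' zero. Subjects with missing dosage must be dropped beforehand.
#'
#' @param dosage per-subject minor-allele dosage (0/1/2, complete).
#' @param labels two-level factor of group membership.
#' @param n_perm number of permutations (the study convention is 10,000).
#' @param seed optional RNG seed; the global RNG state is restored.
#' @return empirical p-value.
#' @export
permutation_empirical_p <- function(dosage, labels, n_perm = 10000, seed = NULL) {
  if (anyNA(dosage) || anyNA(labels)) stop_ctx("dosage/labels must be complete")
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop_ctx("labels must have exactly two levels")
  if (min(table(labels)) < 2L) stop_ctx("need at least 2 subjects per label")
  if (n_perm < 1) stop_ctx("n_perm must be >= 1")
  n <- length(dosage)
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1)
  tot1 <- 2 * n1; tot2 <- 2 * (n - n1)
  cmin <- sum(dosage)                      # total minor alleles, fixed margin
  stat_of_a <- function(a) {
    s <- chi2_2x2(a, tot1 - a, cmin - a, tot2 - (cmin - a))
    ifelse(is.na(s), 0, s)
  }
  obs <- stat_of_a(sum(dosage[g1]))
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(dosage[sample.int(n, n1)]), numeric(1)))
  b <- sum(stat_of_a(perm) >= obs - 1e-12)
  (1 + b) / (1 + n_perm)
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of a binary outcome on additive
#' minor-allele dosage plus covariates; reports the Wald z statistic and
#' p-value for the dosage term. Quasi-separation and non-convergence are
#' reported as such (`converged = FALSE`, p-values NA) rather than as
#' spurious p-values.
#'
#' @param outcome logical/0-1 vector (both classes present).
#' @param dosage minor-allele dosage 0/1/2.
#' @param covariates data frame of covariates (or NULL).
#' @return object of class `logistic_test`: `beta`, `se`, `stat`, `p_adj`,
#'   `or_adj`, `ci95`, `covariates`, `converged`, `n`.
#' @export
logistic_assoc <- function(outcome, dosage, covariates = NULL) {
  outcome <- as.integer(as.logical(outcome))
  keep <- !is.na(outcome) & !is.na(dosage)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  outcome <- outcome[keep]; dosage <- dosage[keep]
  dat <- data.frame(.y = outcome, dosage = dosage)
  if (!is.null(covariates)) {
    cov <- as.data.frame(covariates)[keep, , drop = FALSE]
    ## drop constant columns (e.g. SD status in an all-control stratum)
    cov <- cov[, vapply(cov, function(x) length(unique(x)) > 1L, TRUE), drop = FALSE]
    dat <- cbind(dat, cov)
  }
  if (length(unique(outcome)) < 2L) stop_ctx("outcome has a single class")
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  est <- coef(fit)["dosage"]
  se <- sqrt(diag(vcov(fit)))["dosage"]
  converged <- isTRUE(fit$converged) && is.finite(se) && se < 10
  z <- if (converged) unname(est / se) else NA_real_
  structure(list(beta = unname(est), se = unname(se), stat = z,
                 p_adj = if (converged) 2 * pnorm(-abs(z)) else NA_real_,
                 or_adj = exp(unname(est)),
                 ci95 = if (converged)
                   exp(unname(est) + c(-1, 1) * qnorm(0.975) * unname(se))
                 else c(NA_real_, NA_real_),
                 covariates = setdiff(names(dat), c(".y", "dosage")),
                 converged = converged, n = nrow(dat)),
            class = "logistic_test")
}

#' @export
print.logistic_test <- function(x, ...) {
  if (!x$converged) {
    cat("logistic association: did not converge (possible separation)\n")
  } else {
    cat(sprintf(
      "logistic association: beta = %.3f, z = %.2f, p = %s, OR = %.2f (%.2f-%.2f), n = %d\n",
      x$beta, x$stat, format_pval(x$p_adj), x$or_adj, x$ci95[1], x$ci95[2], x$n))
  }
  invisible(x)
}

BMI_MODELS <- c(overweight = "OVERWEIGHT", obese = "OBESE",
                overweight_obese = "OVERWEIGHT_OBESE")

#' BMI-category association contrasts for one common variant
#'
#' Runs one of the three BMI models -- overweight, obese, or overweight+obese,
#' each against the normal-weight group -- for a single site, pooling SD cases
#' and controls with SD status as a covariate. Underweight subjects are
#' excluded from all three contrasts. Reports the allelic chi-square result
#' (with permutation empirical p when `n_perm > 0`) and the
#' covariate-adjusted logistic fit (sex, age, ancestry proportion, SD
#' status).
#'
#' @param study a SUBJECT_LEVEL [cohort_study()].
#' @param site_id common variant to test.
#' @param model `"overweight"`, `"obese"` or `"overweight_obese"`.
#' @param population `"AA"`, `"EA"` or `"ALL"`.
#' @param n_perm permutations for the empirical p (0 to skip).
#' @param seed RNG seed for the permutations.
#' @return list with elements `allelic` and `logistic`, plus the group sizes.
#' @export
run_bmi_contrasts <- function(study, site_id,
                              model = c("overweight", "obese", "overweight_obese"),
                              population = c("ALL", "AA", "EA"),
                              n_perm = 0, seed = NULL) {
  model <- match.arg(model)
  population <- match.arg(population)
  if (!inherits(study, "cohort_study") || study$provenance != "SUBJECT_LEVEL")
    stop_ctx("BMI contrasts require subject-level data (count-only study given)")
  sub <- study$subjects
  keep <- sub$status %in% c("case", "control") & sub$bmi_class != "UNDERWEIGHT"
  if (population != "ALL") keep <- keep & sub$population == population
  cond <- switch(model,
    overweight = sub$bmi_class == "OVERWEIGHT",
    obese = sub$bmi_class == "OBESE",
    overweight_obese = sub$bmi_class %in% c("OVERWEIGHT", "OBESE"))
  comp <- sub$bmi_class == "NORMAL"
  keep <- keep & (cond | comp)
  dosage <- study$genotypes$calls[, site_id]
  keep <- keep & !is.na(dosage)
  if (sum(keep & cond) == 0 || sum(keep & comp) == 0)
    stop_ctx("untestable contrast: empty %s or normal-weight stratum", model)
  y <- cond[keep]
  d <- dosage[keep]
  a <- sum(d[y]); tot1 <- 2 * sum(y)
  c_ <- sum(d[!y]); tot2 <- 2 * sum(!y)
  al <- allelic_chi2(a, tot1 - a, c_, tot2 - c_)
  if (n_perm > 0)
    al$p_emp <- permutation_empirical_p(d, factor(ifelse(y, "cond", "normal"),
                                                  levels = c("cond", "normal")),
                                        n_perm = n_perm, seed = seed)
  covs <- data.frame(sex = sub$sex[keep], age = sub$age[keep],
                     ancestry = sub$ancestry_prop[keep],
                     sd = as.integer(sub$sd_case[keep]))
  lg <- logistic_assoc(y, d, covs)
  list(site_id = site_id, model = model, population = population,
       n_cond = sum(y), n_comp = sum(!y),
       freq_cond = a / tot1, freq_comp = c_ / tot2,
       allelic = al, logistic = lg)
}

#' SD trait association for one common variant
#'
#' Case-control allelic and logistic association for SD overall or a specific
#' dependence trait (cases for a specific trait are the subset of SD cases
#' with that diagnosis; controls are always the screened controls). BMI is
#' included as an additional covariate alongside sex, age and ancestry.
#'
#' @inheritParams run_bmi_contrasts
#' @param trait one of `"sd"`, `"ad"`, `"cd"`, `"od"`, `"mjd"`.
#' @return list with `allelic` and `logistic` elements.
#' @export
run_sd_assoc <- function(study, site_id, trait = c("sd", "ad", "cd", "od", "mjd"),
                         population = c("ALL", "AA", "EA"),
                         n_perm = 0, seed = NULL) {
  trait <- match.arg(trait)
  population <- match.arg(population)
  if (!inherits(study, "cohort_study") || study$provenance != "SUBJECT_LEVEL")
    stop_ctx("SD association requires subject-level data")
  sub <- study$subjects
  is_case <- if (trait == "sd") sub$status == "case" else
    sub$status == "case" & sub[[trait]]
  keep <- (is_case | sub$status == "control")
  if (population != "ALL") keep <- keep & sub$population == population
  dosage <- study$genotypes$calls[, site_id]
  keep <- keep & !is.na(dosage)
  y <- is_case[keep]; d <- dosage[keep]
  if (!any(y) || !any(!y)) stop_ctx("untestable: empty case or control group")
  a <- sum(d[y]); tot1 <- 2 * sum(y)
  c_ <- sum(d[!y]); tot2 <- 2 * sum(!y)
  al <- allelic_chi2(a, tot1 - a, c_, tot2 - c_)
  if (n_perm > 0)
    al$p_emp <- permutation_empirical_p(d, factor(ifelse(y, "case", "ctrl"),
                                                  levels = c("case", "ctrl")),
                                        n_perm = n_perm, seed = seed)
  covs <- data.frame(sex = sub$sex[keep], age = sub$age[keep],
                     ancestry = sub$ancestry_prop[keep], bmi = sub$bmi[keep])
  lg <- logistic_assoc(y, d, covs)
  list(site_id = site_id, trait = trait, population = population,
       n_case = sum(y), n_ctrl = sum(!y),
       freq_case = a / tot1, freq_ctrl = c_ / tot2,
       allelic = al, logistic = lg)
}
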