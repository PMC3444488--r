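## Retrospective power: minimum detectable odds ratio for the allelic
## (2n chromosomes per group) case-control comparison, using the Fleiss
## continuity-corrected two-proportion normal approximation -- the default
## dichotomous method of the PS power calculator family.

#' Power of the continuity-corrected two-proportion test
#'
#' Normal approximation with pooled-variance null standard error and the
#' continuity correction `(1/N1 + 1/N0)/2` applied to the difference in
#' proportions (Fleiss). Counts are allele-level: pass chromosomes, not
#' subjects, when powering an allelic test.
#'
#' @param p1,p0 event proportions in the two groups.
#' @param n1,n0 group sizes (allele counts for allelic tests).
#' @param alpha two-sided type-I error.
#' @return power in \[0, 1\].
#' @export
power_two_prop_cc <- function(p1, p0, n1, n0, alpha = 0.05) {
  stopifnot(p1 >= 0, p1 <= 1, p0 >= 0, p0 <= 1, n1 > 0, n0 > 0)
  d <- abs(p1 - p0)
  if (d == 0) return(alpha / 2)
  cc <- min(0.5 * (1 / n1 + 1 / n0), d)
  pbar <- (n1 * p1 + n0 * p0) / (n1 + n0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  z <- (d - cc - qnorm(1 - alpha / 2) * se0) / se1
  pnorm(z)
}

#' Minimum detectable odds ratio
#'
#' Smallest odds ratio above 1 at which the continuity-corrected
#' two-proportion test on allele counts reaches the target power, given the
#' control minor allele frequency and the subject group sizes (each subject
#' contributes two chromosomes). Solved by bisection to 1e-4. When even an
#' enormous odds ratio cannot reach the target (tiny samples), the result is
#' `Inf` with `attainable = FALSE`.
#'
#' @param p0 control minor allele frequency (0 < p0 < 1).
#' @param n_case,n_ctrl subject counts.
#' @param alpha two-sided type-I error.
#' @param power target power.
#' @param alleles if TRUE (default), group sizes are `2 * n`.
#' @return list with `or`, `power_at_or`, `attainable`, and the allele-level
#'   group sizes.
#' @export
#' @examples
#' min_detectable_or(p0 = 0.284, n_case = 167, n_ctrl = 113)$or
min_detectable_or <- function(p0, n_case, n_ctrl, alpha = 0.05, power = 0.80,
                              alleles = TRUE) {
  stopifnot(p0 > 0, p0 < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  n1 <- if (alleles) 2 * n_case else n_case
  n0 <- if (alleles) 2 * n_ctrl else n_ctrl
  p_of_or <- function(or) {
    odds <- or * p0 / (1 - p0)
    odds / (1 + odds)
  }
  f <- function(or) power_two_prop_cc(p_of_or(or), p0, n1, n0, alpha) - power
  hi <- 2
  while (f(hi) < 0 && hi < 1e4) hi <- hi * 2
  if (f(hi) < 0)
    return(list(or = Inf, power_at_or = NA_real_, attainable = FALSE,
                n1 = n1, n0 = n0))
  lo <- 1
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  or <- (lo + hi) / 2
  list(or = or, power_at_or = power_two_prop_cc(p_of_or(or), p0, n1, n0, alpha),
       attainable = TRUE, n1 = n1, n0 = n0)
}
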