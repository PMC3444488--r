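## Rare-variant collapsing burden analysis.
##
## Rare minor alleles across the panel are summed into a single variable per
## group. Because the four amplicons sequence with different success rates,
## per-variant chromosome totals N_i differ; the collapse replaces them with
## the harmonic-mean size N = n / sum(1/N_i) and rescales each variant's
## contribution as p_i * N before a single Fisher exact comparison.

#' Classify sites into the rare-variant panel
#'
#' A site is rare when the larger of its pooled-case and pooled-control minor
#' allele frequencies is strictly below `maf_threshold`. The default 0.012
#' keeps every site under the nominal 1% convention plus the single site at
#' MAF 0.011 that the study design includes; pass `maf_threshold = 0.01` for
#' the strict nominal rule. Sites with zero sequenced chromosomes in both
#' strata are excluded with a warning.
#'
#' @param counts long count table (as in a [cohort_study()]).
#' @param maf_threshold strict upper bound on the classification MAF.
#' @return object of class `rare_panel`: `sites`, `common_sites`,
#'   `maf_threshold`, `basis`, and the per-site classification table.
#' @export
#' @examples
#' study <- load_count_fixture("pomc_exon_counts")
#' classify_rare(study$counts)
classify_rare <- function(counts, maf_threshold = 0.012) {
  stopifnot(maf_threshold > 0)
  meta <- parse_group_id(unique(counts$group_id))
  counts2 <- merge(counts, meta, by = "group_id")
  pooled <- function(stratum) {
    sub <- counts2[counts2$stratum %in% stratum, ]
    agg <- aggregate(cbind(n_minor, n_total) ~ site_id, sub, sum)
    agg$freq <- ifelse(agg$n_total > 0, agg$n_minor / agg$n_total, NA_real_)
    agg
  }
  ca <- pooled("case"); co <- pooled("ctrl")
  tab <- merge(ca, co, by = "site_id", suffixes = c("_case", "_ctrl"))
  tab$maf_class <- pmax(tab$freq_case, tab$freq_ctrl, na.rm = TRUE)
  dead <- tab$n_total_case + tab$n_total_ctrl == 0
  if (any(dead)) {
    warning(sprintf("excluding %d site(s) with zero sequenced chromosomes: %s",
                    sum(dead), paste(tab$site_id[dead], collapse = ", ")),
            call. = FALSE)
    tab <- tab[!dead, ]
  }
  tab <- tab[order(match(tab$site_id, unique(counts$site_id))), ]
  rare <- tab$maf_class < maf_threshold
  structure(list(sites = tab$site_id[rare],
                 common_sites = tab$site_id[!rare],
                 maf_threshold = maf_threshold,
                 basis = "max(pooled-case MAF, pooled-control MAF), strict <",
                 classification = tab),
            class = "rare_panel")
}

#' @export
print.rare_panel <- function(x, ...) {
  cat(sprintf("rare_panel: %d rare sites (MAF < %g on %s), %d common excluded\n",
              length(x$sites), x$maf_threshold, x$basis, length(x$common_sites)))
  invisible(x)
}

#' Harmonic-mean sample size
#'
#' `N = n / sum(1/N_i)` over the `n` panel variants' chromosome totals,
#' correcting for variable sequencing success across amplicons. Always lies
#' between `min(N_i)` and `max(N_i)`, and never exceeds the arithmetic mean.
#'
#' @param per_site_N vector of per-variant chromosome totals, all positive.
#' @return harmonic mean, full precision.
#' @export
#' @examples
#' harmonic_mean_size(c(100, 100, 100))
harmonic_mean_size <- function(per_site_N) {
  if (length(per_site_N) == 0) stop_ctx("empty panel")
  if (any(per_site_N <= 0))
    stop_ctx("all N_i must be positive (drop failed sites upstream)")
  length(per_site_N) / sum(1 / per_site_N)
}

#' Harmonic-mean-adjusted collapsed counts for one group
#'
#' The collapsed numerator is `round(sum_i p_i * N)` with
#' `p_i = n_minor_i / N_i` and `N` the harmonic-mean size, rounded half away
#' from zero; the raw numerator `sum_i n_minor_i` is retained alongside.
#' When all `N_i` are equal the adjusted and raw numerators coincide.
#'
#' @param panel a [classify_rare()] result (or character vector of site ids).
#' @param counts count rows for one group covering every panel site.
#' @param group_id label for the result.
#' @return object of class `collapsed_counts`: `raw_minor`, `n_variants`,
#'   `per_site_N`, `harmonic_N`, `adj_minor`, `adj_total`.
#' @export
adjusted_collapsed_counts <- function(panel, counts, group_id = NULL) {
  sites <- if (inherits(panel, "rare_panel")) panel$sites else panel
  if (length(sites) == 0) stop_ctx("empty rare panel")
  sub <- counts[counts$site_id %in% sites, ]
  if (!is.null(sub$group_id) && length(unique(sub$group_id)) > 1)
    stop_ctx("counts must belong to a single group")
  if (is.null(group_id))
    group_id <- if (!is.null(sub$group_id)) unique(sub$group_id) else "group"
  missing_sites <- setdiff(sites, sub$site_id)
  if (length(missing_sites))
    stop_ctx("no counts for panel site(s): %s", paste(missing_sites, collapse = ", "))
  sub <- sub[match(sites, sub$site_id), ]
  if (any(sub$n_total <= 0))
    stop_ctx("site(s) with zero sequenced chromosomes in group %s: %s",
             group_id, paste(sub$site_id[sub$n_total <= 0], collapse = ", "))
  N <- harmonic_mean_size(sub$n_total)
  adj <- round_half_away(sum(sub$n_minor / sub$n_total) * N)
  structure(list(group_id = group_id,
                 raw_minor = as.integer(sum(sub$n_minor)),
                 raw_total = as.integer(sum(sub$n_total)),
                 n_variants = length(sites),
                 per_site_N = sub$n_total,
                 harmonic_N = N,
                 adj_minor = as.integer(adj),
                 adj_total = as.integer(round_half_away(N))),
            class = "collapsed_counts")
}

#' @export
print.collapsed_counts <- function(x, ...) {
  cat(sprintf("collapsed counts [%s]: adjusted %d/%d (raw %d over %d variants, harmonic N = %.1f)\n",
              x$group_id, x$adj_minor, x$adj_total, x$raw_minor, x$n_variants,
              x$harmonic_N))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-ordering convention: the p-value sums hypergeometric
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed the observed table's by more than a relative tolerance of
#' 1e-7. Probabilities are computed in log space for stability. A zero
#' margin gives p = 1 with a `degenerate` attribute.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = minor/major.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(13, 178, 3, 207)
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_ctx("cell counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  if (min(r1, r2, c1, c2) <= 0)
    return(structure(1, degenerate = TRUE))
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  k <- lo:hi
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  logp_obs <- logp[match(a, k)]
  p <- sum(exp(logp[logp <= logp_obs + log1p(1e-7)]))
  structure(min(1, p), degenerate = FALSE)
}

#' Collapsed rare-variant burden test between two groups
#'
#' Fisher's exact test on the harmonic-mean-adjusted collapsed table
#' `[adj_minor_a, adj_total_a - adj_minor_a; adj_minor_b, ...]`. Because the
#' published intermediate is ambiguous about the exact rounding stage, the
#' unadjusted raw-count test (raw minor alleles over summed per-site totals)
#' is always reported alongside as a sensitivity check.
#'
#' @param panel a [classify_rare()] result or site-id vector.
#' @param counts_a,counts_b count rows for the two groups.
#' @param group_a,group_b labels.
#' @return object of class `burden_result`: the two [collapsed_counts()],
#'   `p_fet`, `p_fet_raw`.
#' @export
burden_test <- function(panel, counts_a, counts_b,
                        group_a = NULL, group_b = NULL) {
  ca <- adjusted_collapsed_counts(panel, counts_a, group_a)
  cb <- adjusted_collapsed_counts(panel, counts_b, group_b)
  clamp <- function(x) {
    if (x$adj_minor > x$adj_total) {
      warning(sprintf("group %s: adjusted numerator exceeds total; clamped",
                      x$group_id), call. = FALSE)
      x$adj_minor <- x$adj_total
    }
    x
  }
  ca <- clamp(ca); cb <- clamp(cb)
  p <- fisher_exact_2x2(ca$adj_minor, ca$adj_total - ca$adj_minor,
                        cb$adj_minor, cb$adj_total - cb$adj_minor)
  p_raw <- fisher_exact_2x2(ca$raw_minor, ca$raw_total - ca$raw_minor,
                            cb$raw_minor, cb$raw_total - cb$raw_minor)
  structure(list(group_a = ca, group_b = cb,
                 p_fet = as.numeric(p), p_fet_raw = as.numeric(p_raw)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("burden test %s vs %s: %s vs %s, P_FET(1df) = %s (raw-count P = %s)\n",
              x$group_a$group_id, x$group_b$group_id,
              format_nN(x$group_a$adj_minor, x$group_a$adj_total),
              format_nN(x$group_b$adj_minor, x$group_b$adj_total),
              format_pval(x$p_fet), format_pval(x$p_fet_raw)))
  invisible(x)
}

#' Bonferroni thresholding over trait contrasts
#'
#' Significance at `p < alpha / k`; the capped adjusted p-value
#' `min(1, k p)` is reported as well. The study convention is k = 5 (SD
#' overall plus the four specific dependence traits), giving a 0.01
#' threshold at alpha = 0.05.
#'
#' @param p_values numeric vector.
#' @param k number of comparisons.
#' @param alpha family-wise error target.
#' @return data frame with `p`, `p_bonf`, `significant`; the threshold is in
#'   attribute `"threshold"`.
#' @export
#' @examples
#' bonferroni_adjust(c(0.007, 0.026, 0.3))
bonferroni_adjust <- function(p_values, k = 5, alpha = 0.05) {
  stopifnot(k >= 1)
  out <- data.frame(p = p_values,
                    p_bonf = pmin(1, k * p_values),
                    significant = p_values < alpha / k)
  attr(out, "threshold") <- alpha / k
  out
}

#' Burden tests across the study's trait contrasts
#'
#' Runs the collapsed burden test per population for the SD case-control
#' contrasts (SD overall and, with subject-level data, AD/CD/OD/MjD, whose
#' case groups are non-exclusive subsets of the SD cases against the same
#' screened controls) and the three BMI contrasts against the normal-weight
#' group (subject-level data only; SD cases and controls pooled). On a
#' count-only study, contrasts that need subject-level detail are skipped
#' with a notice in the result.
#'
#' @param study a [cohort_study()].
#' @param panel optional [classify_rare()] result; classified from the
#'   study's counts by default.
#' @param populations populations to test.
#' @param contrasts subset of `c("sd","ad","cd","od","mjd","overweight",`
#'   `"obese","overweight_obese")`.
#' @param maf_threshold passed to [classify_rare()] when `panel` is NULL.
#' @param k,alpha Bonferroni settings applied over the SD-trait contrasts.
#' @return data frame with one row per population x contrast, plus attributes
#'   `panel` and `skipped`.
#' @export
burden_contrasts <- function(study, panel = NULL,
                             populations = c("AA", "EA"),
                             contrasts = c("sd", "ad", "cd", "od", "mjd",
                                           "overweight", "obese",
                                           "overweight_obese"),
                             maf_threshold = 0.012, k = 5, alpha = 0.05) {
  stopifnot(inherits(study, "cohort_study"))
  if (is.null(panel)) panel <- classify_rare(study$counts, maf_threshold)
  subject_level <- study$provenance == "SUBJECT_LEVEL"
  rows <- list(); skipped <- character()
  group_counts <- function(sel) {
    counts_from_genotypes(study$genotypes, list(g = sel))
  }
  for (pop in populations) {
    popl <- tolower(pop)
    for (ct in contrasts) {
      if (ct %in% SD_TRAITS) {
        if (ct == "sd") {
          if (subject_level) {
            sub <- study$subjects
            sel_a <- sub$population == pop & sub$status == "case"
            sel_b <- sub$population == pop & sub$status == "control"
            ca <- group_counts(sel_a); cb <- group_counts(sel_b)
          } else {
            ca <- study$counts[study$counts$group_id == paste0(popl, "_case"), ]
            cb <- study$counts[study$counts$group_id == paste0(popl, "_ctrl"), ]
          }
        } else {
          if (!subject_level) {
            skipped <- c(skipped, paste(pop, ct, sep = ":"))
            next
          }
          sub <- study$subjects
          sel_a <- sub$population == pop & sub$status == "case" & sub[[ct]]
          sel_b <- sub$population == pop & sub$status == "control"
          ca <- group_counts(sel_a); cb <- group_counts(sel_b)
        }
        lab_a <- paste0(popl, "_", ct, "_case"); lab_b <- paste0(popl, "_ctrl")
      } else {
        if (!subject_level) {
          skipped <- c(skipped, paste(pop, ct, sep = ":"))
          next
        }
        sub <- study$subjects
        base <- sub$population == pop & sub$status %in% c("case", "control")
        cond <- switch(ct,
          overweight = sub$bmi_class == "OVERWEIGHT",
          obese = sub$bmi_class == "OBESE",
          overweight_obese = sub$bmi_class %in% c("OVERWEIGHT", "OBESE"))
        sel_b <- base & sub$bmi_class == "NORMAL"
        sel_a <- base & cond
        ca <- group_counts(sel_b); cb <- group_counts(sel_a)
        ## conditioned group listed second to mirror "normal vs X" layout
        lab_a <- paste0(popl, "_normal"); lab_b <- paste0(popl, "_", ct)
      }
      bt <- burden_test(panel, ca, cb, lab_a, lab_b)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, contrast = ct,
        counts_a = format_nN(bt$group_a$adj_minor, bt$group_a$adj_total),
        counts_b = format_nN(bt$group_b$adj_minor, bt$group_b$adj_total),
        raw_a = bt$group_a$raw_minor, raw_b = bt$group_b$raw_minor,
        p_fet = bt$p_fet, p_fet_raw = bt$p_fet_raw)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sd_rows <- out$contrast %in% SD_TRAITS
  out$significant_bonferroni <- NA
  if (any(sd_rows)) {
    adj <- bonferroni_adjust(out$p_fet[sd_rows], k = k, alpha = alpha)
    out$significant_bonferroni[sd_rows] <- adj$significant
  }
  attr(out, "panel") <- panel
  attr(out, "skipped") <- skipped
  out
}
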