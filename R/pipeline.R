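## End-to-end orchestration: cohort load (or synthesis) -> variant count
## table -> common-variant association -> haplotype analysis -> rare-variant
## burden -> retrospective power, with deterministic TSV report rendering.

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `mode` ("fixture", "preset" or "files"), `fixture`,
#' `phenotypes`, `vcf`, `out_dir`, `seed`, `n_perm`, `maf_threshold`,
#' `alpha`, `k`, and `effects` (a mapping passed to [effect_spec()] in
#' preset mode).
#'
#' @param path YAML file.
#' @return config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mode)) stop_ctx("%s: 'mode' is required", path)
  cfg
}

#' Render a count table for display
#'
#' "n/N" cells per group plus pooled case and control MAFs rounded to three
#' decimals.
#'
#' @param study a [cohort_study()].
#' @return data frame ready for [write_tsv()]-style output.
#' @export
render_count_table <- function(study) {
  counts <- study$counts
  sites <- if (!is.null(study$genotype_sites)) study$genotype_sites
           else study$genotypes$sites
  out <- sites[, intersect(c("site_id", "exon", "region", "dbsnp", "effect"),
                           names(sites))]
  meta <- parse_group_id(unique(counts$group_id))
  for (g in unique(counts$group_id)) {
    sub <- counts[counts$group_id == g, ]
    ix <- match(out$site_id, sub$site_id)
    out[[g]] <- format_nN(sub$n_minor[ix], sub$n_total[ix])
  }
  pooled_freq <- function(stratum) {
    gs <- meta$group_id[meta$stratum == stratum]
    vapply(out$site_id, function(s) {
      sub <- counts[counts$site_id == s & counts$group_id %in% gs, ]
      if (sum(sub$n_total) == 0) NA_real_ else
        round(compute_maf(sub), 3)
    }, numeric(1))
  }
  if (any(meta$stratum == "case")) out$maf_case <- pooled_freq("case")
  if (any(meta$stratum == "ctrl")) out$maf_ctrl <- pooled_freq("ctrl")
  rownames(out) <- NULL
  out
}

#' Render burden results as a report table
#'
#' @param burden data frame from [burden_contrasts()].
#' @return data frame with "n/N" count cells and formatted p-values.
#' @export
render_burden_table <- function(burden) {
  data.frame(population = burden$population, contrast = burden$contrast,
             counts = paste(burden$counts_a, burden$counts_b, sep = ", "),
             p_fet_1df = format_pval(burden$p_fet),
             p_fet_raw = format_pval(burden$p_fet_raw),
             significant_bonferroni = burden$significant_bonferroni)
}

#' Run the full analysis pipeline
#'
#' Stages: input (count fixture, packaged preset simulation, or phenotype
#' TSV + VCF) -> variant count table -> common-variant association (SD
#' traits and the three BMI models, both common sites, per population) ->
#' two-locus haplotype LD and association -> collapsed rare-variant burden
#' -> retrospective minimum detectable odds ratios. Count-only input runs
#' the count-level stages and reports the subject-level stages as skipped.
#' All randomness is governed by `config$seed`; outputs are byte-identical
#' across runs with the same config and seed.
#'
#' @param config list (see [read_pipeline_config()]).
#' @return list of result objects, invisibly; TSVs are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop_ctx("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_perm <- config$n_perm %||% 1000
  maf_threshold <- config$maf_threshold %||% 0.012
  alpha <- config$alpha %||% 0.05
  k <- config$k %||% 5
  seed <- config$seed %||% 1L
  mode <- config$mode %||% "fixture"
  log_msg <- function(...) message("[pipeline] ", sprintf(...))

  log_msg("stage input: mode=%s seed=%d", mode, seed)
  study <- switch(mode,
    fixture = load_count_fixture(config$fixture %||% "pomc_exon_counts"),
    preset = {
      eff <- if (is.null(config$effects)) effect_spec(burden_or_sd = 3.3,
                                                      common_or_bmi = 2.0)
             else do.call(effect_spec, config$effects)
      simulate_cohort(pomc_preset(effects = eff, seed = seed))
    },
    files = {
      subjects <- load_phenotypes(config$phenotypes)
      gm <- load_genotypes(config$vcf, subjects = subjects)
      cohort_study(genotypes = gm, subjects = subjects,
                   provenance = "SUBJECT_LEVEL")
    },
    stop_ctx("unknown mode: %s", mode))
  subject_level <- study$provenance == "SUBJECT_LEVEL"
  results <- list(study = study)

  log_msg("stage counts: %d sites", length(unique(study$counts$site_id)))
  write_tsv(render_count_table(study), file.path(out_dir, "variant_table.tsv"))
  write_count_fixture(study, file.path(out_dir, "count_table.tsv"))

  panel <- classify_rare(study$counts, maf_threshold)
  log_msg("stage panel: %d rare sites, %d excluded as non-rare (%s)",
          length(panel$sites), length(panel$common_sites),
          paste(panel$common_sites, collapse = ", "))
  ## single-marker stages run on genuinely common sites only; borderline
  ## sites just above the rare threshold have degenerate per-stratum tables
  cls <- panel$classification
  common_sites <- cls$site_id[cls$maf_class >= 0.05]
  if (length(common_sites) > 2) {
    ord <- order(cls$maf_class[match(common_sites, cls$site_id)],
                 decreasing = TRUE)
    common_sites <- common_sites[ord[1:2]]
  }

  if (subject_level && length(common_sites)) {
    log_msg("stage common association (n_perm=%d)", n_perm)
    rows <- list()
    i <- 0L
    for (site in common_sites) for (p in c("AA", "EA")) {
      for (tr in SD_TRAITS) {
        i <- i + 1L
        r <- tryCatch(run_sd_assoc(study, site, tr, p, n_perm = n_perm,
                                   seed = seed + i), error = function(e) NULL)
        if (is.null(r)) {
          log_msg("common association %s %s %s: untestable, skipped",
                  site, p, tr)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          site = site, population = p, contrast = tr,
          freq = sprintf("%.3f/%.3f", r$freq_case, r$freq_ctrl),
          chi2 = sprintf("%.2f", r$allelic$chi2),
          p_obs = format_pval(r$allelic$p_obs),
          or = sprintf("%.2f (%.2f-%.2f)", r$allelic$or,
                       r$allelic$ci95[1], r$allelic$ci95[2]),
          p_emp = format_pval(r$allelic$p_emp),
          stat = if (r$logistic$converged) sprintf("%.2f", r$logistic$stat) else ".",
          p_adj = format_pval(r$logistic$p_adj),
          or_adj = if (r$logistic$converged)
            sprintf("%.2f (%.2f-%.2f)", r$logistic$or_adj,
                    r$logistic$ci95[1], r$logistic$ci95[2]) else ".")
      }
      for (m in names(BMI_MODELS)) {
        i <- i + 1L
        r <- tryCatch(run_bmi_contrasts(study, site, m, p, n_perm = n_perm,
                                        seed = seed + i),
                      error = function(e) NULL)
        if (is.null(r)) {
          log_msg("BMI contrast %s %s %s: untestable, skipped", site, p, m)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          site = site, population = p, contrast = paste0("bmi_", m),
          freq = sprintf("%.3f/%.3f", r$freq_cond, r$freq_comp),
          chi2 = sprintf("%.2f", r$allelic$chi2),
          p_obs = format_pval(r$allelic$p_obs),
          or = sprintf("%.2f (%.2f-%.2f)", r$allelic$or,
                       r$allelic$ci95[1], r$allelic$ci95[2]),
          p_emp = format_pval(r$allelic$p_emp),
          stat = if (r$logistic$converged) sprintf("%.2f", r$logistic$stat) else ".",
          p_adj = format_pval(r$logistic$p_adj),
          or_adj = if (r$logistic$converged)
            sprintf("%.2f (%.2f-%.2f)", r$logistic$or_adj,
                    r$logistic$ci95[1], r$logistic$ci95[2]) else ".")
      }
    }
    common_tab <- do.call(rbind, rows)
    results$common <- common_tab
    write_tsv(common_tab, file.path(out_dir, "common_assoc.tsv"))

    log_msg("stage haplotype")
    hap_rows <- list()
    for (p in c("AA", "EA")) {
      sel <- study$subjects$population == p &
        study$subjects$status %in% c("case", "control")
      keep_bmi <- sel & study$subjects$bmi_class %in%
        c("NORMAL", "OVERWEIGHT", "OBESE")
      lab <- factor(ifelse(study$subjects$bmi_class[keep_bmi] == "NORMAL",
                           "normal", "elevated"),
                    levels = c("elevated", "normal"))
      ha <- haplotype_assoc(study$genotypes$calls[keep_bmi, common_sites[1]],
                            study$genotypes$calls[keep_bmi, common_sites[2]],
                            lab, n_perm = n_perm, seed = seed + 1000 + match(p, c("AA", "EA")))
      t <- ha$tests
      t$population <- p
      t$dprime <- round(ha$ld$d_prime, 2)
      t$r2 <- round(ha$ld$r2, 2)
      hap_rows[[p]] <- t
    }
    hap_tab <- do.call(rbind, hap_rows)
    rownames(hap_tab) <- NULL
    hap_tab$freq_pooled <- round(hap_tab$freq_pooled, 4)
    hap_tab$freq1 <- round(hap_tab$freq1, 4)
    hap_tab$freq2 <- round(hap_tab$freq2, 4)
    hap_tab$count1 <- round(hap_tab$count1, 2)
    hap_tab$count2 <- round(hap_tab$count2, 2)
    hap_tab$chi2 <- round(hap_tab$chi2, 3)
    hap_tab$p_obs <- format_pval(hap_tab$p_obs)
    hap_tab$p_emp <- format_pval(hap_tab$p_emp)
    results$haplotype <- hap_tab
    write_tsv(hap_tab, file.path(out_dir, "haplotype_assoc.tsv"))
  } else {
    log_msg("stage common association: SKIPPED (count-only input; subject-level data required)")
    log_msg("stage haplotype: SKIPPED (count-only input; subject-level data required)")
  }

  log_msg("stage burden (threshold %g)", maf_threshold)
  burden <- burden_contrasts(study, panel = panel, k = k, alpha = alpha)
  skipped <- attr(burden, "skipped")
  if (length(skipped))
    log_msg("burden contrasts unavailable on this input: %s",
            paste(skipped, collapse = " "))
  results$burden <- burden
  write_tsv(render_burden_table(burden), file.path(out_dir, "burden.tsv"))

  log_msg("stage power")
  group_n <- study$group_n
  pw_rows <- list()
  if (!is.null(group_n) && length(common_sites)) {
    for (site in common_sites) for (p in c("AA", "EA")) {
      pl <- tolower(p)
      ctrl <- study$counts[study$counts$site_id == site &
                           study$counts$group_id == paste0(pl, "_ctrl"), ]
      if (nrow(ctrl) == 0 || ctrl$n_total == 0) next
      p0 <- ctrl$n_minor / ctrl$n_total
      if (p0 <= 0 || p0 >= 1) next
      res <- min_detectable_or(p0, group_n[[paste0(pl, "_case")]],
                               group_n[[paste0(pl, "_ctrl")]], alpha = alpha)
      pw_rows[[length(pw_rows) + 1L]] <- data.frame(
        site = site, population = p, p0 = round(p0, 3),
        min_or = round(res$or, 2), power = 0.80)
    }
  }
  if (length(pw_rows)) {
    pw <- do.call(rbind, pw_rows)
    results$power <- pw
    write_tsv(pw, file.path(out_dir, "power.tsv"))
  }

  prov <- data.frame(
    key = c("mode", "seed", "n_perm", "maf_threshold", "alpha", "k",
            "provenance", "n_sites", "n_rare"),
    value = c(mode, seed, n_perm, maf_threshold, alpha, k, study$provenance,
              length(unique(study$counts$site_id)), length(panel$sites)))
  write_tsv(prov, file.path(out_dir, "provenance.tsv"))
  log_msg("done: outputs in %s", out_dir)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
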