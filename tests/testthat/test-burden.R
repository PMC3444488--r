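test_that("rare classification reproduces the published 21-variant panel", {
  fx <- load_count_fixture("pomc_exon_counts")
  panel <- classify_rare(fx$counts)
  expect_length(panel$sites, 21)
  expect_setequal(panel$common_sites, c("c.560_561insAGCAGCGGC", "c.1130C>T"))
  expect_true("c.61A>G" %in% panel$sites)     # the MAF 0.011 site is kept
  # nominal 1% threshold drops that site
  strict <- classify_rare(fx$counts, maf_threshold = 0.01)
  expect_false("c.61A>G" %in% strict$sites)
  expect_length(strict$sites, 20)
})

test_that("rare threshold is strict and degenerate sites are excluded", {
  counts <- rbind(
    data.frame(site_id = "s1", group_id = c("aa_case", "aa_ctrl"),
               n_minor = c(12, 12), n_total = c(1000, 1000)),
    data.frame(site_id = "s2", group_id = c("aa_case", "aa_ctrl"),
               n_minor = c(11, 0), n_total = c(1000, 1000)),
    data.frame(site_id = "s3", group_id = c("aa_case", "aa_ctrl"),
               n_minor = c(0, 0), n_total = c(0, 0)))
  expect_warning(panel <- classify_rare(counts, maf_threshold = 0.012),
                 "zero sequenced")
  expect_equal(panel$sites, "s2")            # 0.012 is excluded: strict <
  expect_equal(panel$common_sites, "s1")
})

test_that("harmonic mean size follows n / sum(1/N_i)", {
  expect_equal(harmonic_mean_size(rep(100, 5)), 100)
  expect_equal(harmonic_mean_size(73), 73)
  fx <- load_count_fixture("pomc_exon_counts")
  panel <- classify_rare(fx$counts)
  aa_case <- fx$counts[fx$counts$group_id == "aa_case" &
                       fx$counts$site_id %in% panel$sites, ]
  # direct evaluation oracle over the 21 AA-case denominators
  expect_equal(harmonic_mean_size(aa_case$n_total),
               21 / sum(1 / aa_case$n_total))
  expect_equal(harmonic_mean_size(aa_case$n_total), 279.78, tolerance = 1e-4)
  expect_error(harmonic_mean_size(c(100, 0)), "positive")
  expect_error(harmonic_mean_size(numeric(0)), "empty")
  # harmonic <= arithmetic mean, equality only when all equal
  set.seed(2)
  for (i in 1:20) {
    N <- sample(50:400, 8)
    expect_lte(harmonic_mean_size(N), mean(N))
  }
})

test_that("adjusted collapsed numerators reproduce the published collapsed table", {
  fx <- load_count_fixture("pomc_exon_counts")
  panel <- classify_rare(fx$counts)
  want_adj <- c(aa_case = 16L, aa_ctrl = 4L, ea_case = 14L, ea_ctrl = 18L)
  for (g in names(want_adj)) {
    cc <- adjusted_collapsed_counts(panel,
                                    fx$counts[fx$counts$group_id == g, ])
    expect_identical(cc$adj_minor, want_adj[[g]])
    expect_identical(cc$raw_minor, as.integer(want_adj[[g]]))
    expect_true(cc$harmonic_N >= min(cc$per_site_N) &&
                cc$harmonic_N <= max(cc$per_site_N))
  }
})

test_that("adjusted equals raw numerator when all denominators are equal", {
  counts <- data.frame(site_id = paste0("s", 1:4), group_id = "g",
                       n_minor = c(3, 0, 1, 2), n_total = 200)
  cc <- adjusted_collapsed_counts(paste0("s", 1:4), counts)
  expect_identical(cc$adj_minor, cc$raw_minor)
  expect_equal(cc$harmonic_N, 200)
  expect_error(adjusted_collapsed_counts(paste0("s", 1:5), counts),
               "no counts for panel site")
})

test_that("Fisher exact matches the R reference implementation and handles degenerate tables", {
  expect_equal(as.numeric(fisher_exact_2x2(0, 10, 0, 10)), 1)
  expect_equal(as.numeric(fisher_exact_2x2(5, 5, 5, 5)), 1)
  expect_true(attr(fisher_exact_2x2(0, 10, 0, 10), "degenerate"))
  expect_equal(as.numeric(fisher_exact_2x2(13, 178, 3, 207)),
               fisher.test(matrix(c(13, 178, 3, 207), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  set.seed(33)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(2, 8, 25), 1))
    if (min(cells[1] + cells[2], cells[3] + cells[4],
            cells[1] + cells[3], cells[2] + cells[4]) == 0) next
    expect_equal(as.numeric(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])),
                 fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("burden test is null for identical groups and orders effect vs null p-values", {
  counts <- data.frame(site_id = paste0("s", 1:3), group_id = "a",
                       n_minor = c(2, 1, 0), n_total = c(180, 200, 190))
  counts_b <- transform(counts, group_id = "b")
  bt <- burden_test(paste0("s", 1:3), counts, counts_b)
  expect_equal(bt$p_fet, 1)
  # adding a case-only carrier never increases the case-vs-control burden p
  p_prev <- 1
  cb <- counts_b
  for (extra in 1:6) {
    ca <- counts
    ca$n_minor[1] <- ca$n_minor[1] + extra
    bt <- burden_test(paste0("s", 1:3), ca, cb)
    expect_lte(bt$p_fet, p_prev + 1e-12)
    p_prev <- bt$p_fet
  }
})

test_that("burden contrasts cover the five SD traits and three BMI models on synthetic cohorts", {
  st <- simulate_cohort(toy_config(55, n_case = 120, n_ctrl = 120))
  panel <- paste0("rare", 1:6)
  out <- burden_contrasts(st, panel = structure(
    list(sites = panel, common_sites = c("cmn1", "cmn2"),
         maf_threshold = 0.012, basis = "fixed"), class = "rare_panel"),
    populations = "AA")
  expect_setequal(out$contrast,
                  c("sd", "ad", "cd", "od", "mjd",
                    "overweight", "obese", "overweight_obese"))
  expect_true(all(out$p_fet > 0 & out$p_fet <= 1))
  expect_false(anyNA(out$significant_bonferroni[out$contrast %in%
                                                c("sd", "ad", "cd", "od", "mjd")]))
  # count-only input: only the SD contrast is computable
  fx <- load_count_fixture("pomc_exon_counts")
  out_fx <- burden_contrasts(fx)
  expect_setequal(out_fx$contrast, "sd")
  expect_true(length(attr(out_fx, "skipped")) > 0)
  expect_equal(out_fx$counts_a[out_fx$population == "AA"], "16/280")
  expect_equal(out_fx$counts_b[out_fx$population == "AA"], "4/211")
})

test_that("Bonferroni adjustment over five trait contrasts", {
  adj <- bonferroni_adjust(c(0.007, 0.026, 0.3), k = 5, alpha = 0.05)
  expect_equal(attr(adj, "threshold"), 0.01)
  expect_equal(adj$significant, c(TRUE, FALSE, FALSE))
  expect_equal(adj$p_bonf, c(0.035, 0.13, 1))
  one <- bonferroni_adjust(0.03, k = 1, alpha = 0.05)
  expect_true(one$significant)
})
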