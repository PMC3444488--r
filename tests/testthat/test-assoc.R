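test_that("HWE chi-square is zero at perfect proportions and exact matches enumeration", {
  perfect <- hwe_test(25, 50, 25, method = "chi2")
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p, 1)
  expect_equal(hwe_test(10, 0, 0, method = "exact")$p, 1)   # monomorphic
  expect_equal(hwe_test(0, 0, 7, method = "chi2")$p, 1)
  expect_error(hwe_test(-1, 2, 3), "non-negative")

  # brute-force enumeration oracle: all heterozygote counts compatible with
  # the observed allele totals, exact multinomial probabilities
  enum_exact <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    na <- 2 * naa + nAa; nA <- 2 * nAA + nAa
    rare <- min(na, nA)
    hets <- seq(rare %% 2, rare, by = 2)
    pr <- vapply(hets, function(h) {
      aa <- (min(na, nA) - h) / 2; AA <- (max(na, nA) - h) / 2
      exp(lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
            h * log(2) + lfactorial(na) + lfactorial(nA) - lfactorial(2 * n))
    }, numeric(1))
    pr <- pr / sum(pr)
    obs <- pr[match(nAa, hets)]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }
  for (cnt in list(c(3, 5, 2), c(40, 12, 8), c(1, 1, 5), c(90, 18, 3))) {
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3], method = "exact")$p,
                 enum_exact(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("allelic chi-square matches the closed form and known hand values", {
  r0 <- allelic_chi2(10, 90, 10, 90)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_obs, 1)
  expect_equal(r0$or, 1)

  r1 <- allelic_chi2(30, 70, 15, 85)
  expect_equal(r1$chi2, 6.451613, tolerance = 1e-6)
  expect_equal(r1$or, 2.428571, tolerance = 1e-6)

  r2 <- allelic_chi2(20, 80, 10, 90)
  expect_equal(r2$or, 2.25)
  expect_equal(r2$ci95, c(0.9942, 5.0917), tolerance = 1e-3)

  expect_error(allelic_chi2(0, 0, 3, 7), "zero margin")

  # independent contingency-table implementation on random tables
  set.seed(42)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    mine <- allelic_chi2(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(chisq.test(matrix(cells, 2, 2, byrow = TRUE),
                                       correct = FALSE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_obs, ref$p.value, tolerance = 1e-10)
  }
})

test_that("odds ratio symmetry: invariant under double swap, reciprocal under single", {
  r <- allelic_chi2(23, 77, 11, 89)
  swapped_both <- allelic_chi2(89, 11, 77, 23)
  swapped_rows <- allelic_chi2(11, 89, 23, 77)
  expect_equal(r$or, swapped_both$or)
  expect_equal(r$or, 1 / swapped_rows$or)
  # Haldane-Anscombe correction engages only on zero cells
  rz <- allelic_chi2(0, 50, 5, 45)
  expect_equal(rz$or, (0.5 * 45.5) / (50.5 * 5.5))
})

test_that("permutation empirical p is deterministic, bounded away from zero, and 1 for invariant statistics", {
  dos <- c(2, 2, 1, 1, 0, 0, 0, 0)
  lab <- factor(rep(c("g1", "g2"), each = 4))
  p1 <- permutation_empirical_p(dos, lab, n_perm = 999, seed = 5)
  p2 <- permutation_empirical_p(dos, lab, n_perm = 999, seed = 5)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 1000)
  # constant dosage: statistic identical under all labelings
  expect_equal(permutation_empirical_p(rep(1, 10),
                                       factor(rep(c("a", "b"), 5)),
                                       n_perm = 99, seed = 1), 1)
  expect_error(permutation_empirical_p(dos, factor(rep("a", 8))), "two levels")
})

test_that("permutation p approaches the asymptotic p for common variants at n = 2000", {
  set.seed(88)
  dos <- rbinom(2000, 2, 0.3)
  lab <- factor(rep(c("case", "ctrl"), each = 1000))
  a <- sum(dos[lab == "case"]); c_ <- sum(dos[lab == "ctrl"])
  al <- allelic_chi2(a, 2000 - a, c_, 2000 - c_)
  p_emp <- permutation_empirical_p(dos, lab, n_perm = 4000, seed = 12)
  expect_lt(abs(p_emp - al$p_obs), 0.05)
})

test_that("logistic association recovers the null and flags separation", {
  set.seed(19)
  n <- 3000
  dos <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, 0.4)           # independent of dosage
  r <- logistic_assoc(y, dos, data.frame(age = rnorm(n, 40, 10)))
  expect_true(r$converged)
  expect_lt(abs(r$beta), 0.15)
  expect_equal(r$or_adj, exp(r$beta))
  # perfectly separated data must not yield a p-value
  sep <- logistic_assoc(c(rep(0, 20), rep(1, 20)),
                        c(rep(0, 20), rep(2, 20)))
  expect_false(sep$converged)
  expect_true(is.na(sep$p_adj))
})

test_that("unadjusted logistic p agrees with the allelic chi-square p within a factor of two", {
  set.seed(23)
  n <- 1000
  dos <- rbinom(n, 2, 0.25)
  y <- rbinom(n, 1, plogis(-0.4 + 0.35 * dos))
  a <- sum(dos[y == 1]); c_ <- sum(dos[y == 0])
  al <- allelic_chi2(a, 2 * sum(y) - a, c_, 2 * sum(!y) - c_)
  lg <- logistic_assoc(y, dos)
  ratio <- lg$p_adj / al$p_obs
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("BMI contrasts require subject-level data and detect a simulated EA-only effect", {
  fx <- load_count_fixture("pomc_exon_counts")
  expect_error(run_bmi_contrasts(fx, "c.1130C>T", "overweight"),
               "subject-level")
  # EA-only effect at the 3'UTR-like site: EA contrast detects it, AA is null
  cfg <- pomc_preset(effects = effect_spec(burden_or_sd = 1,
                                           common_or_bmi = 2.5),
                     seed = 404)
  cfg$n_aa_case <- 400; cfg$n_aa_ctrl <- 400
  cfg$n_ea_case <- 400; cfg$n_ea_ctrl <- 400
  st <- simulate_cohort(cfg)
  ea <- run_bmi_contrasts(st, "c.1130C>T", "overweight_obese", "EA")
  aa <- run_bmi_contrasts(st, "c.1130C>T", "overweight_obese", "AA")
  expect_lt(ea$logistic$p_adj, 0.05)
  expect_gt(aa$logistic$p_adj, 0.05)
  expect_gt(ea$logistic$beta, 0)
})
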