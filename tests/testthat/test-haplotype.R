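test_that("EM equals direct gamete counting when no double heterozygotes exist", {
  # dosage pairs chosen so every subject's phase is determined
  g1 <- c(0, 0, 2, 2, 1, 1, 0)
  g2 <- c(0, 2, 0, 2, 0, 2, 1)
  em <- em_haplotype_freqs(g1, g2)
  # direct count over the 14 gametes: AB 4, Ab 4, aB 3, ab 3
  expect_equal(unname(em$freqs), c(4, 4, 3, 3) / 14, tolerance = 1e-9)
  expect_true(em$converged)
  # single subject, both loci homozygous major
  one <- em_haplotype_freqs(0, 0)
  expect_equal(unname(one$freqs["AB"]), 1)
})

test_that("EM frequencies sum to one and the log-likelihood never decreases", {
  set.seed(14)
  for (i in 1:10) {
    d <- draw_two_locus(60, c(0.4, 0.2, 0.15, 0.25))
    em <- em_haplotype_freqs(d$g1, d$g2)
    expect_equal(sum(em$freqs), 1, tolerance = 1e-9)
    expect_true(all(em$freqs >= 0))
    expect_true(all(diff(em$loglik_trace) >= -1e-8))
  }
})

test_that("EM matches a likelihood grid-search oracle on instances with double heterozygotes", {
  set.seed(77)
  for (i in 1:5) {
    d <- draw_two_locus(40, c(0.35, 0.25, 0.15, 0.25))
    if (!any(d$g1 == 1 & d$g2 == 1)) next
    em <- em_haplotype_freqs(d$g1, d$g2)
    n <- length(d$g1)
    p1 <- sum(d$g1) / (2 * n); p2 <- sum(d$g2) / (2 * n)
    n9 <- table(factor(d$g1, 0:2), factor(d$g2, 0:2))
    lo <- max(0, (1 - p1) + (1 - p2) - 1); hi <- min(1 - p1, 1 - p2)
    grid <- seq(lo, hi, length.out = 20001)
    ll <- vapply(grid, hap_loglik_given_margins, numeric(1), p1 = p1, p2 = p2,
                 n9 = n9)
    expect_lt(abs(unname(em$freqs["AB"]) - grid[which.max(ll)]), 1e-4)
  }
})

test_that("EM is invariant to subject order and equivariant to allele swaps", {
  set.seed(5)
  d <- draw_two_locus(80, c(0.5, 0.2, 0.1, 0.2))
  em <- em_haplotype_freqs(d$g1, d$g2)
  perm <- sample(80)
  em_perm <- em_haplotype_freqs(d$g1[perm], d$g2[perm])
  expect_equal(em$freqs, em_perm$freqs, tolerance = 1e-9)
  # swapping allele coding at locus 1 permutes AB<->aB, Ab<->ab
  em_swap <- em_haplotype_freqs(2 - d$g1, d$g2)
  expect_equal(unname(em_swap$freqs[c("aB", "ab", "AB", "Ab")]),
               unname(em$freqs), tolerance = 1e-8)
})

test_that("estimated frequencies on phased-simulated data lie within 3 SE of truth", {
  truth <- c(0.45, 0.2, 0.1, 0.25)
  set.seed(99)
  d <- draw_two_locus(5000, truth)
  em <- em_haplotype_freqs(d$g1, d$g2)
  se <- sqrt(truth * (1 - truth) / (2 * 5000))
  expect_true(all(abs(em$freqs - truth) < 3 * se))
})

test_that("LD statistics follow the closed forms", {
  perfect <- ld_stats(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$d_prime, 1)
  expect_equal(perfect$r2, 1)
  eq <- ld_stats(c(0.35, 0.35, 0.15, 0.15))  # product of margins
  expect_equal(eq$d_prime, 0)
  expect_equal(eq$r2, 0)
  hand <- ld_stats(c(0.6, 0.1, 0.05, 0.25))
  expect_equal(hand$d, 0.6 - 0.7 * 0.65)
  expect_equal(hand$d_prime, 0.145 / min(0.7 * 0.35, 0.3 * 0.65),
               tolerance = 1e-9)
  expect_equal(hand$r2, 0.145^2 / (0.7 * 0.3 * 0.65 * 0.35), tolerance = 1e-9)
  mono <- ld_stats(c(0.7, 0.3, 0, 0))
  expect_false(mono$defined)
  expect_true(is.na(mono$d_prime))
})

test_that("haplotype test equals the single-marker test for a perfect-LD pair", {
  set.seed(120)
  # complete LD: locus 2 duplicates locus 1
  g1 <- rbinom(400, 2, 0.3)
  g2 <- g1
  lab <- factor(rep(c("x", "y"), each = 200))
  ha <- haplotype_assoc(g1, g2, lab)
  a <- sum(g1[lab == "x"]); c_ <- sum(g1[lab == "y"])
  single <- allelic_chi2(a, 400 - a, c_, 400 - c_)
  expect_equal(ha$tests$p_obs[ha$tests$haplotype == "ab"], single$p_obs,
               tolerance = 1e-9)
  expect_equal(ha$ld$d_prime, 1)
})

test_that("an effect carried on one haplotype makes that haplotype's test most significant", {
  set.seed(321)
  hf <- c(0.45, 0.2, 0.1, 0.25)
  d1 <- draw_two_locus(500, hf)
  # enrich haplotype 'ab' among group 1, spreading the deficit over the rest
  hf_shift <- c(0.420, 0.170, 0.075, 0.335)
  d2 <- draw_two_locus(500, hf_shift)
  g1 <- c(d2$g1, d1$g1); g2 <- c(d2$g2, d1$g2)
  lab <- factor(rep(c("grp1", "grp2"), each = 500))
  ha <- haplotype_assoc(g1, g2, lab, n_perm = 500, seed = 2)
  t <- ha$tests
  expect_equal(t$haplotype[which.min(t$p_obs)], "ab")
  expect_lt(t$p_emp[t$haplotype == "ab"], 0.05)
})

test_that("haplotypes with tiny expected counts are flagged unreliable", {
  set.seed(9)
  d <- draw_two_locus(60, c(0.94, 0.05, 0.005, 0.005))
  lab <- factor(rep(c("u", "v"), 30))
  ha <- haplotype_assoc(d$g1, d$g2, lab)
  expect_true(any(ha$tests$unreliable))
})
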