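# Shared in-code fixtures for the suite.

# Small synthetic site panel: two common sites and six rare sites spread over
# three amplicon segments.
toy_sites <- function() {
  s <- data.frame(
    site_id = c("cmn1", "cmn2", paste0("rare", 1:6)),
    exon = c(4, 4, 1, 3, 3, 4, 4, 4),
    region = c("CDS", "3UTR", "5UTR", "CDS", "CDS", "CDS", "CDS", "3UTR"),
    dbsnp = c("rs1", "rs2", rep(NA_character_, 6)),
    stringsAsFactors = FALSE)
  s$segment <- c("S2", "S3", "S1", "S2", "S2", "S2", "S3", "S3")
  s
}

toy_rare_freqs <- function() {
  setNames(c(0.02, 0.01, 0.015, 0.005, 0.01, 0.02), paste0("rare", 1:6))
}

# AA-only cohort config with configurable effects; defaults are null.
toy_config <- function(seed, n_case = 150, n_ctrl = 150,
                       effects = effect_spec(), pool_mult = 3) {
  simulation_config(
    n_aa_case = n_case, n_aa_ctrl = n_ctrl, n_ea_case = 0, n_ea_ctrl = 0,
    common_maf = list(aa = c(0.25, 0.15), ea = c(0.05, 0.20)),
    rare_freqs = list(aa = toy_rare_freqs(), ea = toy_rare_freqs()),
    sites = toy_sites(), common_sites = c("cmn1", "cmn2"),
    segment_dropout = matrix(c(0.10, 0.05, 0.08, 0.10, 0.05, 0.08), 3, 2,
                             dimnames = list(c("S1", "S2", "S3"),
                                             c("AA", "EA"))),
    effects = effects, seed = seed, pool_mult = pool_mult)
}

# Random dosage matrix with missingness, for counting oracles.
random_calls <- function(n_subj, sites, p_missing = 0.1) {
  calls <- matrix(sample(0:2, n_subj * nrow(sites), replace = TRUE,
                         prob = c(0.7, 0.25, 0.05)),
                  n_subj, nrow(sites), dimnames = list(NULL, sites$site_id))
  calls[matrix(runif(length(calls)) < p_missing, nrow(calls))] <- NA
  genotype_matrix(sites, calls)
}

# Independent multinomial log-likelihood of two-locus haplotype frequencies,
# for the EM grid-search oracle (one free parameter, margins fixed).
hap_loglik_given_margins <- function(fAB, p1, p2, n9) {
  f <- c(fAB, (1 - p1) - fAB, (1 - p2) - fAB, p1 + p2 - 1 + fAB)
  if (any(f < -1e-12)) return(-Inf)
  f <- pmax(f, 1e-300)
  P <- matrix(0, 3, 3)
  P[1, 1] <- f[1]^2; P[1, 3] <- f[2]^2; P[3, 1] <- f[3]^2; P[3, 3] <- f[4]^2
  P[1, 2] <- 2 * f[1] * f[2]; P[3, 2] <- 2 * f[3] * f[4]
  P[2, 1] <- 2 * f[1] * f[3]; P[2, 3] <- 2 * f[2] * f[4]
  P[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
  sum(n9[n9 > 0] * log(P[n9 > 0]))
}

# Draw unphased genotypes at two loci from a known haplotype table.
draw_two_locus <- function(n, hap_freqs) {
  hap <- matrix(sample.int(4L, 2 * n, replace = TRUE, prob = hap_freqs),
                ncol = 2)
  list(g1 = rowSums(matrix(c(0, 0, 1, 1)[hap], ncol = 2)),
       g2 = rowSums(matrix(c(0, 1, 0, 1)[hap], ncol = 2)))
}
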