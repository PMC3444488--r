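## Two-locus haplotype phasing by EM from unphased dosages, linkage
## disequilibrium statistics (D', r^2), and haplotype-based association using
## pooled-EM posterior fractional counts.
##
## Haplotypes are labelled AB / Ab / aB / ab where a and b are the counted
## (minor-coded) alleles at the two loci, so f(AB) is the frequency of the
## haplotype carrying neither counted allele.

HAP_LABELS <- c("AB", "Ab", "aB", "ab")

#' EM estimation of two-locus haplotype frequencies
#'
#' Only double heterozygotes have ambiguous phase; the EM splits each between
#' the coupling (AB/ab) and repulsion (Ab/aB) resolutions by their current
#' posterior odds. Initialisation is at linkage equilibrium (product of
#' observed allele frequencies), a single start: with two loci the observed
#' single-locus allele frequencies are fixed margins, leaving a
#' one-dimensional likelihood that is unimodal in practice. Subjects missing
#' either call are dropped.
#'
#' @param g1,g2 minor-allele dosage vectors (0/1/2, NA allowed) at the two
#'   sites.
#' @param tol convergence tolerance on the maximum frequency change.
#' @param max_iter iteration cap; exceeding it is reported as non-converged.
#' @return object of class `haplotype_table`: `freqs` (named AB/Ab/aB/ab),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `n` (subjects phased).
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-8, max_iter = 1000) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- as.integer(g1[keep]); g2 <- as.integer(g2[keep])
  n <- length(g1)
  if (n < 1) stop_ctx("no subject has complete calls at both sites")
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) stop_ctx("dosages must be 0/1/2")
  ## genotype class counts, n9[i+1, j+1] = #subjects with dosages (i, j)
  n9 <- matrix(0, 3, 3)
  for (k in seq_len(n)) n9[g1[k] + 1L, g2[k] + 1L] <- n9[g1[k] + 1L, g2[k] + 1L] + 1
  p1 <- sum(g1) / (2 * n)   # counted-allele frequency, locus 1
  p2 <- sum(g2) / (2 * n)
  ## haplotype counts determined regardless of phase (double hets excluded)
  ndh <- n9[2, 2]
  base <- c(
    AB = 2 * n9[1, 1] + n9[1, 2] + n9[2, 1],
    Ab = 2 * n9[1, 3] + n9[1, 2] + n9[2, 3],
    aB = 2 * n9[3, 1] + n9[2, 1] + n9[3, 2],
    ab = 2 * n9[3, 3] + n9[3, 2] + n9[2, 3])
  f <- c(AB = (1 - p1) * (1 - p2), Ab = (1 - p1) * p2,
         aB = p1 * (1 - p2), ab = p1 * p2)
  loglik_of <- function(f) {
    probs <- matrix(0, 3, 3)
    probs[1, 1] <- f["AB"]^2;            probs[1, 3] <- f["Ab"]^2
    probs[3, 1] <- f["aB"]^2;            probs[3, 3] <- f["ab"]^2
    probs[1, 2] <- 2 * f["AB"] * f["Ab"]; probs[3, 2] <- 2 * f["aB"] * f["ab"]
    probs[2, 1] <- 2 * f["AB"] * f["aB"]; probs[2, 3] <- 2 * f["Ab"] * f["ab"]
    probs[2, 2] <- 2 * f["AB"] * f["ab"] + 2 * f["Ab"] * f["aB"]
    sum(n9[n9 > 0] * log(probs[n9 > 0]))
  }
  trace <- loglik_of(f)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    w <- if (denom > 0) unname(f["AB"] * f["ab"] / denom) else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    f_new <- cnt / (2 * n)
    ll <- loglik_of(f_new)
    if (ll < trace[length(trace)] - 1e-8)
      stop_ctx("internal error: EM log-likelihood decreased")
    trace <- c(trace, ll)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(freqs = f, loglik = trace[length(trace)],
                 loglik_trace = trace, n_iter = it, converged = converged,
                 n = n),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("two-locus haplotype table (EM, %d subjects, %d iterations%s)\n",
              x$n, x$n_iter, if (x$converged) "" else ", NOT converged"))
  print(round(x$freqs, 4))
  invisible(x)
}

#' Linkage disequilibrium statistics from a haplotype table
#'
#' `D = f(AB) - pA pB`; `D' = |D| / Dmax` with
#' `Dmax = min(pA pb, pa pB)` for positive D and `min(pA pB, pa pb)` for
#' negative D; `r^2 = D^2 / (pA pa pB pb)`. Both are undefined (returned as
#' NA with `defined = FALSE`) when either locus is monomorphic.
#'
#' @param table a [em_haplotype_freqs()] result, or a numeric vector of four
#'   haplotype frequencies in AB/Ab/aB/ab order.
#' @return list with `d`, `d_prime`, `r2`, allele frequencies, `defined`.
#' @export
#' @examples
#' ld_stats(c(0.6, 0.1, 0.05, 0.25))
ld_stats <- function(table) {
  f <- if (inherits(table, "haplotype_table")) table$freqs else table
  stopifnot(length(f) == 4, all(f >= -1e-12), abs(sum(f) - 1) < 1e-6)
  f <- pmax(f, 0)
  names(f) <- HAP_LABELS
  pA <- f["AB"] + f["Ab"]; pB <- f["AB"] + f["aB"]
  pa <- 1 - pA; pb <- 1 - pB
  if (min(pA, pa, pB, pb) <= 0)
    return(list(d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                pA = unname(pA), pB = unname(pB), defined = FALSE))
  D <- unname(f["AB"] - pA * pB)
  d_max <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (pA * pa * pB * pb)
  list(d = D, d_prime = unname(d_prime), r2 = unname(r2),
       pA = unname(pA), pB = unname(pB), defined = TRUE)
}

## Per-subject expected (posterior fractional) haplotype counts, n x 4,
## under the pooled EM frequencies. Determined subjects get integer counts;
## double heterozygotes split between coupling and repulsion by w.
hap_posterior_counts <- function(g1, g2, freqs) {
  denom <- freqs["AB"] * freqs["ab"] + freqs["Ab"] * freqs["aB"]
  w <- if (denom > 0) unname(freqs["AB"] * freqs["ab"] / denom) else 0.5
  n <- length(g1)
  out <- matrix(0, n, 4, dimnames = list(NULL, HAP_LABELS))
  for (k in seq_len(n)) {
    i <- g1[k]; j <- g2[k]
    if (is.na(i) || is.na(j)) { out[k, ] <- NA_real_; next }
    if (i == 1 && j == 1) {
      out[k, ] <- c(w, 1 - w, 1 - w, w)
    } else {
      ## haplotype alleles determined: i copies of 'a' and j copies of 'b'
      lab1 <- paste0(if (i >= 1) "a" else "A", if (j >= 1) "b" else "B")
      lab2 <- paste0(if (i == 2) "a" else "A", if (j == 2) "b" else "B")
      out[k, lab1] <- out[k, lab1] + 1
      out[k, lab2] <- out[k, lab2] + 1
    }
  }
  out
}

#' Haplotype-based association between two strata
#'
#' Estimates haplotype frequencies by EM in the pooled sample, assigns each
#' subject posterior fractional haplotype counts, and compares each
#' haplotype's count between the two strata with a 1-df chi-square on the
#' (possibly fractional) 2x2 table. The empirical p permutes stratum labels
#' while re-using the fixed posterior assignment. Haplotypes with expected
#' count below 1 in either stratum are flagged unreliable.
#'
#' @param g1,g2 dosage vectors at the two sites.
#' @param labels two-level factor of stratum membership (same length).
#' @param n_perm permutations for empirical p-values (0 to skip).
#' @param seed RNG seed for the permutations.
#' @param tol,max_iter passed to [em_haplotype_freqs()].
#' @return list with the pooled `table` (class `haplotype_table`), `ld`, and
#'   `tests`: a data frame with one row per haplotype (frequencies by
#'   stratum, chi2, p_obs, p_emp, unreliable flag).
#' @export
haplotype_assoc <- function(g1, g2, labels, n_perm = 0, seed = NULL,
                            tol = 1e-8, max_iter = 1000) {
  keep <- !is.na(g1) & !is.na(g2) & !is.na(labels)
  g1 <- g1[keep]; g2 <- g2[keep]
  labels <- factor(labels[keep])
  if (nlevels(labels) != 2L) stop_ctx("labels must have exactly two levels")
  em <- em_haplotype_freqs(g1, g2, tol = tol, max_iter = max_iter)
  if (!em$converged) stop_ctx("pooled EM did not converge")
  post <- hap_posterior_counts(g1, g2, em$freqs)
  s1 <- labels == levels(labels)[1]
  n1 <- sum(s1); n2 <- sum(!s1)
  x1 <- colSums(post[s1, , drop = FALSE])
  x2 <- colSums(post[!s1, , drop = FALSE])
  chi2 <- vapply(HAP_LABELS, function(h) {
    s <- chi2_2x2(x1[h], 2 * n1 - x1[h], x2[h], 2 * n2 - x2[h])
    ifelse(is.na(s), 0, s)
  }, numeric(1))
  p_obs <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p_emp <- rep(NA_real_, 4)
  if (n_perm > 0) {
    b <- with_seed(seed, {
      acc <- numeric(4)
      for (i in seq_len(n_perm)) {
        idx <- sample.int(n1 + n2, n1)
        x1p <- colSums(post[idx, , drop = FALSE])
        x2p <- (x1 + x2) - x1p
        sp <- vapply(seq_len(4), function(h) {
          s <- chi2_2x2(x1p[h], 2 * n1 - x1p[h], x2p[h], 2 * n2 - x2p[h])
          ifelse(is.na(s), 0, s)
        }, numeric(1))
        acc <- acc + (sp >= chi2 - 1e-12)
      }
      acc
    })
    p_emp <- (1 + b) / (1 + n_perm)
  }
  tests <- data.frame(
    haplotype = HAP_LABELS,
    freq_pooled = unname(em$freqs),
    freq1 = unname(x1 / (2 * n1)), freq2 = unname(x2 / (2 * n2)),
    count1 = unname(x1), count2 = unname(x2),
    chi2 = unname(chi2), p_obs = unname(p_obs), p_emp = p_emp,
    unreliable = unname(x1 < 1 | x2 < 1))
  list(table = em, ld = ld_stats(em), tests = tests,
       strata = setNames(c(n1, n2), levels(labels)))
}
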