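---
title: "Methods: candidate-gene resequencing association with rare-variant collapsing"
author: "pomcvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene resequencing association with rare-variant collapsing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomcvar)
```

## The study design

`pomcvar` implements the statistical pipeline of a candidate-gene exon
resequencing case-control study: all exons of *POMC* Sanger-sequenced in two
admixture-defined populations (280 African Americans, 308 European
Americans; 167/113 and 144/164 cases/controls), with lifetime substance
dependence (SD: alcohol, cocaine, opioid and/or marijuana dependence, any of
the four) and WHO BMI category as the phenotypes. Sequencing yielded 23
exonic variants: two common polymorphisms — a 9-bp in-frame coding insertion
(the insertion allele is the minor allele) and a 3'UTR SNP — and 21 rare
variants, 12 of them novel. The package ships the per-variant count table
(`load_count_fixture("pomc_exon_counts")`): minor-allele count *n* over
sequenced chromosomes *N* per population × SD stratum.

Two structural features of the data drive the methods:

* **Variable call rates across amplicons.** The four exons (exon 4 in three
  pieces) amplified with different success, so the per-variant chromosome
  totals *N~i~* differ — visible in the table as five families of
  denominators. `segments_from_counts()` recovers this amplicon structure by
  grouping sites with identical denominator vectors.
* **Rarity.** Twenty-one variants are individually too rare to test, so they
  are collapsed into one burden variable before a single exact test.

A note on the cohort sizes: the source material reports the EA case count
inconsistently (114 in one summary, 144 in the cohort table); 144 is the
value consistent with the population totals (308 EA, 277 controls) and is
used throughout, with the header of the packaged table recording the
ambiguity.

## Phenotype derivation

Population is assigned from the model-based African ancestry proportion:
≥ 0.50 → AA, otherwise EA, ties to AA (`assign_population()`). The ancestry
proportion is also carried as a continuous covariate in every logistic
model. BMI (kg/m²) is classified by the WHO cut points with half-open
intervals: underweight < 18.5, normal [18.5, 25), overweight [25, 30),
obese ≥ 30 (`classify_bmi()`); the conventional "24.9"/"29.9" upper bounds
are display conventions, not closed bounds. A subject is an SD case if any
of the four dependence diagnoses is present; unaffected subjects are
controls only when screened, otherwise they are excluded from case-control
contrasts rather than silently treated as controls (`derive_sd_status()`).

Allele counting assumes two chromosome copies per subject: a group's total
is twice its number of non-missing calls at the site, and subjects whose
sequencing failed at a site are dropped *per site*, not listwise — this is
what makes the per-variant denominators differ (`count_alleles()`).

## Common-variant association

For each common site the package provides:

* **HWE tests** (`hwe_test()`): the exact test sums probabilities of all
  heterozygote configurations no more probable than the observed one,
  conditional on allele counts; a 1-df chi-square version is also available.
  Monomorphic input returns p = 1.
* **Allelic 2×2 chi-square** (`allelic_chi2()`): Pearson chi-square on
  allele counts without continuity correction (the convention of the
  standard association toolkits this pipeline mirrors), OR = ad/bc, Woolf
  log-interval for the CI. The Haldane–Anscombe 0.5 correction is applied to
  all cells, for the OR and CI only, exactly when a zero cell occurs — the
  dominant convention where the source is silent.
* **Permutation empirical p** (`permutation_empirical_p()`): group labels
  are permuted over subjects (10,000 permutations by convention), and the
  estimator is (b+1)/(m+1), which cannot return zero; whether the original
  analysis used b/m or (b+1)/(m+1) is unstated, and the two differ by less
  than one part in 10⁴ at m = 10,000.
* **Covariate-adjusted logistic regression** (`logistic_assoc()`):
  maximum-likelihood fit with additive dosage coding, Wald z and p (not the
  likelihood-ratio test, matching the reporting convention of the toolkits
  above). Covariates are sex, age and ancestry proportion, plus BMI when the
  outcome is an SD trait and SD status when the outcome is a BMI contrast.
  Separation or non-convergence is reported as such (`converged = FALSE`,
  p = NA), never as a spurious p-value.

BMI contrasts (`run_bmi_contrasts()`) follow the three-model design —
overweight, obese, and overweight+obese, each against the normal-weight
group — pooling cases and controls with SD status as a covariate. The three
underweight subjects are excluded from all three contrasts, matching the
three-model layout.

Published single-marker chi-square/OR values for this study are *not* exact
targets of the test suite: they require the per-stratum genotype tables
with missingness, which the printed tables do not carry. The suite instead
verifies the machinery against independent implementations and checks that
the synthetic preset reproduces the findings qualitatively (an EA-specific
3'UTR–BMI association; no SD association at either common site).

## Two-locus haplotype analysis

`em_haplotype_freqs()` estimates the four haplotype frequencies from
unphased dosages by EM. Only double heterozygotes are phase-ambiguous; the
EM splits them between the coupling and repulsion resolutions by their
posterior odds. Initialisation is at linkage equilibrium (product of
observed allele frequencies), single start: with two biallelic loci the
observed allele frequencies are fixed margins of the estimate, leaving a
one-dimensional likelihood that is unimodal in practice — the test suite
guards this with a grid-search maximiser over the free parameter.
Convergence is declared when the largest frequency change drops below 1e-8
(default), iteration capped at 1000 with an explicit non-convergence flag;
the log-likelihood is asserted non-decreasing at every step. Subjects
missing either call are dropped from phasing.

`ld_stats()` computes D = f(AB) − p~A~p~B~, D′ = |D|/D~max~ and
r² = D²/(p~A~p~a~p~B~p~b~); both are flagged undefined at monomorphic loci.
Note r² ≤ D′ does *not* hold in general and is not asserted.

`haplotype_assoc()` compares per-haplotype expected counts between two
strata using pooled-sample EM posterior fractional counts per subject
(pooled, not per-stratum, EM — matching the behaviour of the haplotype
association tools this mirrors), a 1-df chi-square per haplotype on the
possibly fractional 2×2 table, and a label-permutation empirical p that
re-uses the fixed posterior assignment. Haplotypes with expected count
below 1 in either stratum are flagged unreliable. The published D′/r²
values (0.87/0.04 AA, 1.00/0.02 EA) are qualitative references only — they
require the raw genotypes — but the synthetic preset, whose default LD puts
the two minor alleles in repulsion at |D′| = 0.9, lands close to them.

## The rare-variant collapsing burden test

This is the package's core computation (`classify_rare()`,
`harmonic_mean_size()`, `adjusted_collapsed_counts()`, `burden_test()`):

1. **Panel.** A site is rare when the larger of its pooled-case and
   pooled-control MAFs is strictly below the threshold. The nominal
   convention is 1%; the study panel includes one site at MAF 0.011, so the
   package default is 0.012, which reproduces the 21-site panel from the
   packaged table (the strict 0.01 rule is one flag away). The two common
   sites are never part of the panel.
2. **Harmonic-mean size.** With *n* panel variants of chromosome totals
   *N~i~*, the collapse uses N = n/Σ(1/N~i~) — always between min and max
   of the *N~i~* and never above their arithmetic mean — to put variants
   sequenced with different success on one footing.
3. **Adjusted counts.** Each variant contributes p~i~·N with
   p~i~ = n~i~/N~i~; the sum is rounded half away from zero to an integer
   numerator over the rounded harmonic total. When all *N~i~* are equal
   this reduces exactly to the raw allele count. Because the published
   intermediate is ambiguous about where rounding happens, the unadjusted
   raw-count test is always reported alongside as a sensitivity check.
4. **Test.** Two-sided Fisher's exact test with the probability-ordering
   convention and 1e-7 relative tolerance of the R reference
   implementation (the analysis this re-implements was run in R), computed
   in log space. The five SD-trait contrasts (SD overall, AD, CD, OD, MjD —
   non-exclusive case subsets against one screened-control group) are
   Bonferroni-thresholded at α/5 = 0.01; no correction is applied inside
   the collapse, which is a single variable by construction.

Two published quantities deliberately are **not** reproduction targets. The
printed collapsed denominators (265, 208, 248, 290) do not equal
n/Σ(1/N~i~) evaluated on the printed per-variant denominators (≈ 279.8,
211.2, 261.2, 307.9) — the numerators do match (16, 4, 14, 18), and the
package reports the formula's value. Likewise the printed exact-test
p-values are not reproducible from the printed integer counts under either
sidedness; the test suite instead proves the Fisher implementation
equivalent to brute-force hypergeometric enumeration (to 1e-12,
exhaustively over all 2×2 tables with margins ≤ 60).

## Retrospective power

`min_detectable_or()` inverts the Fleiss continuity-corrected two-proportion
normal approximation — the default dichotomous method of the PS-family
power calculators — by bisection (to 1e-4) to find the smallest OR reaching
80% power at α = 0.05 on allele counts (2n chromosomes per group, matching
the allelic tests being powered). Whether the original calculation powered
allele or subject counts, and with which correction, is unstated; the
method here reproduces the published minimum detectable ORs
(1.67/2.50 for the indel in AA/EA, 2.00/1.68 for the 3'UTR SNP) within
±0.1–0.15, and Monte-Carlo simulation of the continuity-corrected test at
the returned OR confirms the attained power within ±0.03.

## The synthetic cohort generator

`simulate_cohort()` exists so every downstream stage is testable without
any external data. What it emulates, and how:

* **Genotypes.** The two common sites are drawn as two haplotypes per
  subject from a population-specific two-locus haplotype table
  parameterised by the marginal MAFs and a signed D′ (default −0.9:
  minor alleles in repulsion, echoing the observed "tight LD, low
  correlation"). Rare sites are independent carriers — carrier probability
  f per subject, homozygous with probability f within carriers, so
  homozygotes occur at f² — with no LD among rare sites, since the study
  reports no rare-haplotype structure.
* **Dropout.** Sequencing failure is per amplicon segment and subject,
  applied after phenotype simulation inputs are taken (dropout is
  measurement, not biology). The preset fits one dropout rate per segment
  and population so the expected pooled per-population denominators equal
  the packaged table's exactly; case/control splits of a segment can
  deviate by a few percent because dropout is independent of phenotype.
* **Phenotypes.** SD follows a logistic liability on the subject's total
  rare-allele count (odds ratio `burden_or_sd` per allele) plus fixed
  sex/age/ancestry coefficients (0.2 male, 0.1 per decade, 0.3 per unit
  ancestry — arbitrary but frozen in the preset). Specific dependence
  diagnoses are drawn at the study's conditional rates given SD. Elevated
  weight (overweight or obese) vs normal follows an independent logistic
  model with odds ratio `common_or_bmi` per 3'UTR minor allele in EA
  subjects only; elevated subjects split into overweight/obese
  independently of genotype, so all three BMI contrasts share one
  generating odds ratio and the overweight+obese model recovers exactly
  ln(`common_or_bmi`). BMI values are drawn from class-conditional
  truncated normals matching the study's class means and SDs
  (22.4 ± 1.6, 27.1 ± 1.4, 35.5 ± 5.1; underweight at rate 0.005).
* **Sampling.** Target case/control counts per population are met by
  oversampling a pool (`pool_mult`, default 3) and taking the required
  numbers — rejection resampling rather than retrospective likelihood,
  chosen for simplicity and documented as approximate under strong
  effects.

Preset effect sizes: the study reports no burden effect estimate, only
p-values, so the preset uses the allele-level odds ratio implied by the
collapsed AA counts, (16/249)/(4/204) ≈ 3.3, and a BMI odds ratio of 2.0
matching the reported EA 3'UTR association; both are configurable. Rare
carrier frequencies come from the packaged table by inverting
f(1+f)/2 = p (allele frequency p).

What the generator does **not** emulate: sequence context and mutation
processes, ancestry-informative-marker noise in the admixture scores,
self-report error in height/weight, household or family structure, and any
SD–BMI dependence beyond their shared covariates. Passing calibration and
recovery tests on these cohorts therefore demonstrates correctness of the
statistical machinery under the stated model, not robustness to the
messiness of real cohort data.

## Numerical and testing choices

* All chi-square formulas run in doubles (32-bit integer overflow in
  n(ad−bc)² is real at these sample sizes) and the Fisher test runs in log
  space.
* Rounding of adjusted counts is half-away-from-zero, since base R's
  round-half-even would disagree with printed integer tables.
* Null calibration (500 synthetic replicates) asserts the asymptotic
  allelic test's type-I error within three binomial standard errors of
  0.05 two-sidedly, but the burden and haplotype tests only from above:
  exact and fractional-count tests are conservative by construction, and
  their null p-values are super-uniform.
* Problem sizes in the heavier experiments — 500 calibration replicates of
  a 300-subject cohort, 100 recovery replicates at n = 4000, exhaustive
  Fisher verification to margin 60 — were chosen as the smallest designs
  that make the binomial error bands meaningful, and run in a few minutes
  in total.
* The pipeline (`run_pipeline()`) seeds every stochastic stage from one
  seed and formats every number deterministically, so a config + seed pair
  reproduces its output files byte for byte.

## Known limitations

Single-gene scope (no genome-wide machinery, no imputation); two-locus
phasing only; no weighted or variance-component rare-variant tests (they
postdate the collapsing design implemented here); no covariate adjustment
inside the burden test — population is handled by stratification, which is
exactly the original design's limitation; exact logistic regression is not
provided, so heavily separated strata report non-convergence instead of a
p-value.
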