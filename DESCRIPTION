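Package: pomcvar
Title: Candidate-Gene Exon Resequencing Association Analysis with
    Rare-Variant Collapsing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control association analysis for candidate-gene exon
    resequencing studies, built around the POMC exonic variant data
    distributed with the package: allelic chi-square and covariate-adjusted
    logistic association for common variants, permutation empirical p-values,
    two-locus EM haplotype phasing with D'/r-squared linkage disequilibrium,
    a rare-variant collapsing burden test with harmonic-mean adjustment for
    variable per-amplicon sequencing success, retrospective
    minimum-detectable odds-ratio power calculations, and a synthetic cohort
    generator emulating the study design (two admixture-defined populations,
    per-amplicon dropout, logistic liability for substance dependence, and
    WHO body-mass-index categories).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
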