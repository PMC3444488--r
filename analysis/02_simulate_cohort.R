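#!/usr/bin/env Rscript
# Generate the preset synthetic cohort (two populations, per-amplicon
# dropout, SD liability on the rare-allele burden, BMI effect at the
# 3'UTR-like site in EAs) and write it in the package's exchange formats.

library(pomcvar)
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)

seed <- 17L
cfg <- pomc_preset(seed = seed)
st <- simulate_cohort(cfg)

write_phenotypes(st$subjects, "results/synthetic/phenotypes.tsv")
write_genotypes_vcf(st$genotypes, "results/synthetic/genotypes.vcf")
write_count_fixture(st, "results/synthetic/count_table.tsv")

tab <- table(st$subjects$population, st$subjects$status)
message(sprintf("seed %d: %d subjects (AA %d case / %d control, EA %d / %d)",
                seed, nrow(st$subjects),
                tab["AA", "case"], tab["AA", "control"],
                tab["EA", "case"], tab["EA", "control"]))
message(sprintf("missing calls: %.1f%% (per-amplicon dropout)",
                100 * mean(is.na(st$genotypes$calls))))
message("wrote results/synthetic/{phenotypes.tsv,genotypes.vcf,count_table.tsv}")
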