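#!/usr/bin/env Rscript
# Stage 1: simulate the desk-scale study cohort and write its input files.
#
# The cohort emulates the structure of the real study population: one farm,
# categorical birthplace and rearing-season covariates, biallelic autosomal
# SNPs with MAF >= 0.05, genera with a long-tailed prevalence spectrum and
# additive genetic control, and a weight phenotype with h2 = 0.39 and
# m2 = 0.20. Sizes are desk-scale (n = 300, 2,000 SNPs, 100 genera) so the
# whole analysis chain runs in minutes on a laptop.

suppressPackageStartupMessages(library(microbiability))

seed <- 20240901L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_individuals = 300, n_snps = 2000, n_taxa = 100,
                  pheno_h2 = 0.39, pheno_m2 = 0.20, seed = seed)
cohort <- simulate_cohort(cfg)

write_genotypes_vcf(cohort$geno, file.path(out, "genotypes.vcf"))
write_genotypes_tsv(cohort$geno, file.path(out, "genotypes.tsv"))
write_abundance_tsv(cohort$abundance, file.path(out, "abundance.tsv"))
write_phenotype_tsv(cohort$phenotype, file.path(out, "phenotype.tsv"))
write_truth_json(cohort$truth[c("true_h2_per_taxon", "true_pheno_h2",
                                "true_pheno_m2")],
                 file.path(out, "truth.json"))

prev <- prevalence(cohort$abundance)
cat("cohort:", nrow(cohort$geno$values), "individuals,",
    ncol(cohort$geno$values), "SNPs,", ncol(cohort$abundance$values),
    "genera\n")
cat("genera at 100% prevalence:", sum(prev == 1),
    "| below 10%:", sum(prev < 0.1), "\n")
cat("phenotype: mean", round(mean(cohort$phenotype$weight), 2),
    "sd", round(sd(cohort$phenotype$weight), 2),
    "| true h2", cfg$pheno_h2, "m2", cfg$pheno_m2, "\n")
cat("inputs written under", out, "\n")
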