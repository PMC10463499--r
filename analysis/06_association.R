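#!/usr/bin/env Rscript
# Stage 6: GWAS for weight, mbGWAS for heritable features, two-part MWAS.
#
# EMMAX-style mixed-model association with birthplace, season and top-3
# genetic PCs as covariates; significance tiers at 1e-6 (suggestive),
# 1e-8 (genome-wide) and 0.05/N_SNPs (study-wide). The MWAS regresses the
# covariate-adjusted weight on genus presence (prevalence < 60%) or CLR
# abundance (>= 60%), Bonferroni-corrected.

suppressPackageStartupMessages(library(microbiability))

geno <- read_genotypes_vcf("results/cohort/genotypes.vcf")
pheno <- read.table("results/cohort/phenotype.tsv", sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
rel <- read_abundance_tsv("results/features/genus_filtered.tsv",
                          kind = "relative")
grm <- read_grm_gcta("results/kinship/grm")
pcs <- as.matrix(read.table("results/kinship/genetic_pcs.tsv", sep = "\t",
                            header = TRUE, row.names = 1))
scan <- read.table("results/varcomp/h2_scan.tsv", sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
out <- "results/assoc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

geno_qc <- qc_genotypes(geno)
X <- build_design(pheno[, c("birthplace", "season")],
                  pcs = pcs[, 1:3, drop = FALSE])
y <- pheno$weight

gwas <- mlm_gwas(y, X, grm, geno_qc)
cat("weight GWAS:", sum(gwas$tier != "none", na.rm = TRUE),
    "SNPs at suggestive or better (null-model h2 =",
    round(attr(gwas, "h2_null"), 3), ")\n")
write.table(gwas, file.path(out, "gwas_weight.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

feats <- build_feature_set(rel, k_pcoa = 5)
mb <- mbgwas_scan(feats, scan, prevalence(rel), X, grm, geno_qc)
n_assoc <- sum(sapply(mb, function(t) sum(t$tier != "none", na.rm = TRUE)))
cat("mbGWAS:", length(mb), "heritable features scanned,",
    n_assoc, "feature-SNP associations at suggestive or better\n")
for (nm in names(mb)) {
  write.table(mb[[nm]], file.path(out, paste0("mbgwas_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

y_adj <- adjust_phenotype(y, pheno[, c("birthplace", "season")])
mwas <- mwas_two_part(y_adj, rel, pcs = pcs[, 1:3, drop = FALSE])
cat("MWAS:", nrow(mwas), "genera tested,", sum(mwas$significant),
    "marker genera (Bonferroni p < 0.05)\n")
write.table(mwas, file.path(out, "mwas.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("association tables written under", out, "\n")
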