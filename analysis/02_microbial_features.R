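#!/usr/bin/env Rscript
# Stage 2: genus filtering and the microbial feature set.
#
# Filters the genus table (classified genera, mean relative abundance
# > 1e-6, occurrence in more than 3 samples), then derives community
# traits (richness, Chao1, ACE, Shannon, F:B ratio, top-5 Bray-Curtis
# PCoA scores) and partitions genera into CLR quantitative traits
# (prevalence >= 60%) and presence/absence binary traits (1.5-60%).

suppressPackageStartupMessages(library(microbiability))

abund <- read_abundance_tsv("results/cohort/abundance.tsv", kind = "relative")
out <- "results/features"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rel <- filter_genera(abund)
cat("genera:", ncol(abund$values), "input ->", ncol(rel$values),
    "after filtering\n")

feats <- build_feature_set(rel, k_pcoa = 5)
cat("feature set:", ncol(feats$traits$quantitative), "quantitative (CLR),",
    ncol(feats$traits$binary), "binary,",
    length(feats$traits$excluded), "excluded (<1.5% prevalence)\n")
cat("PCoA axes 1-5 explain",
    paste0(round(100 * feats$pcoa$var_explained, 1), "%", collapse = ", "),
    "of Bray-Curtis variance\n")

write.table(feats$community, file.path(out, "community_traits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(feats$traits$quantitative),
                       feats$traits$quantitative, check.names = FALSE),
            file.path(out, "quantitative_clr.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(feats$traits$binary),
                       feats$traits$binary, check.names = FALSE),
            file.path(out, "binary_presence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_abundance_tsv(rel, file.path(out, "genus_filtered.tsv"))
cat("feature tables written under", out, "\n")
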