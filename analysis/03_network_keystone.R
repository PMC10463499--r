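#!/usr/bin/env Rscript
# Stage 3: core genera and keystone taxa.
#
# Core = genera detected in every sample. Keystones come from the CLR
# Spearman co-occurrence network (|r| > 0.6, BH-adjusted p < 0.05 after
# excluding genera with summed relative abundance < 0.01% or prevalence
# < 1.5%): greedy modularity modules, then Zi/Pi classification with the
# conventional 2.5 / 0.62 threshold boxes.

suppressPackageStartupMessages(library(microbiability))

rel <- read_abundance_tsv("results/features/genus_filtered.tsv",
                          kind = "relative")
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

core <- core_taxa(rel)
cat("core genera (100% prevalence):", length(core), "\n")

ks <- keystone_analysis(rel)
cat("network:", length(ks$network$nodes), "nodes,",
    nrow(ks$network$edges), "edges")
if (!is.null(ks$modules)) {
  cat(",", length(unique(ks$modules$membership)), "modules (Q =",
      round(ks$modules$modularity, 3), ")")
}
cat("\n")
if (nrow(ks$topology)) {
  cat("node classes:", paste(names(table(ks$topology$node_class)),
                             table(ks$topology$node_class),
                             collapse = ", "), "\n")
  cat("keystone taxa:", length(ks$keystone), "\n")
  write.table(ks$topology, file.path(out, "node_topology.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ks$network$edges, file.path(out, "edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(core, file.path(out, "core_taxa.txt"))
cat("network tables written under", out, "\n")
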