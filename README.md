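# microbiability

Quantifying how much of a quantitative phenotype is explained by host
genetics versus a host-associated microbial community — and whether the
two pathways run through the same loci. The package implements the full
analysis chain used in large livestock microbiome cohorts (the motivating
setting is rumen microbiota and lamb body weight) as tested, reusable R
functions, together with a synthetic cohort generator with known truth so
every stage can be validated without access to animal data.

## The models

**Relationship matrices.** Host similarity is the SNP-based genomic
relationship matrix (GRM) with the Yang marker estimator,

    A_jk = (1/N) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2 p_i (1 − p_i)),  j ≠ k

(diagonals use the corrected single-individual form). Microbiota
similarity is the microbial relationship matrix (MRM) `M = ZZ′/m` from
column z-scored taxon abundances, so `trace(M) = n − 1`. A one-sided
permutation Mantel test (Pearson correlation of off-diagonals) asks
whether genetically similar hosts carry similar communities.

**Variance components.** For a phenotype or microbial feature `y`,

    model 1:  y = Xb + Wa + e,        a ~ N(0, G σ²a)      →  h² = σ²a/σ²p
    model 2:  y = Xb + Zm + e,        m ~ N(0, M σ²m)      →  m² = σ²m/σ²p
    model 3:  y = Xb + Wa + Zm + e                          →  joint h², m²

fitted by AI-REML (EM warm start, non-negativity constraints, analytic
average-information standard errors), with a single-matrix
eigendecomposition fast path that is reused across hundreds of features.
Significance of a component uses the boundary-corrected LRT
(`p = ½ P(χ²₁ ≥ 2ΔlogL)`). `m²` — the *microbiability* — is the share of
phenotypic variance attributable to the microbial community.

**Feature engineering.** Genus tables are filtered (classified genera,
mean relative abundance > 1e-6, occurrence in > 3 samples) and split by
prevalence: ≥ 60% → quantitative traits (CLR-transformed abundance),
1.5–60% → presence/absence binary traits, < 1.5% → excluded. Community
traits are richness, Chao1, ACE, Shannon, the Firmicutes:Bacteroidetes
ratio and the top-5 Bray-Curtis PCoA scores.

**Networks and keystones.** Co-occurrence networks from all-pairs
Spearman correlations of CLR abundances (edges: |r| > 0.6 and
Benjamini-Hochberg p < 0.05), greedy modularity modules, and Zi/Pi
(within-/among-module connectivity) node classification at the
conventional 2.5 / 0.62 thresholds; connectors and hubs are keystone
taxa. Core taxa are genera present in every sample.

**Association.** EMMAX-style mixed-linear-model GWAS (null REML fit, then
per-SNP GLS under the fitted covariance) for the phenotype and for every
heritable microbial feature (mbGWAS), with suggestive 1e-6 / genome-wide
1e-8 / Bonferroni study-wide tiers. A two-part microbiota-wide
association model (MWAS) regresses the covariate-adjusted phenotype on
genus presence (binary part) or CLR abundance (quantitative part).

**Recursive integration.** MWAS-significant "marker" genera define
indirect SNP sets (their mbGWAS hits). Each indirect SNP is then tested
for a direct phenotype signal — exact locus overlap with the phenotype
GWAS, and a Kruskal-Wallis test of the phenotype across its genotypes
(p < 0.01) — yielding "recursive" (direct + mediated) versus
"indirect only" labels.

## Worked example

The `analysis/` directory is a numbered workflow over a desk-scale
synthetic cohort (n = 300, 2,000 SNPs, 100 genera; true h² = 0.39,
m² = 0.20):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/04_kinship_mantel.R
Rscript analysis/05_heritability.R   # needs 02 for the feature tables
```

Stage 4 prints

    Mantel: r = 0.0385, one-sided p = 0.0001 (9999 permutations)

— the host genome and the community covary because a subset of genera is
genetically controlled. Stage 5 prints

    weight h2 (GRM model): 0.298 (se 0.230, LRT p 0.107)
    weight m2 (MRM model): 0.196 (se 0.064, LRT p 9.56e-05)
    joint model: h2 = 0.369, m2 = 0.205 (combined 0.574)

At n = 300 a single h² estimate is noisy (the standard error says so);
the joint model still lands near the simulated 0.39/0.20, and the
acceptance script below shows that across repeated cohorts at n = 800 the
mean estimates recover the truth closely. Stage 7 classifies a designed
pleiotropic SNP as "recursive (overlap); recursive (KW)" and a
taxon-only SNP as "indirect only".

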