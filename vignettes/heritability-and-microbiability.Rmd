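---
title: "Heritability and microbiability of host-associated microbiomes: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability and microbiability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models it fits, the defaults it ships, what the synthetic cohort
generator does and does not emulate, and the choices made where more
than one defensible design existed.

## The scientific question

In ruminant livestock, body weight is shaped both by host additive
genetics and by the rumen microbial community — and the community itself
is partly under host genetic control. Three quantities organise the
analysis: the heritability `h²` of a trait (share of phenotypic variance
explained by additive genetics, via the genomic relationship matrix), the
*microbiability* `m²` (share explained by the microbiota, via a microbial
relationship matrix), and the set of loci whose effect on the phenotype
runs through phenotype-associated ("marker") taxa — possibly in addition
to a direct effect, the "recursive" configuration.

## Variance-component engine

`reml_fit()` implements AI-REML for `y = Xb + Σ_k u_k + e` with
`u_k ~ N(0, σ²_k K_k)`:

* the first 3 iterations are EM updates (robust far from the optimum),
  then average-information Newton steps with step halving and an EM
  fallback whenever a step would decrease the restricted likelihood;
* components are constrained non-negative: proposals below
  `1e-6 · var(y)` are clamped there and flagged `fixed_at_boundary`;
* convergence at successive log-likelihood change `< 1e-8` or relative
  parameter change `< 1e-6` (cap 100 iterations; non-convergence is
  flagged in the result, never raised as an error);
* standard errors of components and ratios come from the inverse AI
  matrix (delta method for ratios).

For a single random term, `reml_fit_eigen()` rotates by the eigenvectors
of `K`, profiles out the scale, and maximises the one-dimensional
restricted likelihood in `h = σ²_k/(σ²_k + σ²_e)` by Brent search with
explicit boundary evaluation. The restricted likelihood convention (the
`-½ log|X'V⁻¹X|` REML term, constants included) is identical across the
fast path, the general path and the standalone evaluator `reml_loglik()`,
so differences of any two fits are valid LRT statistics. The fast path's
one-off eigendecomposition is reused across all features in
`feature_h2_scan()` and across all SNPs in `mlm_gwas()` — this is what
makes a 300-feature scan and per-feature GWAS affordable.

Testing a variance component pins it to the boundary of its parameter
space, so `lrt()` uses the 50:50 mixture of a point mass at zero and
`χ²₁`: `p = ½ P(χ²₁ ≥ 2ΔlogL)`. Binary presence/absence traits are fitted
on the observed 0/1 scale; no liability-scale transform is applied.

An important identifiability caveat, surfaced by the tests: when the
relationship matrix is close to the identity (few markers relative to n,
unrelated individuals), the `G`-vs-`I` split is weakly determined, the
profile likelihood is nearly flat, and boundary optima occur. The
engine's unit oracles therefore use Wishart-structured matrices with a
wide eigenvalue spread; on marker-based GRMs the reported standard errors
carry the identifiability information and should be read.

## Relationship matrices and the Mantel test

The GRM uses the Yang marker estimator with its corrected diagonal;
missing genotypes are mean-imputed per SNP before computation. QC
defaults mirror common practice for dense panels: biallelic autosomal
SNPs, MAF ≥ 0.05, missingness ≤ 0.3. The MRM is `ZZ′/m` from
column-z-scored abundances (sample SD), giving `trace(M) = n − 1`
exactly; zero-variance taxa are dropped with a warning. The Mantel test
correlates the vectorised off-diagonal upper triangles (similarity
matrices directly, no distance conversion), permutes rows/columns of one
matrix simultaneously, and reports the one-sided upper-tail p with the
`+1` correction, so `p` can never be 0; an exhaustive mode enumerates all
`n!` permutations for tiny n.

## Microbial features

* Prevalence thresholds: genera below 1.5% prevalence are excluded;
  `[1.5%, 60%)` becomes binary presence traits; `≥ 60%` becomes
  quantitative traits. The 60% boundary itself is assigned to the
  quantitative class (the verbal rules "less than 60% → binary" and
  "more than 60% → quantitative" leave exactly-60% open; `≥` keeps the
  partition deterministic).
* The genus filter reads "mean relative abundance > 0.0001%" as the
  proportion 1e-6 and "occurrence in more than 3 samples" as strictly
  more (≥ 4); unclassified genera are removed first.
* The CLR transform uses a pseudocount of 1e-6 on relative abundances
  (configurable); every output row sums to zero by construction.
* Chao1 is the bias-corrected variant `S + F1(F1−1)/(2(F2+1))`; ACE uses
  the conventional rare/abundant cutoff of 10. Both are delegated to
  vegan's `estimateR`; when a sample has no rare taxa at all (every
  count > 10) ACE is defined as the observed richness, since there is
  nothing to extrapolate.
* Rarefaction subsamples without replacement (hypergeometric) to the
  exact depth and drops samples whose total is below it, with a warning —
  the behaviour of the standard QIIME-style rarefier.
* PCoA is classical metric MDS of Bray-Curtis distances; negative
  eigenvalues are ignored both as axes and in the variance-explained
  denominator (no Cailliez correction; fractions are of
  positive-eigenvalue variance).

## Co-occurrence network and keystones

Edges require tie-corrected Spearman `|r| > 0.6` *and* BH-adjusted
`p < 0.05` over all tested pairs; p-values use the t approximation, with
an exact permutation p for `n < 10`. Module detection uses deterministic
greedy modularity maximisation (CNM, via igraph), with a seeded Louvain
alternative behind a flag; the connected-components partition is accepted
when its modularity ties or beats the greedy result, which also makes
singleton components their own modules and sidesteps a float-tie artefact
of the greedy merge sequence on complete graphs. `Zi` uses the node's
module's within-degree mean and SD (0 when the SD is 0); `Pi` is the
participation coefficient. Classification thresholds 2.5 / 0.62 are
strict inequalities — boundary values fall to the lower class.
Classification always emits all four classes; which ones are populated is
a property of the data.

## Association models

`mlm_gwas()` is the EMMAX approximation: variance components are
estimated once under the null (no SNP) model and fixed; each SNP is then
tested by GLS under `V̂`, computed in the GRM's eigenbasis. The residual
scale is re-estimated per SNP and the test is t-referenced with
`df = n − p − 1`. This choice (over a fixed-scale Gaussian Wald) makes
the estimator reduce *exactly* to OLS when `V̂ ∝ I`, which is both a
useful invariant and a correctness anchor at small n; at GWAS sample
sizes the two are indistinguishable. Monomorphic SNPs return `p = NA`.
Exact per-SNP REML is not implemented — at 2 × 10⁷ markers only the
fixed-components approximation is practical, matching standard MLM
tooling.

The mbGWAS scan takes only features that passed the heritability LRT
(`p < 0.05`), and binary genus traits additionally require prevalence
≥ 30% (low-prevalence presence traits are false-positive prone). The
two-part MWAS regresses the covariate-adjusted phenotype on the presence
indicator (prevalence < 60%, coefficient β₁) or the CLR abundance
(≥ 60%, β₂), with genetic PCs as covariates and a linear (not logistic)
binary part, matching the linear two-part formulation; p-values are
t-referenced and Bonferroni-corrected over all genera tested.

Both the heritability covariates ("top five PCs") and the association
covariates ("top three PCs") are taken to be *genetic* PCs of the GRM —
the reading most consistent with their role as population-structure
adjustments; microbial PCoA scores enter the analysis as traits, not
covariates.

## Recursive integration

Marker genera are the Bonferroni-significant MWAS taxa. Their mbGWAS
hits at the suggestive tier (1e-6; the tier that maximises instrument
strength, configurable) form the per-genus indirect SNP sets. Locus
overlap with the phenotype GWAS is exact SNP identity (a ±bp window is
available but off by default). The Kruskal-Wallis screen labels an
indirect SNP "recursive (KW)" at `p < 0.01`; overlap and KW labels are
not exclusive, and no additional GWAS-nominal requirement is imposed on
KW-recursive SNPs.

## The synthetic cohort generator

`sim_config()` defaults describe the emulated study structure: n = 1150
individuals, MAF ∈ [0.05, 0.5] Hardy-Weinberg SNPs laid round-robin over
26 autosomes, 300 genera with a long-tailed prevalence spectrum (~15% of
taxa at 100% prevalence decaying geometrically to 2%), per-taxon latent
heritabilities drawn uniformly on [0, 0.7], phenotype h² = 0.39 and
m² = 0.20, and two 4-level categorical covariates with ±0.5 SD fixed
offsets. The SNP panel size (default 10,000) is a modelling choice for
marker-based relationship estimation, not an emulation of a sequencing
panel. Workflow and test runs scale n, SNPs and taxa down and say so at
each site; the recovery studies use n = 800, 5,000 SNPs, 150 taxa.

Mechanism: each taxon's latent Gaussian value is a standardized sum of
its causal-SNP genotypes plus noise in the configured variance ratio;
abundances are `exp(latent + per-taxon offset)`, zero-truncated at the
latent quantile that realises the target prevalence, then total-sum
scaled. The phenotype adds covariate offsets, a breeding value from its
own causal SNPs, a microbial value `Zw` (random weights on the z-scored
abundance columns — its covariance is therefore *exactly* proportional to
the MRM built downstream from the same table), and Gaussian residual;
all components are standardized so realized sample variance fractions
equal the configured ones, making recovery studies measure estimator
error only.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent), pedigree/family structure, sequencing depth and count
noise (abundances are continuous proportions; a multinomial count layer
would attenuate rare-taxon prevalence), taxonomic mis-assignment, and
batch effects beyond the two categorical covariates. Passing tests
therefore validate the estimators under their own assumptions, not
robustness to those real-data complications. The exponential link itself
is a stand-in — the generative distribution of real genus abundances is
unknown; any monotone positive link with controllable zero pattern would
serve.

One consequence worth knowing: the latent heritability of a taxon is
attenuated on derived scales. Estimated on the taxon's log abundance the
bias is small (≈ −0.06 at latent h² = 0.6 in the shipped regime); on the
CLR scale the per-sample centring term — which carries presence/absence
flips of rare taxa — adds common-mode noise and costs roughly another
0.1. The recovery test therefore checks the log scale, and real-data CLR
h² estimates should be expected to sit slightly below their
relative-abundance counterparts.

`simulate_recursive_cohort()` builds the designed-truth cohort for
validating the scenario classifier: a single always-present marker taxon
driven by two designated common SNPs (12% of latent variance each), a
phenotype with polygenic background (h² = 0.25), a direct effect of the
first SNP (4% of variance) and an effect of the marker taxon's observed
CLR abundance (4%). The sizes were chosen by power analysis *before*
running: both SNPs are detected by the taxon's mbGWAS with high
probability; the direct 4% effect makes the first SNP Kruskal-Wallis
significant essentially always; and the second SNP's only phenotype path
is the mediated one (≈ 0.5% of variance), keeping its KW rate near the
boundary of the noise — exactly the configuration in which "recursive"
versus "indirect only" labels are informative. A genuine mediated effect
means the taxon-only SNP is occasionally (≈ 10% of cohorts) KW-significant;
that is correct behaviour of the screen, not misclassification.

## Numerical and degenerate-input policy

* Monomorphic SNPs: an error in `compute_grm()` (the QC contract was
  violated), `NA` with a message in GWAS.
* Constant features: skipped with a warning in scans; constant coded
  genera skipped in the MWAS.
* All-zero samples: an error in `alpha_diversity`; zero Bacteroidetes
  makes the F:B ratio `NA` (excluded downstream).
* Seeds: a single master seed; every stochastic stage derives a named
  child stream (`child_seed`), so stages are independently reproducible
  and reordering stages cannot silently change results.
* Ties: Spearman uses mid-ranks (tie-corrected); Kruskal-Wallis uses the
  tie-corrected H (delegated to `stats::kruskal.test`, with the full-tie
  case defined as H = 0, p = 1).

## Problem sizes

The shipped studies use: n = 800, 5,000 SNPs, 150 taxa, 25 seeds for
variance-component recovery; n = 300 with 200 replicates for LRT null
calibration; n = 500 with 2,000 SNPs for GWAS inflation; n = 800 with 20
seeds for the recursive classification study; and a n = 300 / 2,000 SNP /
100-genus cohort for the narrative workflow. These sizes give stable
Monte-Carlo means (SE of the recovery mean ≈ 0.025) while keeping a full
run in minutes; they are the package's definition of "desk scale".

## Known limitations

* Single-phenotype, single-kingdom: no bivariate REML, no GxE, no
  multi-omic relationship matrices.
* The EMMAX approximation understates significance for SNPs with large
  effects on highly heritable traits (as all fixed-components MLMs do).
* Binary-trait h² on the observed scale is not comparable across
  prevalences without a liability transform.
* No LD-aware locus clumping: "locus overlap" is exact SNP identity
  unless a window is requested, which is the honest choice for
  independent simulated SNPs but conservative for dense real panels.
* No formal mediation or Mendelian-randomisation analysis; the recursive
  labels are threshold-based screens, not causal estimates.
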