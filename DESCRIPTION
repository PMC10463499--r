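Package: microbiability
Title: Heritability and Microbiability of Host-Associated Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis chain linking host genotypes, rumen
    microbiota composition and body weight in a livestock cohort: genomic
    (GRM, Yang estimator) and microbial (MRM, z-score) relationship
    matrices with a permutation Mantel test between them; AI-REML variance
    component models estimating heritability (h2) and microbiability (m2)
    with boundary-corrected likelihood-ratio tests; microbial feature
    engineering (genus filtering, rarefaction, alpha diversity, F:B ratio,
    Bray-Curtis PCoA, CLR transform, prevalence-based trait
    classification); co-occurrence networks with Zi/Pi keystone-taxon
    classification; mixed-linear-model GWAS for microbial and weight
    traits; a two-part (presence/abundance) microbiota-wide association
    model; and the integration of GWAS, mbGWAS and MWAS hits into
    indirect and recursive genotype-microbiota-phenotype scenarios. A
    synthetic cohort generator with known truth makes every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
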