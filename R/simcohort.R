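#' Configuration for the synthetic genotype-microbiota-phenotype cohort
#'
#' The generator emulates the structure of a large single-farm lamb cohort:
#' biallelic autosomal SNPs in Hardy-Weinberg proportions with MAF above a
#' floor, several hundred rumen genera with a long-tailed prevalence
#' spectrum (a core of always-present taxa down to rare ones), per-taxon
#' additive genetic control, and a weight-like phenotype with additive
#' genetic and microbial variance components plus categorical husbandry
#' covariates (birthplace, rearing season).
#'
#' @param n_individuals cohort size.
#' @param n_snps number of biallelic autosomal SNPs.
#' @param maf_range allele-frequency range (each SNP's alternative-allele
#'   frequency is drawn uniformly from it), within (0, 0.5].
#' @param n_taxa number of genera.
#' @param taxon_h2 per-taxon heritability of the latent abundance, in
#'   `[0, 1)`; default draws uniformly on `[0, 0.7]`.
#' @param prevalence_targets per-taxon target prevalence in (0, 1];
#'   default draws a long-tailed spectrum: ~15% of taxa at 1.0 (core),
#'   the rest sloping down to rare (many below 10%).
#' @param pheno_h2 additive genetic fraction of phenotypic variance.
#' @param pheno_m2 microbial fraction of phenotypic variance
#'   (`pheno_h2 + pheno_m2 < 1`).
#' @param n_causal_snps_per_taxon causal SNPs behind each taxon's latent
#'   genetic value.
#' @param n_causal_snps_pheno causal SNPs behind the phenotype's direct
#'   additive genetic value.
#' @param n_covariate_levels named integer vector: levels of the
#'   `birthplace` and `season` factors.
#' @param covariate_effect_sd half-range of the per-level fixed offsets,
#'   in phenotypic standard deviations.
#' @param abundance_dispersion SD of the per-taxon log-abundance scale
#'   offsets that create the long-tailed abundance spectrum.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 1150,
                       n_snps = 10000,
                       maf_range = c(0.05, 0.5),
                       n_taxa = 300,
                       taxon_h2 = NULL,
                       prevalence_targets = NULL,
                       pheno_h2 = 0.39,
                       pheno_m2 = 0.20,
                       n_causal_snps_per_taxon = 10,
                       n_causal_snps_pheno = 300,
                       n_covariate_levels = c(birthplace = 4L, season = 4L),
                       covariate_effect_sd = 0.5,
                       abundance_dispersion = 1.0,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_snps >= 1, n_taxa >= 1,
            n_causal_snps_per_taxon >= 1, n_causal_snps_pheno >= 1,
            all(n_covariate_levels >= 1))
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5] with min <= max", call. = FALSE)
  }
  if (pheno_h2 < 0 || pheno_h2 >= 1 || pheno_m2 < 0 || pheno_m2 >= 1 ||
      pheno_h2 + pheno_m2 >= 1) {
    stop("pheno_h2 and pheno_m2 must be in [0,1) with h2 + m2 < 1", call. = FALSE)
  }
  if (is.null(taxon_h2)) {
    set.seed(child_seed(seed, "taxon_h2"))
    taxon_h2 <- stats::runif(n_taxa, 0, 0.7)
  }
  if (length(taxon_h2) == 1L) taxon_h2 <- rep(taxon_h2, n_taxa)
  if (length(taxon_h2) != n_taxa || any(taxon_h2 < 0) || any(taxon_h2 >= 1)) {
    stop("taxon_h2 must have length n_taxa with values in [0, 1)", call. = FALSE)
  }
  if (is.null(prevalence_targets)) {
    prevalence_targets <- default_prevalence_spectrum(n_taxa)
  }
  if (length(prevalence_targets) == 1L) {
    prevalence_targets <- rep(prevalence_targets, n_taxa)
  }
  if (length(prevalence_targets) != n_taxa ||
      any(prevalence_targets <= 0) || any(prevalence_targets > 1)) {
    stop("prevalence_targets must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_range = maf_range, n_taxa = as.integer(n_taxa),
    taxon_h2 = taxon_h2, prevalence_targets = prevalence_targets,
    pheno_h2 = pheno_h2, pheno_m2 = pheno_m2,
    n_causal_snps_per_taxon = as.integer(n_causal_snps_per_taxon),
    n_causal_snps_pheno = as.integer(min(n_causal_snps_pheno, n_snps)),
    n_covariate_levels = n_covariate_levels,
    covariate_effect_sd = covariate_effect_sd,
    abundance_dispersion = abundance_dispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default long-tailed prevalence spectrum
#'
#' A core block (~15% of taxa) at 100% prevalence, then a geometric decay
#' down to 2% so that many taxa sit below 10% -- the shape of a real
#' genus-level prevalence distribution.
#'
#' @param n_taxa number of taxa.
#' @return numeric vector of target prevalences in (0, 1].
#' @export
default_prevalence_spectrum <- function(n_taxa) {
  n_core <- max(1L, round(0.15 * n_taxa))
  n_rest <- n_taxa - n_core
  tail <- 0.98 * exp(seq(0, log(0.02 / 0.98), length.out = max(n_rest, 1L)))
  c(rep(1, n_core), tail)[seq_len(n_taxa)]
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each SNP's alternative-allele frequency is drawn uniformly from
#' `maf_range`; genotypes are the sum of two independent Bernoulli(p)
#' allele draws (Hardy-Weinberg sampling). SNPs are laid out round-robin
#' across 26 autosomes with increasing positions.
#'
#' @param config a [sim_config].
#' @return a [genotype_matrix].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  p <- config$n_snps
  set.seed(child_seed(config$seed, "genotypes"))
  freq <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  values <- matrix(
    stats::rbinom(n * p, size = 2L, prob = rep(freq, each = n)),
    nrow = n, ncol = p
  )
  storage.mode(values) <- "integer"
  rownames(values) <- sprintf("ind%04d", seq_len(n))
  chr <- rep_len(1:26, p)
  map <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(p)),
    chr = chr,
    pos = 1000L + 500L * (seq_len(p) - 1L) %/% 26L,
    stringsAsFactors = FALSE
  )
  genotype_matrix(values, map)
}

#' Simulate rumen-like genus abundances under additive genetic control
#'
#' For each taxon a latent Gaussian value is built as a standardized sum
#' of causal-SNP genotypes (variance fraction `taxon_h2`) plus independent
#' noise. Latents are pushed through an exponential link with a per-taxon
#' scale offset (long-tailed abundance spectrum), zero-truncated at the
#' per-taxon latent quantile that realises the target prevalence, and
#' total-sum scaled to relative abundances.
#'
#' @param geno a [genotype_matrix] from [simulate_genotypes()].
#' @param config the same [sim_config].
#' @return list with `abundance` (an [abundance_table], relative) and
#'   `truth` (causal SNP ids, realized latent h2 per taxon, latent matrix).
#' @export
simulate_microbiota <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  n <- nrow(geno$values)
  n_taxa <- config$n_taxa
  n_causal <- min(config$n_causal_snps_per_taxon, ncol(geno$values))
  set.seed(child_seed(config$seed, "microbiota"))

  Xs <- scale(geno$values)  # SNP-standardized genotypes
  Xs[is.na(Xs)] <- 0        # monomorphic columns carry no signal

  latent <- matrix(0, n, n_taxa)
  causal <- vector("list", n_taxa)
  realized_h2 <- numeric(n_taxa)
  for (t in seq_len(n_taxa)) {
    h2 <- config$taxon_h2[t]
    idx <- sample.int(ncol(Xs), n_causal)
    causal[[t]] <- geno$map$snp_id[idx]
    g <- Xs[, idx, drop = FALSE] %*% stats::rnorm(n_causal)
    sg <- stats::sd(g)
    g <- if (sg > 0) g / sg else g * 0
    e <- stats::rnorm(n)
    e <- e / stats::sd(e)
    latent[, t] <- sqrt(h2) * g + sqrt(1 - h2) * e
    realized_h2[t] <- h2  # components standardized to exact sample variance
  }

  # exponential link with per-taxon scale offsets; larger offsets for
  # high-prevalence taxa so core taxa are also the abundant ones
  mu <- 2 * config$prevalence_targets +
    stats::rnorm(n_taxa, 0, config$abundance_dispersion)
  abund <- exp(sweep(latent, 2, mu, "+"))

  # zero-truncation at the latent quantile matching target prevalence
  for (t in seq_len(n_taxa)) {
    q <- config$prevalence_targets[t]
    if (q < 1) {
      n_present <- max(1L, round(q * n))
      thr <- sort(latent[, t], decreasing = TRUE)[n_present]
      abund[latent[, t] < thr, t] <- 0
    }
  }

  rel <- abund / rowSums(abund)
  rownames(rel) <- rownames(geno$values)
  taxonomy <- data.frame(
    taxon_id = sprintf("genus%03d", seq_len(n_taxa)),
    phylum = rep_len(c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                       "Fibrobacterota", "Actinobacteriota"), n_taxa),
    genus = sprintf("genus%03d", seq_len(n_taxa)),
    is_classified = TRUE,
    stringsAsFactors = FALSE
  )
  table <- abundance_table(rel, taxonomy, kind = "relative")
  list(
    abundance = table,
    truth = list(
      true_h2_per_taxon = realized_h2,
      causal_snp_ids = causal,
      latent = latent
    )
  )
}

#' Simulate a weight-like phenotype with genetic and microbial components
#'
#' `y = covariate offsets + breeding value + microbial value + residual`.
#' The breeding value is a standardized sum of causal-SNP genotype effects
#' scaled to variance `pheno_h2`; the microbial value is a random linear
#' combination of the z-scored taxon abundances scaled to variance
#' `pheno_m2` (so its covariance is exactly proportional to the MRM built
#' from the same table); the residual makes total non-covariate variance 1.
#' Components are standardized so realized sample variance fractions equal
#' the configured ones.
#'
#' @param geno a [genotype_matrix].
#' @param micro the [abundance_table] from [simulate_microbiota()].
#' @param config the same [sim_config].
#' @return list with `phenotype` (data.frame: sample_id, weight,
#'   birthplace, season) and `truth` (causal SNPs, breeding and microbial
#'   values, realized variance fractions).
#' @export
simulate_phenotype <- function(geno, micro, config) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(micro, "abundance_table"),
            inherits(config, "sim_config"))
  assert_aligned(rownames(geno$values), rownames(micro$values),
                 "genotypes and abundances")
  n <- nrow(geno$values)
  set.seed(child_seed(config$seed, "phenotype"))

  # covariates: categorical birthplace and season, fixed per-level offsets
  lv <- config$n_covariate_levels
  birthplace <- factor(sample.int(lv[["birthplace"]], n, replace = TRUE),
                       labels = sprintf("bp%d", seq_len(lv[["birthplace"]])))
  season <- factor(sample.int(lv[["season"]], n, replace = TRUE),
                   labels = sprintf("s%d", seq_len(lv[["season"]])))
  eff_bp <- seq(-config$covariate_effect_sd, config$covariate_effect_sd,
                length.out = nlevels(birthplace))
  eff_se <- seq(-config$covariate_effect_sd, config$covariate_effect_sd,
                length.out = nlevels(season))
  cov_part <- eff_bp[as.integer(birthplace)] + eff_se[as.integer(season)]

  scale_to_var <- function(x, v) {
    s <- stats::sd(x)
    if (s == 0 || v == 0) return(rep(0, length(x)))
    (x - mean(x)) / s * sqrt(v)
  }

  # direct additive genetic value
  idx <- sample.int(ncol(geno$values), config$n_causal_snps_pheno)
  Xs <- scale(geno$values[, idx, drop = FALSE])
  Xs[is.na(Xs)] <- 0
  a <- scale_to_var(Xs %*% stats::rnorm(length(idx)), config$pheno_h2)

  # microbial value: Z w with Z the z-scored abundances, so cov(m) ∝ MRM
  Z <- scale(micro$values)
  Z <- Z[, !is.na(colSums(Z)), drop = FALSE]
  m <- scale_to_var(Z %*% stats::rnorm(ncol(Z)) / sqrt(ncol(Z)), config$pheno_m2)

  e <- scale_to_var(stats::rnorm(n), 1 - config$pheno_h2 - config$pheno_m2)
  y <- 50 + cov_part + a + m + e  # 50: arbitrary weight-scale intercept

  list(
    phenotype = data.frame(
      sample_id = rownames(geno$values),
      weight = as.numeric(y),
      birthplace = birthplace,
      season = season,
      stringsAsFactors = FALSE
    ),
    truth = list(
      true_pheno_h2 = config$pheno_h2,
      true_pheno_m2 = config$pheno_m2,
      causal_snp_ids = geno$map$snp_id[idx],
      breeding_values = as.numeric(a),
      microbial_values = as.numeric(m)
    )
  )
}

#' Simulate a cohort with a designed recursive and a taxon-only SNP
#'
#' Constructs a cohort whose causal structure is known exactly, for
#' validating the indirect/recursive scenario classification:
#' * one marker taxon (always present) whose latent abundance is driven
#'   by two designated SNPs, each contributing `snp_taxon_var` of the
#'   latent variance;
#' * a phenotype with a polygenic background (`pheno_h2`), a direct
#'   effect of the first designated SNP (`snp_direct_var` of phenotypic
#'   variance) and an effect of the marker taxon's observed CLR
#'   abundance (`marker_y_var`), plus categorical covariates.
#'
#' The first designated SNP therefore has both a direct and a
#' taxon-mediated path to the phenotype (the recursive configuration);
#' the second affects the phenotype only through the taxon (indirect).
#' Remaining taxa are non-heritable background with a common-to-rare
#' prevalence spectrum.
#'
#' @param n_individuals,n_snps,n_taxa cohort dimensions.
#' @param marker_y_var phenotypic variance fraction of the marker-taxon
#'   effect.
#' @param snp_direct_var phenotypic variance fraction of the pleiotropic
#'   SNP's direct effect.
#' @param snp_taxon_var latent-variance fraction contributed by each
#'   designed SNP to the marker taxon.
#' @param pheno_h2 polygenic background heritability of the phenotype.
#' @param seed master seed.
#' @return list with `geno`, `abundance`, `phenotype`, `marker_taxon`,
#'   `snp_pleiotropic`, `snp_taxon_only`.
#' @export
simulate_recursive_cohort <- function(n_individuals = 800, n_snps = 1500,
                                      n_taxa = 60, marker_y_var = 0.04,
                                      snp_direct_var = 0.04,
                                      snp_taxon_var = 0.12,
                                      pheno_h2 = 0.25, seed = 1L) {
  stopifnot(2 * snp_taxon_var < 1,
            pheno_h2 + snp_direct_var + marker_y_var < 1)
  cfg <- sim_config(n_individuals = n_individuals, n_snps = n_snps,
                    n_taxa = n_taxa, taxon_h2 = 0, pheno_h2 = pheno_h2,
                    pheno_m2 = 0, seed = seed)
  geno <- simulate_genotypes(cfg)
  n <- n_individuals
  set.seed(child_seed(seed, "recursive"))

  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  maf <- pmin(allele_freq(geno), 1 - allele_freq(geno))
  common <- which(maf >= 0.2)
  designed <- sample(common, 2)
  snp_a <- geno$map$snp_id[designed[1]]  # pleiotropic
  snp_b <- geno$map$snp_id[designed[2]]  # taxon-only

  # marker taxon latent: two designed SNPs + environmental noise
  za <- zscore(geno$values[, designed[1]])
  zb <- zscore(geno$values[, designed[2]])
  lat1 <- sqrt(snp_taxon_var) * za + sqrt(snp_taxon_var) * zb +
    sqrt(1 - 2 * snp_taxon_var) * zscore(stats::rnorm(n))

  # background taxa: pure noise, common-to-rare prevalence
  prev <- c(1, seq(1, 0.5, length.out = n_taxa - 1))
  latent <- cbind(lat1, matrix(stats::rnorm(n * (n_taxa - 1)), n))
  mu <- 2 * prev + stats::rnorm(n_taxa)
  abund <- exp(sweep(latent, 2, mu, "+"))
  for (t in 2:n_taxa) {
    n_present <- max(1L, round(prev[t] * n))
    thr <- sort(latent[, t], decreasing = TRUE)[n_present]
    abund[latent[, t] < thr, t] <- 0
  }
  rel <- abund / rowSums(abund)
  rownames(rel) <- rownames(geno$values)
  taxonomy <- data.frame(
    taxon_id = sprintf("genus%03d", seq_len(n_taxa)),
    phylum = rep_len(c("Firmicutes", "Bacteroidetes"), n_taxa),
    genus = sprintf("genus%03d", seq_len(n_taxa)),
    is_classified = TRUE, stringsAsFactors = FALSE
  )
  table <- abundance_table(rel, taxonomy, kind = "relative")

  # phenotype: covariates + polygenic + direct SNP + observed marker taxon
  lv <- cfg$n_covariate_levels
  birthplace <- factor(sample.int(lv[["birthplace"]], n, replace = TRUE),
                       labels = sprintf("bp%d", seq_len(lv[["birthplace"]])))
  season <- factor(sample.int(lv[["season"]], n, replace = TRUE),
                   labels = sprintf("s%d", seq_len(lv[["season"]])))
  cov_part <- seq(-0.5, 0.5, length.out = nlevels(birthplace))[as.integer(birthplace)] +
    seq(-0.5, 0.5, length.out = nlevels(season))[as.integer(season)]
  poly_idx <- setdiff(seq_len(n_snps), designed)
  poly_idx <- sample(poly_idx, min(300L, length(poly_idx)))
  Xs <- scale(geno$values[, poly_idx, drop = FALSE])
  Xs[is.na(Xs)] <- 0
  g_poly <- zscore(Xs %*% stats::rnorm(length(poly_idx)))
  marker_feature <- zscore(clr_transform(table)[, 1])
  e_var <- 1 - pheno_h2 - snp_direct_var - marker_y_var
  y <- 50 + cov_part + sqrt(pheno_h2) * g_poly +
    sqrt(snp_direct_var) * za + sqrt(marker_y_var) * marker_feature +
    sqrt(e_var) * zscore(stats::rnorm(n))

  list(
    geno = geno,
    abundance = table,
    phenotype = data.frame(sample_id = rownames(geno$values),
                           weight = as.numeric(y),
                           birthplace = birthplace, season = season,
                           stringsAsFactors = FALSE),
    marker_taxon = "genus001",
    snp_pleiotropic = snp_a,
    snp_taxon_only = snp_b
  )
}

#' Simulate a full cohort (genotypes, microbiota, phenotype, truth)
#'
#' @param config a [sim_config].
#' @return list with `geno`, `abundance`, `phenotype`, and a merged `truth`.
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  mic <- simulate_microbiota(geno, config)
  ph <- simulate_phenotype(geno, mic$abundance, config)
  list(
    geno = geno,
    abundance = mic$abundance,
    phenotype = ph$phenotype,
    truth = list(
      true_h2_per_taxon = mic$truth$true_h2_per_taxon,
      taxon_causal_snp_ids = mic$truth$causal_snp_ids,
      true_pheno_h2 = ph$truth$true_pheno_h2,
      true_pheno_m2 = ph$truth$true_pheno_m2,
      pheno_causal_snp_ids = ph$truth$causal_snp_ids,
      breeding_values = ph$truth$breeding_values,
      microbial_values = ph$truth$microbial_values
    )
  )
}
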