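#' Bonferroni threshold or adjustment
#'
#' With `p = NULL` returns the family-wise threshold `alpha / n_tests`;
#' otherwise returns the adjusted p-values `min(1, p * n_tests)`.
#'
#' @param p vector of p-values, or `NULL` for threshold mode.
#' @param n_tests number of tests (defaults to `length(p)`).
#' @param alpha family-wise error rate for threshold mode.
#' @return threshold (scalar) or adjusted p-values.
#' @export
bonferroni <- function(p = NULL, n_tests = NULL, alpha = 0.05) {
  if (is.null(n_tests)) n_tests <- length(p)
  if (is.null(n_tests) || n_tests <= 0) stop("n_tests must be positive", call. = FALSE)
  if (is.null(p)) return(alpha / n_tests)
  pmin(1, p * n_tests)
}

# significance tier per SNP: the strictest of the passed thresholds
assign_tier <- function(p, suggestive = 1e-6, genomewide = 1e-8,
                        studywide = NULL) {
  thr <- c(suggestive = suggestive, genome_wide = genomewide)
  if (!is.null(studywide)) thr <- c(thr, study_wide = studywide)
  thr <- sort(thr, decreasing = TRUE)  # loosest first
  tier <- rep("none", length(p))
  for (k in seq_along(thr)) tier[!is.na(p) & p < thr[k]] <- names(thr)[k]
  tier
}

#' Mixed-linear-model GWAS (EMMAX-style two-stage)
#'
#' Stage 1 fits the null polygenic model `y = Xb + a + e` by REML with
#' the GRM (eigendecomposition fast path); stage 2 tests each SNP by
#' generalised least squares under the fitted covariance
#' `V = sigma2_a G + sigma2_e I`, i.e. ordinary regression after rotating
#' and whitening by the eigensystem of G. The residual scale is
#' re-estimated per SNP and the test is t-referenced with
#' `df = n - ncol(X) - 1`, which reduces exactly to the OLS p-value in
#' the `sigma2_a -> 0` limit. Missing genotypes are mean-imputed;
#' monomorphic SNPs get `p = NA`.
#'
#' @param y trait vector.
#' @param X covariate design matrix (see [build_design()]).
#' @param G GRM ([relationship_matrix], matrix, or [rel_eigen()] output).
#' @param geno a [genotype_matrix] of SNPs to test.
#' @param suggestive,genomewide significance tiers.
#' @param n_snps_total SNP count for the Bonferroni study-wide tier
#'   (default: number of SNPs tested).
#' @param studywide_alpha family-wise alpha for the study-wide tier.
#' @return data.frame of class `gwas_result`: snp_id, chr, pos, beta,
#'   se, p_value, tier; attributes `h2_null` and `var_components`.
#' @export
mlm_gwas <- function(y, X, G, geno, suggestive = 1e-6, genomewide = 1e-8,
                     n_snps_total = NULL, studywide_alpha = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- length(y)
  if (stats::sd(y) == 0) stop("trait is constant", call. = FALSE)
  eig <- if (is.list(G) && !is.null(G$vectors) &&
             !inherits(G, "relationship_matrix")) G else rel_eigen(G)
  null_fit <- reml_fit_eigen(y, X, eig, compute_se = FALSE)
  h <- null_fit$ratios[1]
  w <- 1 / (h * eig$values + (1 - h))
  sw <- sqrt(w)

  Xs <- crossprod(eig$vectors, X) * sw
  ys <- drop(crossprod(eig$vectors, y)) * sw

  Gm <- geno$values
  mono <- apply(Gm, 2, function(g) {
    g <- g[!is.na(g)]
    length(unique(g)) < 2
  })
  if (anyNA(Gm)) {
    mu <- colMeans(Gm, na.rm = TRUE)
    idx <- which(is.na(Gm), arr.ind = TRUE)
    Gm[idx] <- mu[idx[, 2]]
  } else storage.mode(Gm) <- "double"
  S <- crossprod(eig$vectors, Gm) * sw

  qrX <- qr(Xs)
  Q <- qr.Q(qrX)
  Sr <- S - Q %*% crossprod(Q, S)
  yr <- ys - drop(Q %*% crossprod(Q, ys))

  sxx <- colSums(Sr^2)
  sxy <- drop(crossprod(Sr, yr))
  beta <- sxy / sxx
  dfree <- n - ncol(X) - 1L
  rss <- sum(yr^2) - beta * sxy
  sig2 <- pmax(rss, 0) / dfree
  se <- sqrt(sig2 / sxx)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = dfree)
  bad <- mono | sxx < 1e-10
  if (any(bad)) {
    message(sum(bad), " monomorphic/degenerate SNP(s): p set to NA")
    beta[bad] <- se[bad] <- pval[bad] <- NA_real_
  }
  if (is.null(n_snps_total)) n_snps_total <- ncol(Gm)
  res <- data.frame(
    snp_id = geno$map$snp_id, chr = geno$map$chr, pos = geno$map$pos,
    beta = beta, se = se, p_value = pval,
    tier = assign_tier(pval, suggestive, genomewide,
                       studywide = bonferroni(n_tests = n_snps_total,
                                              alpha = studywide_alpha)),
    stringsAsFactors = FALSE
  )
  attr(res, "h2_null") <- unname(h)
  attr(res, "var_components") <- null_fit$sigma2
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Microbiota GWAS over the heritable feature set
#'
#' Runs one [mlm_gwas()] per eligible feature. Eligibility follows the
#' heritability scan: features with LRT `p < alpha_h2`; binary genus
#' traits additionally require prevalence at least `min_prev_binary`.
#'
#' @param features feature list as for [feature_h2_scan()] (or
#'   [build_feature_set()] output).
#' @param h2_scan the data.frame returned by [feature_h2_scan()].
#' @param prev named per-taxon prevalence (needed to filter binary traits).
#' @param X covariate design matrix.
#' @param G GRM (any form accepted by [rel_eigen()]).
#' @param geno a [genotype_matrix].
#' @param alpha_h2 LRT threshold defining heritable features.
#' @param min_prev_binary prevalence floor for binary traits.
#' @param ... passed to [mlm_gwas()].
#' @return named list of `gwas_result` tables, one per scanned feature;
#'   attribute `eligible` records the feature selection.
#' @export
mbgwas_scan <- function(features, h2_scan, prev, X, G, geno,
                        alpha_h2 = 0.05, min_prev_binary = 0.30, ...) {
  if (!is.null(features$traits)) {
    comm <- features$community
    cn <- setdiff(colnames(comm), "sample_id")
    features <- list(
      community = as.matrix(comm[, cn, drop = FALSE]),
      quantitative = features$traits$quantitative,
      binary = features$traits$binary
    )
  }
  herit <- h2_scan[h2_scan$lrt_p < alpha_h2, , drop = FALSE]
  eligible <- herit[
    herit$class != "binary" |
      (herit$feature %in% names(prev)[prev >= min_prev_binary]), ,
    drop = FALSE]
  eig <- rel_eigen(G)
  out <- list()
  for (i in seq_len(nrow(eligible))) {
    cls <- eligible$class[i]
    nm <- eligible$feature[i]
    yv <- as.matrix(features[[cls]])[, nm]
    out[[nm]] <- mlm_gwas(yv, X, eig, geno, ...)
  }
  attr(out, "eligible") <- eligible
  out
}

#' Adjust a phenotype for categorical covariates
#'
#' Residuals of the OLS regression of `y` on the covariate factor
#' dummies (with intercept).
#'
#' @param y phenotype vector.
#' @param covariates data.frame of categorical covariates.
#' @return numeric vector of residuals (orthogonal to every dummy).
#' @export
adjust_phenotype <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  covariates[] <- lapply(covariates, function(x) factor(x))
  for (nm in names(covariates)) {
    tab <- table(covariates[[nm]])
    if (any(tab == 1)) {
      warning("covariate '", nm, "' has level(s) with a single observation")
    }
  }
  stats::residuals(stats::lm(y ~ ., data = covariates))
}

#' Two-part microbiota-wide association with a phenotype
#'
#' Per genus (prefiltered to prevalence at least `min_prev`): genera with
#' prevalence below `split` enter the binary part — linear regression of
#' the adjusted phenotype on the presence indicator (abundance > 0 coded
#' 1) plus the PC covariates, reporting `beta1`; genera at or above
#' `split` enter the quantitative part — regression on the
#' CLR-transformed abundance, reporting `beta2`. P-values are
#' t-referenced and Bonferroni-corrected over all genera tested.
#'
#' @param y_adj covariate-adjusted phenotype (see [adjust_phenotype()]).
#' @param table an [abundance_table] of relative abundances.
#' @param pcs matrix of population-structure covariates (e.g. top-3
#'   genetic PCs); may be `NULL`.
#' @param split binary/quantitative prevalence split.
#' @param min_prev exclusion floor on prevalence.
#' @param pseudocount CLR pseudocount.
#' @param alpha family-wise significance level on the Bonferroni scale.
#' @return data.frame of class `mwas_result`: taxon, part, prevalence,
#'   beta, se, p_value, p_bonferroni, significant.
#' @export
mwas_two_part <- function(y_adj, table, pcs = NULL, split = 0.60,
                          min_prev = 0.015, pseudocount = 1e-6,
                          alpha = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  prev <- prevalence(table)
  test_ids <- names(prev)[prev >= min_prev]
  clr <- clr_transform(table, pseudocount)
  rows <- list()
  for (id in test_ids) {
    is_binary <- prev[id] < split
    x <- if (is_binary) as.numeric(table$values[, id] > 0) else clr[, id]
    if (stats::sd(x) == 0) next  # no variance in the coded form
    dat <- if (is.null(pcs)) data.frame(x = x) else data.frame(x = x, pcs)
    fit <- stats::lm(y_adj ~ ., data = dat)
    cf <- summary(fit)$coefficients
    rows[[id]] <- data.frame(
      taxon = id,
      part = if (is_binary) "binary" else "quantitative",
      prevalence = unname(prev[id]),
      beta = cf["x", "Estimate"], se = cf["x", "Std. Error"],
      p_value = cf["x", "Pr(>|t|)"],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_bonferroni <- bonferroni(res$p_value, n_tests = nrow(res))
  res$significant <- res$p_bonferroni < alpha
  class(res) <- c("mwas_result", "data.frame")
  res
}
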