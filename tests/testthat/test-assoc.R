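test_that("Bonferroni threshold and adjustment follow the definitions", {
  expect_equal(bonferroni(n_tests = 1), 0.05)
  expect_equal(bonferroni(p = 0.4, n_tests = 3), 1)  # capped at 1
  expect_equal(bonferroni(p = 0.01, n_tests = 3), 0.03)
  expect_error(bonferroni(n_tests = 0), "positive")
})

test_that("tier assignment is a nested threshold function", {
  p <- c(0.5, 5e-7, 5e-9, 1e-12, NA)
  tiers <- microbiability:::assign_tier(p, 1e-6, 1e-8, studywide = 2.163378e-9)
  expect_equal(tiers, c("none", "suggestive", "genome_wide", "study_wide", "none"))
  # nesting: study_wide implies genome_wide implies suggestive
  for (thr in list(c("study_wide"), c("study_wide", "genome_wide"))) {
    sel <- tiers %in% thr
    expect_true(all(p[sel] < 1e-6, na.rm = TRUE))
  }
})

test_that("MLM GWAS matches a dense GLS solve on a toy panel", {
  set.seed(80)
  n <- 50
  cfg <- sim_config(n_individuals = n, n_snps = 5, maf_range = c(0.3, 0.5),
                    seed = 80)
  geno <- simulate_genotypes(cfg)
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  X <- cbind(1, rnorm(n))
  y <- drop(chol(K + diag(0.5, n)) %*% rnorm(n)) + X[, 2] + rnorm(n)
  res <- mlm_gwas(y, X, K, geno)
  # oracle: explicit V inverse GLS per SNP with the same fitted components
  s2 <- attr(res, "var_components")
  V <- s2[[1]] * K + s2[[2]] * diag(n)
  Vi <- solve(V)
  for (j in 1:5) {
    snp <- geno$values[, j]
    W <- cbind(X, snp)
    b <- solve(t(W) %*% Vi %*% W, t(W) %*% Vi %*% y)
    r <- y - W %*% b
    sig <- drop(t(r) %*% Vi %*% r) / (n - ncol(W))
    se <- sqrt(sig * solve(t(W) %*% Vi %*% W)[3, 3])
    expect_equal(res$beta[j], b[3], tolerance = 1e-8)
    expect_equal(res$se[j], se, tolerance = 1e-8)
    tv <- b[3] / se
    expect_equal(res$p_value[j], 2 * pt(-abs(tv), n - 3), tolerance = 1e-8)
  }
})

test_that("with an identity kinship the MLM p equals plain OLS", {
  set.seed(81)
  n <- 60
  cfg <- sim_config(n_individuals = n, n_snps = 8, maf_range = c(0.2, 0.5),
                    seed = 81)
  geno <- simulate_genotypes(cfg)
  X <- matrix(1, n, 1)
  y <- rnorm(n)
  res <- mlm_gwas(y, X, diag(n), geno)  # V proportional to I exactly
  for (j in 1:8) {
    ols <- summary(lm(y ~ geno$values[, j]))$coefficients
    expect_equal(res$p_value[j], ols[2, 4], tolerance = 1e-8)
    expect_equal(res$beta[j], ols[2, 1], tolerance = 1e-8)
  }
  # monomorphic SNP gives NA with a message
  v <- geno$values
  v[, 1] <- 1L
  g2 <- genotype_matrix(v, geno$map)
  expect_message(res2 <- mlm_gwas(y, X, diag(n), g2), "monomorphic")
  expect_true(is.na(res2$p_value[1]))
})

test_that("MLM GWAS p-values are invariant to affine rescaling of y", {
  set.seed(82)
  cfg <- sim_config(n_individuals = 80, n_snps = 20, seed = 82)
  geno <- simulate_genotypes(cfg)
  K <- crossprod(matrix(rnorm(80 * 80), 80)) / 80
  X <- matrix(1, 80, 1)
  y <- rnorm(80)
  p1 <- mlm_gwas(y, X, K, geno)$p_value
  p2 <- mlm_gwas(3 + 5 * y, X, K, geno)$p_value
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("phenotype adjustment removes covariate structure exactly", {
  set.seed(83)
  n <- 40
  cov <- data.frame(bp = sample(c("a", "b"), n, TRUE),
                    se = sample(c("x", "y"), n, TRUE))
  y <- rnorm(n) + 2 * (cov$bp == "b") - 1.5 * (cov$se == "y")
  adj <- adjust_phenotype(y, cov)
  D <- model.matrix(~ bp + se, cov)
  expect_true(all(abs(crossprod(D, adj)) < 1e-10))
  # two-group hand case: residuals are group-mean deviations
  y2 <- c(1, 2, 3, 10, 11, 12)
  g2 <- data.frame(g = rep(c("a", "b"), each = 3))
  expect_equal(unname(adjust_phenotype(y2, g2)), rep(c(-1, 0, 1), 2))
  expect_warning(adjust_phenotype(y2, data.frame(g = c("a", "a", "a", "a", "a", "b"))),
                 "single observation")
})

test_that("two-part MWAS codes presence and abundance parts correctly", {
  expect_equal(as.numeric(c(0, 0.2, 0, 0.5) > 0), c(0, 1, 0, 1))
  set.seed(84)
  n <- 60
  # genus1: low prevalence -> binary part; genus2: common -> quantitative
  g1 <- ifelse(runif(n) < 0.3, runif(n), 0)
  g2 <- runif(n) + 0.5
  g3 <- runif(n) + 0.2
  tab <- toy_rel(cbind(g1 = g1, g2 = g2, g3 = g3))
  yv <- rnorm(n)
  res <- mwas_two_part(yv, tab, pcs = NULL, split = 0.60)
  expect_equal(res$part[res$taxon == "g1"], "binary")
  expect_equal(res$part[res$taxon == "g2"], "quantitative")
  # every tested genus is in exactly one part
  expect_equal(anyDuplicated(res$taxon), 0)
  # closed-form simple-regression oracle on a 6-point example
  y6 <- c(2, 4, 5, 4, 5, 7)
  x6 <- c(0, 0, 1, 1, 1, 1)
  m <- cbind(t1 = c(0, 0, 3, 1, 2, 9) + 0, t2 = rep(1, 6))
  tab6 <- toy_rel(m + cbind(rep(0.0, 6), rep(1, 6)))
  res6 <- mwas_two_part(y6, tab6, pcs = NULL, split = 0.9)
  b1 <- sum((x6 - mean(x6)) * (y6 - mean(y6))) / sum((x6 - mean(x6))^2)
  r <- y6 - mean(y6) - b1 * (x6 - mean(x6))
  s2 <- sum(r^2) / 4
  se <- sqrt(s2 / sum((x6 - mean(x6))^2))
  row1 <- res6[res6$taxon == "t1", ]
  expect_equal(row1$beta, b1, tolerance = 1e-10)
  expect_equal(row1$se, se, tolerance = 1e-10)
  expect_equal(row1$p_value, 2 * pt(-abs(b1 / se), 4), tolerance = 1e-10)
})

test_that("an influential genus reaches Bonferroni significance reliably", {
  hits <- sapply(1:20, function(s) {
    set.seed(900 + s)
    n <- 800
    k <- 80
    m <- matrix(exp(rnorm(n * k)), n)
    colnames(m) <- sprintf("g%02d", 1:k)
    tab <- toy_rel(m)
    clr1 <- clr_transform(tab)[, 1]
    yv <- sqrt(0.10) * scale(clr1) + sqrt(0.90) * rnorm(n)
    res <- mwas_two_part(drop(yv), tab, pcs = NULL)
    res$significant[res$taxon == "g01"]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("mbGWAS scans only eligible features", {
  cfg <- sim_config(n_individuals = 120, n_snps = 150, n_taxa = 20, seed = 85)
  co <- simulate_cohort(cfg)
  grm <- compute_grm(qc_genotypes(co$geno))
  rel <- filter_genera(co$abundance)
  feats <- build_feature_set(rel, k_pcoa = 3)
  X <- build_design(co$phenotype[, c("birthplace", "season")])
  scan <- feature_h2_scan(feats, X, grm)
  prev <- prevalence(rel)
  out <- mbgwas_scan(feats, scan, prev, X, grm, co$geno)
  el <- attr(out, "eligible")
  # all scanned features were heritable at the LRT threshold
  expect_true(all(el$lrt_p < 0.05))
  expect_setequal(names(out), el$feature)
  # no binary feature below 30% prevalence enters the scan
  low_prev <- names(prev)[prev < 0.30]
  expect_length(intersect(el$feature[el$class == "binary"], low_prev), 0)
})
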