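test_that("ASV filter applies the presence and total-count rules", {
  m <- rbind(c(1, 0, 2, 3, 10),
             c(1, 0, 2, 0, 10),
             c(0, 5, 2, 0, 10),
             c(0, 0, 0, 3, 10))
  colnames(m) <- paste0("asv", 1:5)
  tab <- abundance_table(m, kind = "counts")
  out <- filter_asvs(tab, min_samples = 3, min_total = 5)
  # asv1: 2 samples -> removed; asv2: 1 sample -> removed;
  # asv3: 3 samples, total 6 > 5 -> kept; asv4: 2 samples -> removed;
  # asv5: 4 samples, total 40 -> kept
  expect_equal(colnames(out$values), c("asv3", "asv5"))
  expect_error(filter_asvs(toy_rel(m + 1)), "count table")
  expect_warning(filter_asvs(tab, min_samples = 5), "no features")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  m <- rbind(a = c(30, 20, 50), b = c(5, 5, 5), c = c(100, 0, 0))
  tab <- abundance_table(m, kind = "counts")
  expect_warning(out <- rarefy(tab, depth = 50, seed = 1), "below depth")
  expect_equal(rownames(out$values), c("a", "c"))
  expect_true(all(rowSums(out$values) == 50))
  # depth equal to the total leaves counts unchanged
  out2 <- rarefy(abundance_table(m[1, , drop = FALSE], kind = "counts"),
                 depth = 100, seed = 1)
  expect_equal(unname(out2$values[1, ]), c(30, 20, 50))
  # hypergeometric mean: E[count_t] = depth * count_t / total
  set.seed(7)
  reps <- replicate(200, {
    r <- rarefy(abundance_table(m[1, , drop = FALSE], kind = "counts"),
                depth = 40, seed = sample.int(1e6, 1))
    r$values[1, 1]
  })
  mu <- 40 * 30 / 100
  v <- 40 * 0.3 * 0.7 * (100 - 40) / (100 - 1)  # hypergeometric variance
  expect_lt(abs(mean(reps) - mu), 3 * sqrt(v / 200))
})

test_that("genus filter drops unclassified and low-signal genera", {
  # 5 genera x 6 samples designed so the survivor set is hand-checkable
  m <- rbind(c(10, 1, 1, 1, 1e-9),
             c(10, 1, 1, 0, 1e-9),
             c(10, 1, 1, 0, 1e-9),
             c(10, 1, 0, 0, 1e-9),
             c(10, 1, 0, 0, 1e-9),
             c(10, 1, 0, 0, 1e-9))
  colnames(m) <- paste0("g", 1:5)
  tab <- toy_rel(m, classified = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  out <- filter_genera(tab, min_mean_abund = 1e-6, min_samples = 3)
  # g1 kept; g2 removed (unclassified, despite high abundance);
  # g3 in exactly 3 samples -> removed (strictly more than 3 required);
  # g4 in 1 sample -> removed; g5 everywhere but mean below 1e-6 -> removed
  expect_equal(colnames(out$values), "g1")
  expect_equal(unname(rowSums(out$values)), rep(1, 6))
})

test_that("prevalence is the detection proportion", {
  m <- rbind(c(1, 0, 2), c(1, 0, 0), c(1, 0, 3), c(1, 0, 4))
  tab <- abundance_table(m, kind = "counts")
  expect_equal(unname(prevalence(tab)), c(1, 0, 0.75))
})

test_that("trait classification partitions genera at the printed thresholds", {
  n <- 100
  prevs <- c(0.59, 0.60, 0.01, 0.015, 1.0)
  m <- sapply(prevs, function(q) {
    x <- c(rep(1, round(q * n)), rep(0, n - round(q * n)))
    x + (x > 0) * runif(n)
  })
  colnames(m) <- paste0("g", 1:5)
  m[, "g5"] <- m[, "g5"] + 0.5  # keep rows nonzero
  tab <- toy_rel(m)
  fs <- classify_traits(tab, low = 0.015, split = 0.60)
  expect_true("g1" %in% fs$binary_ids)            # 0.59 -> binary
  expect_true("g2" %in% fs$quantitative_ids)      # exactly 0.60 -> quantitative
  expect_true("g3" %in% fs$excluded)              # 0.01 -> excluded
  expect_true("g4" %in% fs$binary_ids)            # boundary 0.015 included
  expect_true("g5" %in% fs$quantitative_ids)
  # partition property: disjoint and exhaustive
  all_ids <- colnames(tab$values)
  expect_setequal(c(fs$binary_ids, fs$quantitative_ids, fs$excluded), all_ids)
  expect_length(intersect(fs$binary_ids, fs$quantitative_ids), 0)
  expect_true(all(fs$binary %in% 0:1))
})

test_that("CLR transform centers each sample's log abundances", {
  # uniform composition -> all zeros
  u <- matrix(1 / 4, 3, 4)
  expect_true(all(abs(clr_transform(u, 1e-6)) < 1e-12))
  # closed form for a 2-taxon sample
  x <- matrix(c(0.8, 0.2), 1)
  out <- clr_transform(x, 1e-6)
  expect_equal(out[1, 1], 0.5 * log(0.800001 / 0.200001), tolerance = 1e-12)
  expect_equal(out[1, 2], -0.5 * log(0.800001 / 0.200001), tolerance = 1e-12)
  # row-sum zero on random compositions
  set.seed(1)
  r <- matrix(rexp(50), 5)
  r <- r / rowSums(r)
  expect_true(all(abs(rowSums(clr_transform(r, 1e-6))) < 1e-10))
  expect_error(clr_transform(r, 0), "pseudocount")
})

test_that("alpha diversity matches the closed-form estimators", {
  a <- alpha_diversity(c(5, 5, 5))
  expect_equal(a$chao1, 3)          # no singletons -> Chao1 = S_obs
  expect_equal(a$S_obs, 3)
  b <- alpha_diversity(c(1, 1, 2, 3))
  expect_equal(b$chao1, 4 + 2 * 1 / (2 * 2))  # bias-corrected: 4.5
  expect_equal(b$F1, 2)
  expect_equal(b$F2, 1)
  # equal proportions over k taxa -> Shannon = ln k
  expect_equal(alpha_diversity(rep(7, 9))$shannon, log(9))
  expect_error(alpha_diversity(c(0, 0)), "all-zero")
  # Chao1 >= richness on random samples
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(30, lambda = sample(1:5, 1))
    if (all(x == 0)) next
    d <- suppressWarnings(alpha_diversity(x))  # ACE NaN-able on tiny draws
    expect_gte(d$chao1, d$S_obs)
  }
})

test_that("F:B ratio divides phylum sums and guards zero denominators", {
  m <- rbind(c(0.6, 0.3, 0.1), c(0.45, 0.45, 0.1), c(0.9, 0, 0.1))
  tab <- toy_rel(m, phylum = c("Firmicutes", "Bacteroidetes", "Proteobacteria"))
  r <- unname(fb_ratio(tab))
  expect_equal(r[1], 2)
  expect_equal(r[2], 1)
  expect_true(is.na(r[3]))
  expect_error(fb_ratio(toy_rel(m, phylum = rep("Proteobacteria", 3))),
               "no taxa")
})

test_that("Bray-Curtis PCoA matches a brute-force eigendecomposition", {
  # disjoint supports -> distance 1; identical samples -> 0
  m <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0.5, 0.5))
  d <- as.matrix(vegan::vegdist(m, "bray"))
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 3], 0)

  set.seed(3)
  m4 <- matrix(rexp(4 * 6), 4)
  m4 <- m4 / rowSums(m4)
  res <- bray_curtis_pcoa(m4, k = 2)
  # oracle: double-centred Gower matrix eigendecomposition, dense
  D <- as.matrix(vegan::vegdist(m4, "bray"))
  A <- -0.5 * D^2
  J <- diag(4) - matrix(1 / 4, 4, 4)
  G <- J %*% A %*% J
  e <- eigen(G, symmetric = TRUE)
  oracle <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  for (k in 1:2) {
    expect_lt(min(max(abs(res$scores[, k] - oracle[, k])),
                  max(abs(res$scores[, k] + oracle[, k]))), 1e-8)
  }
  # variance fractions use only positive eigenvalues
  expect_equal(res$var_explained[1], e$values[1] / sum(e$values[e$values > 1e-12]),
               tolerance = 1e-8)
  # sample-order invariance (up to sign)
  perm <- c(3, 1, 4, 2)
  res_p <- bray_curtis_pcoa(m4[perm, ], k = 2)
  for (k in 1:2) {
    expect_lt(min(max(abs(res_p$scores[, k] - res$scores[perm, k])),
                  max(abs(res_p$scores[, k] + res$scores[perm, k]))), 1e-8)
  }
  expect_error(bray_curtis_pcoa(m4, k = 4), "smaller")
})
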