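#' Quality control on a genotype matrix
#'
#' Retains biallelic autosomal SNPs with minor-allele frequency at least
#' `maf_min` and per-SNP missingness at most `max_missing`; sex
#' chromosomes (non-numeric chromosome codes, or `X`/`Y`/`MT`) are
#' removed when `autosomes_only`.
#'
#' @param geno a [genotype_matrix].
#' @param maf_min minimum minor-allele frequency (inclusive).
#' @param max_missing maximum missing-call fraction per SNP (inclusive).
#' @param autosomes_only drop sex-chromosome and mitochondrial SNPs.
#' @return the filtered [genotype_matrix] with an attribute `qc_counts`
#'   recording the filtering funnel.
#' @export
qc_genotypes <- function(geno, maf_min = 0.05, max_missing = 0.3,
                         autosomes_only = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  chr <- as.character(geno$map$chr)
  autosomal <- if (autosomes_only) {
    !is.na(suppressWarnings(as.numeric(chr))) &
      !(toupper(chr) %in% c("X", "Y", "MT", "M"))
  } else rep(TRUE, length(chr))
  miss <- colMeans(is.na(geno$values))
  af <- allele_freq(geno)
  maf <- pmin(af, 1 - af)
  keep <- autosomal & miss <= max_missing & !is.na(maf) & maf >= maf_min
  if (!any(keep)) stop("no SNPs survive QC", call. = FALSE)
  out <- genotype_matrix(geno$values[, keep, drop = FALSE],
                         geno$map[keep, , drop = FALSE])
  attr(out, "qc_counts") <- c(
    input = length(keep),
    non_autosomal = sum(!autosomal),
    high_missing = sum(autosomal & miss > max_missing),
    low_maf = sum(autosomal & miss <= max_missing & (is.na(maf) | maf < maf_min)),
    retained = sum(keep)
  )
  out
}

#' Genetic relationship matrix (Yang estimator)
#'
#' Off-diagonals
#' `A_jk = (1/N) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`;
#' diagonals
#' `A_jj = 1 + (1/N) sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`.
#' Missing genotypes are mean-imputed per SNP before computation.
#'
#' @param geno a QC'd [genotype_matrix]; monomorphic SNPs are an error.
#' @param p per-SNP allele frequencies; default: estimated from the data.
#' @return a [relationship_matrix] with `source = "GRM"`.
#' @export
compute_grm <- function(geno, p = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$values
  if (is.null(p)) p <- allele_freq(geno)
  if (length(p) == 1L) p <- rep(p, ncol(X))
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP reached compute_grm; run qc_genotypes first",
         call. = FALSE)
  }
  # mean imputation
  if (anyNA(X)) {
    mu <- 2 * p
    for (j in which(colSums(is.na(X)) > 0)) {
      X[is.na(X[, j]), j] <- mu[j]
    }
  }
  N <- ncol(X)
  den <- 2 * p * (1 - p)
  W <- sweep(sweep(X, 2, 2 * p, "-"), 2, sqrt(den), "/")
  A <- tcrossprod(W) / N
  diag(A) <- 1 + colMeans((t(X)^2 - (1 + 2 * p) * t(X) + 2 * p^2) / den)
  dimnames(A) <- list(rownames(geno$values), rownames(geno$values))
  relationship_matrix(A, "GRM", n_markers = N)
}

#' Microbial relationship matrix from z-scored abundances
#'
#' Columns (taxa) are z-scored with the sample standard deviation
#' (zero-variance taxa dropped with a warning) and `M = Z Z' / m`, so
#' `trace(M) = n - 1` exactly.
#'
#' @param table an [abundance_table] (or numeric matrix) of abundances.
#' @return a [relationship_matrix] with `source = "MRM"`.
#' @export
compute_mrm <- function(table) {
  v <- if (inherits(table, "abundance_table")) table$values else table
  Z <- scale(v)
  drop <- is.na(colSums(Z))
  if (all(drop)) stop("all taxa have zero variance", call. = FALSE)
  if (any(drop)) {
    warning(sum(drop), " zero-variance taxa dropped from the MRM")
    Z <- Z[, !drop, drop = FALSE]
  }
  M <- tcrossprod(Z) / ncol(Z)
  dimnames(M) <- list(rownames(v), rownames(v))
  relationship_matrix(M, "MRM", n_markers = ncol(Z))
}

#' Principal components of a relationship matrix
#'
#' Top-k eigenvectors scaled by the square root of their eigenvalues
#' (deterministic up to sign).
#'
#' @param rel a [relationship_matrix] (or symmetric matrix).
#' @param k number of components, `k < n`.
#' @return n x k score matrix; attribute `degenerate` flags an
#'   (effectively) isotropic spectrum.
#' @export
genetic_pcs <- function(rel, k = 5L) {
  V <- if (inherits(rel, "relationship_matrix")) rel$values else rel
  if (max(abs(V - t(V))) > 1e-8) stop("input must be symmetric", call. = FALSE)
  n <- nrow(V)
  if (k >= n) stop("k must be < n", call. = FALSE)
  e <- eigen(V, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(k)], 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  rownames(scores) <- rownames(V)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  attr(scores, "degenerate") <- diff(range(e$values)) < 1e-10 * max(abs(e$values), 1)
  scores
}

#' Mantel test between two relationship matrices
#'
#' Pearson correlation of the vectorised off-diagonal upper triangles,
#' with a one-sided (upper tail) permutation p-value under simultaneous
#' row/column permutation of `B`: `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
#'
#' @param A,B [relationship_matrix] objects (or symmetric matrices) over
#'   the same samples in the same order.
#' @param n_perm number of random permutations.
#' @param seed permutation seed.
#' @param exhaustive enumerate all `n!` permutations instead of sampling
#'   (only sensible for very small n); the p-value is then
#'   `#{r_perm >= r_obs} / n!` over the full group.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 9999L, seed = 1L, exhaustive = FALSE) {
  Av <- if (inherits(A, "relationship_matrix")) A$values else A
  Bv <- if (inherits(B, "relationship_matrix")) B$values else B
  n <- nrow(Av)
  stopifnot(nrow(Bv) == n, n >= 4)
  if (!is.null(rownames(Av)) && !is.null(rownames(Bv))) {
    assert_aligned(rownames(Av), rownames(Bv), "relationship matrices")
  }
  ut <- upper.tri(Av)
  a <- Av[ut]
  if (stats::sd(a) == 0 || stats::sd(Bv[ut]) == 0) {
    stop("constant off-diagonals: Mantel r undefined", call. = FALSE)
  }
  r_obs <- stats::cor(a, Bv[ut])
  perm_r <- function(ord) stats::cor(a, Bv[ord, ord][ut])
  if (exhaustive) {
    perms <- permutations_of(n)
    rs <- apply(perms, 1, perm_r)
    p <- mean(rs >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    rs <- replicate(n_perm, perm_r(sample.int(n)))
    p <- (sum(rs >= r_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  list(r = r_obs, p = p, n_perm = n_used)
}
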