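# shared fixtures, all built in code

tiny_config <- function(seed = 1L, ...) {
  sim_config(n_individuals = 120, n_snps = 300, n_taxa = 30,
             n_causal_snps_pheno = 50, seed = seed, ...)
}

# hand-sized genotype matrix from explicit values
toy_geno <- function(values, chr = NULL, pos = NULL) {
  p <- ncol(values)
  storage.mode(values) <- "integer"
  genotype_matrix(values, data.frame(
    snp_id = sprintf("s%d", seq_len(p)),
    chr = chr %||% rep(1L, p),
    pos = pos %||% seq_len(p) * 100L
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# relative abundance table from a plain matrix (rows renormalised)
toy_rel <- function(m, phylum = NULL, classified = TRUE) {
  m <- m / rowSums(m)
  k <- ncol(m)
  abundance_table(m, data.frame(
    taxon_id = colnames(m) %||% sprintf("g%02d", seq_len(k)),
    phylum = phylum %||% rep("Firmicutes", k),
    genus = sprintf("g%02d", seq_len(k)),
    is_classified = rep_len(classified, k)
  ), kind = "relative")
}

# independent dense evaluation of the restricted log-likelihood, written
# from the definition (determinant + quadratic form via solve), used as
# the oracle for the REML fitter
oracle_reml_loglik <- function(y, X, K, s2g, s2e) {
  n <- length(y)
  p <- ncol(X)
  V <- s2g * K + s2e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}
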