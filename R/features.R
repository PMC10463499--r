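#' Filter low-occurrence ASVs/taxa from a count table
#'
#' Retains features present (count > 0) in at least `min_samples` samples
#' and with total count strictly greater than `min_total`; column order is
#' preserved.
#'
#' @param table an [abundance_table] of counts.
#' @param min_samples minimum number of samples with a nonzero count.
#' @param min_total total-count threshold (strict).
#' @return the filtered [abundance_table].
#' @export
filter_asvs <- function(table, min_samples = 3L, min_total = 5L) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "counts") {
    stop("filter_asvs expects a count table", call. = FALSE)
  }
  keep <- colSums(table$values > 0) >= min_samples &
    colSums(table$values) > min_total
  if (!any(keep)) warning("no features survive the ASV filter")
  subset_taxa(table, keep)
}

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (hypergeometric draw); samples whose total is below `depth` are dropped
#' with a warning.
#'
#' @param table an [abundance_table] of counts.
#' @param depth target library size.
#' @param seed integer seed for the subsampling.
#' @return the rarefied [abundance_table]; every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"), depth >= 1)
  if (table$kind != "counts") stop("rarefy expects a count table", call. = FALSE)
  totals <- rowSums(table$values)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped")
  }
  v <- table$values[keep, , drop = FALSE]
  set.seed(seed)
  # vegan warns whenever depth > smallest nonzero count, which is the
  # normal situation for a library-size depth; totals are checked above
  out <- suppressWarnings(vegan::rrarefy(v, sample = depth))
  abundance_table(out, table$taxonomy, kind = "counts")
}

#' Filter a relative-abundance genus table
#'
#' Removes unclassified genera, then retains genera with mean relative
#' abundance strictly greater than `min_mean_abund` and occurrence in
#' strictly more than `min_samples` samples. Rows are renormalised over
#' the survivors.
#'
#' @param table an [abundance_table] of relative abundances.
#' @param min_mean_abund mean relative-abundance threshold (proportion).
#' @param min_samples occurrence threshold (strictly greater than).
#' @return the filtered [abundance_table].
#' @export
filter_genera <- function(table, min_mean_abund = 1e-6, min_samples = 3L) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "relative") {
    stop("filter_genera expects a relative-abundance table", call. = FALSE)
  }
  keep <- table$taxonomy$is_classified &
    colMeans(table$values) > min_mean_abund &
    colSums(table$values > 0) > min_samples
  subset_taxa(table, keep)
}

#' Per-taxon prevalence
#'
#' @param table an [abundance_table].
#' @return named numeric vector: proportion of samples in which each taxon
#'   is detected (value > 0).
#' @export
prevalence <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  colMeans(table$values > 0)
}

#' Centered log-ratio transform
#'
#' Per sample, `log(x + pseudocount)` minus its mean over the included
#' taxa; every output row sums to zero.
#'
#' @param x an [abundance_table] (relative) or a non-negative matrix.
#' @param pseudocount positive offset added before the log.
#' @return matrix of CLR values, same dimnames as the input.
#' @export
clr_transform <- function(x, pseudocount = 1e-6) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  v <- if (inherits(x, "abundance_table")) x$values else x
  lg <- log(v + pseudocount)
  sweep(lg, 1, rowMeans(lg), "-")
}

#' Alpha diversity of a single sample
#'
#' Richness (observed taxa), bias-corrected Chao1
#' `S_obs + F1(F1-1)/(2(F2+1))`, ACE (abundance-based coverage estimator,
#' rare/abundant cutoff 10) and Shannon entropy in nats.
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @return list with `S_obs`, `F1`, `F2`, `chao1`, `ace`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (all(counts == 0)) stop("all-zero sample has undefined diversity", call. = FALSE)
  est <- vegan::estimateR(round(counts))
  p <- counts[counts > 0] / sum(counts)
  s_obs <- sum(counts > 0)
  ace <- unname(est["S.ACE"])
  # no rare taxa (every count > 10): nothing to extrapolate, ACE = S_obs
  if (!is.finite(ace) && !any(counts > 0 & counts <= 10)) ace <- s_obs
  list(
    S_obs = s_obs,
    F1 = sum(counts == 1),
    F2 = sum(counts == 2),
    chao1 = unname(est["S.chao1"]),
    ace = ace,
    shannon = -sum(p * log(p))
  )
}

#' Alpha diversity for every sample of a count table
#'
#' @param table an [abundance_table] of counts (normally rarefied).
#' @return data.frame with one row per sample.
#' @export
alpha_diversity_table <- function(table) {
  stopifnot(inherits(table, "abundance_table"), table$kind == "counts")
  res <- apply(table$values, 1, alpha_diversity)
  out <- do.call(rbind, lapply(res, as.data.frame))
  out$sample_id <- rownames(table$values)
  out[, c("sample_id", "S_obs", "F1", "F2", "chao1", "ace", "shannon")]
}

#' Firmicutes:Bacteroidetes ratio per sample
#'
#' @param table an [abundance_table] with phylum labels.
#' @return numeric vector; `NA` where the Bacteroidetes sum is zero.
#' @export
fb_ratio <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  ph <- table$taxonomy$phylum
  f <- ph %in% c("Firmicutes")
  b <- ph %in% c("Bacteroidetes", "Bacteroidota")
  if (!any(f) && !any(b)) {
    stop("no taxa labelled Firmicutes or Bacteroidetes", call. = FALSE)
  }
  fs <- rowSums(table$values[, f, drop = FALSE])
  bs <- rowSums(table$values[, b, drop = FALSE])
  ifelse(bs == 0, NA_real_, fs / bs)
}

#' Principal coordinates of Bray-Curtis dissimilarities
#'
#' Classical metric MDS (double-centred Gower matrix) of the Bray-Curtis
#' distance matrix. Negative eigenvalues are ignored both as axes and in
#' the variance-explained denominator (no Cailliez correction).
#'
#' @param table an [abundance_table] (relative) or non-negative matrix.
#' @param k number of axes to return.
#' @return list with `scores` (n x k, eigenvector scaled by sqrt
#'   eigenvalue), `eig` (positive eigenvalues) and `var_explained`
#'   (fraction of positive-eigenvalue variance per returned axis).
#' @export
bray_curtis_pcoa <- function(table, k = 5L) {
  v <- if (inherits(table, "abundance_table")) table$values else table
  n <- nrow(v)
  if (k >= n) stop("k must be smaller than the number of samples", call. = FALSE)
  d <- vegan::vegdist(v, method = "bray")
  pc <- ape::pcoa(d)
  eig <- pc$values$Eigenvalues
  pos <- eig[eig > 1e-12]
  k_eff <- min(k, ncol(pc$vectors))
  scores <- pc$vectors[, seq_len(k_eff), drop = FALSE]
  colnames(scores) <- sprintf("PCoA%d", seq_len(k_eff))
  rownames(scores) <- rownames(v)
  list(
    scores = scores,
    eig = pos,
    var_explained = pos[seq_len(k_eff)] / sum(pos)
  )
}

#' Partition genera into quantitative and binary microbial traits
#'
#' Genera detected in fewer than `low` of samples are excluded; prevalence
#' in `[low, split)` makes a presence/absence binary trait; prevalence
#' `>= split` makes a quantitative trait carried as the CLR-transformed
#' relative abundance (the boundary itself is assigned to the quantitative
#' class).
#'
#' @param table an [abundance_table] of relative abundances.
#' @param low exclusion threshold (proportion of samples).
#' @param split binary/quantitative prevalence split.
#' @param pseudocount CLR pseudocount.
#' @return list of class `microbial_feature_set` with `quantitative`
#'   (CLR matrix), `binary` (0/1 matrix), `prevalence`, and the id sets
#'   `excluded`, `binary_ids`, `quantitative_ids`.
#' @export
classify_traits <- function(table, low = 0.015, split = 0.60,
                            pseudocount = 1e-6) {
  stopifnot(inherits(table, "abundance_table"))
  prev <- prevalence(table)
  excluded <- names(prev)[prev < low]
  binary_ids <- names(prev)[prev >= low & prev < split]
  quant_ids <- names(prev)[prev >= split]
  clr <- clr_transform(table, pseudocount)
  structure(list(
    quantitative = clr[, quant_ids, drop = FALSE],
    binary = (table$values[, binary_ids, drop = FALSE] > 0) + 0L,
    prevalence = prev,
    excluded = excluded,
    binary_ids = binary_ids,
    quantitative_ids = quant_ids
  ), class = "microbial_feature_set")
}

#' @export
print.microbial_feature_set <- function(x, ...) {
  cat("microbial_feature_set:", length(x$quantitative_ids), "quantitative,",
      length(x$binary_ids), "binary,", length(x$excluded), "excluded taxa\n")
  invisible(x)
}

#' Assemble the full microbial feature set for heritability analysis
#'
#' Community traits (richness, Chao1, ACE, Shannon, F:B ratio, top-k PCoA
#' scores of the Bray-Curtis dissimilarity) plus the per-genus
#' quantitative (CLR) and binary (presence) traits from
#' [classify_traits()].
#'
#' @param rel an [abundance_table] of relative abundances (genus level,
#'   already filtered).
#' @param counts optional matching count table for the alpha-diversity
#'   indices; when `NULL` they are computed from scaled relative
#'   abundances (`round(rel * scale_depth)`).
#' @param k_pcoa number of PCoA axes.
#' @param scale_depth pseudo-depth used when `counts` is `NULL`.
#' @inheritParams classify_traits
#' @return list with `community` (data.frame of community traits),
#'   `traits` (the `microbial_feature_set`).
#' @export
build_feature_set <- function(rel, counts = NULL, k_pcoa = 5L,
                              low = 0.015, split = 0.60,
                              pseudocount = 1e-6, scale_depth = 1e5) {
  stopifnot(inherits(rel, "abundance_table"), rel$kind == "relative")
  if (is.null(counts)) {
    counts <- abundance_table(round(rel$values * scale_depth), rel$taxonomy,
                              kind = "counts")
  }
  alpha <- alpha_diversity_table(counts)
  pcoa <- bray_curtis_pcoa(rel, k = k_pcoa)
  community <- data.frame(
    sample_id = rownames(rel$values),
    richness = alpha$S_obs,
    chao1 = alpha$chao1,
    ace = alpha$ace,
    shannon = alpha$shannon,
    fb_ratio = fb_ratio(rel),
    stringsAsFactors = FALSE
  )
  community <- cbind(community, as.data.frame(pcoa$scores))
  traits <- classify_traits(rel, low = low, split = split,
                            pseudocount = pseudocount)
  list(community = community, traits = traits, pcoa = pcoa)
}
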