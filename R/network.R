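#' Core taxa: genera detected in every sample
#'
#' @param table an [abundance_table].
#' @return character vector of taxon ids with prevalence exactly 1.
#' @export
core_taxa <- function(table) {
  prev <- prevalence(table)
  names(prev)[prev == 1]
}

#' Spearman correlation with p-values for all column pairs
#'
#' Tie-corrected Spearman r (Pearson on mid-ranks). P-values from the
#' t approximation `t = r * sqrt((n-2)/(1-r^2))`; for `n < 10` an exact
#' permutation p over all `n!` orderings is used instead.
#'
#' @param m numeric matrix (samples x variables).
#' @return list of matrices `r` and `p`.
#' @keywords internal
spearman_all_pairs <- function(m) {
  n <- nrow(m)
  r <- stats::cor(m, method = "spearman")
  if (n < 10) {
    p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(r))
    perms <- permutations_of(n)
    rk <- apply(m, 2, rank)
    for (i in seq_len(ncol(m) - 1)) {
      for (j in (i + 1):ncol(m)) {
        robs <- r[i, j]
        rs <- apply(perms, 1, function(pp) stats::cor(rk[, i], rk[pp, j]))
        p[i, j] <- p[j, i] <- mean(abs(rs) >= abs(robs) - 1e-12)
      }
    }
    diag(p) <- 0
  } else {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(r) >= 1 - 1e-12] <- 0
    diag(p) <- 0
  }
  list(r = r, p = p)
}

# all n! permutations of seq_len(n), rows = permutations
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (s in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[s, ]])
      row <- row + 1L
    }
  }
  out
}

#' Build a genus co-occurrence network from CLR abundances
#'
#' Genera are prefiltered (summed relative abundance and prevalence
#' floors), all-pairs Spearman correlations are computed on the CLR
#' values, p-values are Benjamini-Hochberg adjusted over all tested
#' pairs, and edges are kept iff `|r| > r_threshold` and adjusted
#' `p < alpha`.
#'
#' @param table an [abundance_table] of relative abundances.
#' @param min_summed_abund exclusion floor on a genus's summed relative
#'   abundance across samples (proportion).
#' @param min_prev exclusion floor on prevalence.
#' @param r_threshold absolute Spearman correlation threshold (strict).
#' @param alpha BH-adjusted p threshold (strict).
#' @param pseudocount CLR pseudocount.
#' @return list of class `cooccurrence_network`: `graph` (igraph),
#'   `edges` (data.frame i, j, r, p, p_adj), `nodes` (taxon ids kept).
#' @export
build_network <- function(table, min_summed_abund = 1e-4, min_prev = 0.015,
                          r_threshold = 0.6, alpha = 0.05,
                          pseudocount = 1e-6) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table$values) < 3) stop("need at least 3 samples", call. = FALSE)
  prev <- prevalence(table)
  keep <- colSums(table$values) >= min_summed_abund & prev >= min_prev
  if (sum(keep) < 3) stop("fewer than 3 taxa survive the prefilter", call. = FALSE)
  clr <- clr_transform(table$values[, keep, drop = FALSE], pseudocount)

  sp <- spearman_all_pairs(clr)
  ut <- upper.tri(sp$r)
  idx <- which(ut, arr.ind = TRUE)
  edges <- data.frame(
    i = colnames(clr)[idx[, 1]],
    j = colnames(clr)[idx[, 2]],
    r = sp$r[ut],
    p = sp$p[ut],
    stringsAsFactors = FALSE
  )
  edges$p_adj <- stats::p.adjust(edges$p, method = "BH")
  kept <- edges[abs(edges$r) > r_threshold & edges$p_adj < alpha, , drop = FALSE]

  g <- igraph::graph_from_data_frame(
    kept[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = colnames(clr))
  )
  if (nrow(kept)) igraph::E(g)$weight <- abs(kept$r)
  structure(list(graph = g, edges = kept, all_pairs = edges,
                 nodes = colnames(clr)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Module detection by greedy modularity maximisation
#'
#' Deterministic greedy agglomeration (Clauset-Newman-Moore, via igraph);
#' isolated nodes become singleton modules. A seeded Louvain alternative
#' is available.
#'
#' @param net a `cooccurrence_network`.
#' @param method `"greedy"` (default, deterministic) or `"louvain"`.
#' @param seed seed used only for `"louvain"`.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
detect_modules <- function(net, method = c("greedy", "louvain"), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(net, "cooccurrence_network"))
  if (igraph::ecount(net$graph) < 1) stop("network has no edges", call. = FALSE)
  g <- net$graph
  if (method == "greedy") {
    cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  } else {
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  }
  membership <- igraph::membership(cl)
  q <- igraph::modularity(g, membership, weights = igraph::E(g)$weight)
  # guard against greedy merge-sequence float ties (e.g. a single clique):
  # the connected-components partition is a valid candidate and also makes
  # every singleton component its own module
  comp <- igraph::components(g)$membership
  q_comp <- igraph::modularity(g, comp, weights = igraph::E(g)$weight)
  if (q_comp >= q - 1e-12) {
    membership <- comp
    q <- q_comp
  }
  list(membership = membership, modularity = q)
}

#' Within-module (Zi) and among-module (Pi) connectivity per node
#'
#' `Zi = (k_within - mean_module) / sd_module` (0 when the module sd is
#' 0), where the mean/sd are over the within-module degrees of the node's
#' module; `Pi = 1 - sum_m (k_im / k_i)^2`. Nodes are classified by the
#' conventional threshold boxes: peripheral (Zi < 2.5, Pi < 0.62),
#' connector (Zi < 2.5, Pi > 0.62), module hub (Zi > 2.5, Pi < 0.62),
#' network hub (Zi > 2.5, Pi > 0.62); boundary values fall to the lower
#' class. Connectors and both hub types are flagged keystone. Isolated
#' nodes get Zi = Pi = 0 and are peripheral.
#'
#' @param net a `cooccurrence_network`.
#' @param membership module assignment from [detect_modules()].
#' @param zi_threshold,pi_threshold classification thresholds.
#' @return data.frame: taxon, module, degree, Zi, Pi, node_class, keystone.
#' @export
zi_pi <- function(net, membership, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  mem <- membership[nodes]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  k <- rowSums(adj)

  # within-module degree and its per-module moments
  k_within <- vapply(seq_along(nodes), function(i) {
    sum(adj[i, ] & mem == mem[i])
  }, numeric(1))
  zi <- numeric(length(nodes))
  for (m in unique(mem)) {
    in_m <- mem == m
    mu <- mean(k_within[in_m])
    sdv <- stats::sd(k_within[in_m])
    zi[in_m] <- if (is.na(sdv) || sdv == 0) 0 else (k_within[in_m] - mu) / sdv
  }

  pi <- vapply(seq_along(nodes), function(i) {
    if (k[i] == 0) return(0)
    km <- tapply(adj[i, ], mem, sum)
    1 - sum((km / k[i])^2)
  }, numeric(1))

  node_class <- classify_node(zi, pi, zi_threshold, pi_threshold)
  data.frame(
    taxon = nodes, module = as.integer(mem), degree = as.integer(k),
    Zi = zi, Pi = pi, node_class = node_class,
    keystone = node_class != "peripheral",
    stringsAsFactors = FALSE
  )
}

#' Classify nodes by the four Zi/Pi threshold boxes
#'
#' Strict inequalities: values exactly on a threshold fall to the lower
#' class.
#'
#' @param zi,pi numeric vectors of within- and among-module connectivity.
#' @param zi_threshold,pi_threshold box boundaries.
#' @return character vector: `peripheral`, `connector`, `module_hub` or
#'   `network_hub`.
#' @export
classify_node <- function(zi, pi, zi_threshold = 2.5, pi_threshold = 0.62) {
  ifelse(
    zi > zi_threshold,
    ifelse(pi > pi_threshold, "network_hub", "module_hub"),
    ifelse(pi > pi_threshold, "connector", "peripheral")
  )
}

#' Full keystone-taxon analysis
#'
#' Builds the co-occurrence network, detects modules, and classifies all
#' nodes by Zi/Pi.
#'
#' @inheritParams build_network
#' @inheritParams zi_pi
#' @return list with `network`, `modules`, `topology` (the Zi/Pi table)
#'   and `keystone` (taxon ids).
#' @export
keystone_analysis <- function(table, min_summed_abund = 1e-4,
                              min_prev = 0.015, r_threshold = 0.6,
                              alpha = 0.05, pseudocount = 1e-6,
                              zi_threshold = 2.5, pi_threshold = 0.62) {
  net <- build_network(table, min_summed_abund, min_prev, r_threshold,
                       alpha, pseudocount)
  if (nrow(net$edges) == 0) {
    return(list(network = net, modules = NULL,
                topology = data.frame(), keystone = character(0)))
  }
  mod <- detect_modules(net)
  topo <- zi_pi(net, mod$membership, zi_threshold, pi_threshold)
  list(network = net, modules = mod, topology = topo,
       keystone = topo$taxon[topo$keystone])
}
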