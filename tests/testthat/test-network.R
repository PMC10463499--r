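test_that("core taxa are exactly the always-present genera", {
  m <- rbind(c(5, 1, 0), c(3, 1, 2), c(2, 1, 1), c(1, 1, 1))
  colnames(m) <- c("a", "b", "c")
  tab <- abundance_table(m, kind = "counts")
  expect_setequal(core_taxa(tab), c("a", "b"))
  m2 <- m
  m2[1, 1] <- 0  # one absence disqualifies
  expect_setequal(core_taxa(abundance_table(m2, kind = "counts")), "b")
})

test_that("pairwise Spearman r matches the independent rank formula", {
  set.seed(10)
  m <- matrix(rnorm(15 * 4), 15)
  m[3, 2] <- m[5, 2]  # introduce a tie
  sp <- microbiability:::spearman_all_pairs(m)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      ct <- suppressWarnings(cor.test(m[, i], m[, j], method = "spearman"))
      expect_equal(sp$r[i, j], unname(ct$estimate), tolerance = 1e-12)
      # t-approximation p equals Pearson-on-ranks test p
      rt <- cor.test(rank(m[, i]), rank(m[, j]))
      expect_equal(sp$p[i, j], rt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("co-occurrence edges require strong, significant correlations", {
  set.seed(4)
  n <- 40
  base <- rnorm(n)
  m <- cbind(
    t1 = exp(base + rnorm(n, 0, 0.05)),      # t1, t2 strongly comonotone
    t2 = exp(base + rnorm(n, 0, 0.05)),
    t3 = exp(rnorm(n)),                       # independent
    t4 = exp(rnorm(n)),
    t5 = exp(2 * base + rnorm(n, 0, 0.05))   # monotone with t1/t2
  )
  tab <- toy_rel(m)
  net <- build_network(tab, r_threshold = 0.6, alpha = 0.05)
  key <- paste(net$edges$i, net$edges$j)
  expect_true("t1 t2" %in% key)
  expect_true(all(abs(net$edges$r) > 0.6))
  expect_true(all(net$edges$p_adj < 0.05))
  # perfect monotone pair has r = 1
  r12 <- net$all_pairs$r[net$all_pairs$i == "t1" & net$all_pairs$j == "t2"]
  expect_gt(r12, 0.9)
  # BH monotonicity: adjusted p nondecreasing in raw p
  o <- order(net$all_pairs$p)
  expect_true(all(diff(net$all_pairs$p_adj[o]) > -1e-12))
  # edge set invariant to taxon ordering
  perm <- c(4, 2, 5, 1, 3)
  net_p <- build_network(toy_rel(m[, perm]), r_threshold = 0.6, alpha = 0.05)
  canon <- function(e) sort(paste(pmin(e$i, e$j), pmax(e$i, e$j)))
  expect_equal(canon(net$edges), canon(net_p$edges))
})

test_that("independent taxa produce essentially no edges", {
  n_edges <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    m <- matrix(exp(rnorm(200 * 10)), 200)
    nrow(build_network(toy_rel(m))$edges)
  })
  expect_lte(mean(n_edges), 0.1)
})

test_that("module detection separates disconnected cliques", {
  clique_edges <- function(ids) t(combn(ids, 2))
  edges <- rbind(clique_edges(paste0("t", 1:4)), clique_edges(paste0("t", 5:8)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  net <- structure(list(graph = g, edges = as.data.frame(edges),
                        nodes = igraph::V(g)$name),
                   class = "cooccurrence_network")
  mod <- detect_modules(net)
  expect_equal(length(unique(mod$membership[paste0("t", 1:4)])), 1)
  expect_equal(length(unique(mod$membership[paste0("t", 5:8)])), 1)
  expect_false(mod$membership[["t1"]] == mod$membership[["t5"]])
  # modularity beats random assignments of the same group sizes
  g <- net$graph
  set.seed(6)
  rand_q <- replicate(100, igraph::modularity(g, sample(mod$membership)))
  expect_gte(mod$modularity, max(rand_q))
  # a single clique collapses to one module
  g1 <- igraph::graph_from_edgelist(clique_edges(paste0("t", 1:4)),
                                    directed = FALSE)
  igraph::E(g1)$weight <- 1
  net1 <- structure(list(graph = g1, edges = NULL, nodes = igraph::V(g1)$name),
                    class = "cooccurrence_network")
  expect_equal(length(unique(detect_modules(net1)$membership)), 1)
})

test_that("Zi/Pi follow the participation formulas and threshold boxes", {
  # hand-built 10-node graph, two modules of 5
  edges <- rbind(
    # module 1: star around n1 plus a chord
    c("n1", "n2"), c("n1", "n3"), c("n1", "n4"), c("n1", "n5"), c("n2", "n3"),
    # module 2: path-ish
    c("n6", "n7"), c("n6", "n8"), c("n7", "n8"), c("n9", "n6"), c("n10", "n6"),
    # n5 connects across
    c("n5", "n6"), c("n5", "n7")
  )
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  net <- structure(list(graph = g,
                        edges = data.frame(i = edges[, 1], j = edges[, 2]),
                        nodes = igraph::V(g)$name),
                   class = "cooccurrence_network")
  mem <- c(n1 = 1, n2 = 1, n3 = 1, n4 = 1, n5 = 1,
           n6 = 2, n7 = 2, n8 = 2, n9 = 2, n10 = 2)
  topo <- zi_pi(net, mem)
  rownames(topo) <- topo$taxon
  # hand computation, module 1 within-degrees: n1=4, n2=2, n3=2, n4=1, n5=1
  kw <- c(4, 2, 2, 1, 1)
  expect_equal(topo["n1", "Zi"], (4 - mean(kw)) / sd(kw), tolerance = 1e-12)
  # n5: within 1 (n1), outside 2 (n6, n7), k=3 -> Pi = 1 - (1/3)^2 - (2/3)^2
  expect_equal(topo["n5", "Pi"], 1 - (1 / 3)^2 - (2 / 3)^2, tolerance = 1e-12)
  # all of n2..n4's edges inside module 1 -> Pi = 0
  expect_equal(topo["n2", "Pi"], 0)
  expect_equal(topo["n4", "Pi"], 0)
  # n5's Pi = 4/9 stays below 0.62, Zi below 2.5 -> peripheral box
  expect_equal(topo["n5", "node_class"], "peripheral")
  expect_true(all(topo$node_class[topo$Zi < 2.5 & topo$Pi < 0.62] == "peripheral"))
  # keystone set = exactly the nodes beyond either threshold
  expect_setequal(topo$taxon[topo$keystone],
                  topo$taxon[topo$Pi > 0.62 | topo$Zi > 2.5])
})

test_that("node classes follow the four threshold boxes with strict bounds", {
  expect_equal(classify_node(2.6, 0.7), "network_hub")
  expect_equal(classify_node(2.6, 0.5), "module_hub")
  expect_equal(classify_node(1.0, 0.7), "connector")
  expect_equal(classify_node(1.0, 0.5), "peripheral")
  # boundary values fall to the lower class
  expect_equal(classify_node(2.5, 0.62), "peripheral")
  expect_equal(classify_node(2.5, 0.9), "connector")
  expect_equal(classify_node(3.0, 0.62), "module_hub")
})

test_that("degree split equally across four modules gives Pi = 0.75", {
  edges <- rbind(c("x", "a"), c("x", "b"), c("x", "c"), c("x", "d"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  net <- structure(list(graph = g, edges = as.data.frame(edges),
                        nodes = igraph::V(g)$name),
                   class = "cooccurrence_network")
  mem <- c(x = 1, a = 1, b = 2, c = 3, d = 4)
  topo <- zi_pi(net, mem)
  rownames(topo) <- topo$taxon
  expect_equal(topo["x", "Pi"], 0.75, tolerance = 1e-12)
  expect_equal(topo["x", "node_class"], "connector")  # Zi < 2.5
  # isolated node handling
  g2 <- igraph::add_vertices(g, 1, name = "iso")
  net2 <- structure(list(graph = g2, edges = as.data.frame(edges),
                         nodes = igraph::V(g2)$name),
                    class = "cooccurrence_network")
  topo2 <- zi_pi(net2, c(mem, iso = 5))
  rownames(topo2) <- topo2$taxon
  expect_equal(topo2["iso", "Pi"], 0)
  expect_equal(topo2["iso", "node_class"], "peripheral")
})
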