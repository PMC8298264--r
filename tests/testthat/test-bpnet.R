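test_that("network construction follows the representation rules", {
  ann <- annotation_table(c("g", "g", "h", "z", "ghost"),
                          c("A", "B", "A", "A", "B"))
  means <- c(g = 5, h = 2, z = 0)
  expect_message(net <- build_network(means, ann, "WT"), "dropped")
  expect_setequal(net$gene_nodes, c("g", "h"))          # z excluded (weight 0)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight[net$edges$gene == "g"] == 5))
  expect_equal(sum(net$edges$bp == "A"), 2L)            # BP A in-degree 2
})

test_that("weighted degree sums incident weights", {
  net <- bipartite_net("WT", c("g", "g", "g", "h"), c("A", "B", "C", "A"),
                       c(5, 5, 5, 2))
  expect_equal(weighted_degree(net, "g"), 15)
  expect_equal(weighted_degree(net, "A"), 7)
  expect_error(weighted_degree(net, "nope"), "not in the network")
})

test_that("centrality matches analytic values on stars and single edges", {
  star <- bipartite_net("WT", c("g1", "g2", "g3"), rep("A", 3), rep(2, 3))
  ce <- eigenvector_centrality(star)
  expect_equal(ce$eig_centrality[ce$node == "A"], 1)
  expect_equal(ce$eig_centrality[ce$part == "gene"],
               rep(1 / sqrt(3), 3), tolerance = 1e-8)
  expect_equal(max(ce$eig_centrality), 1)               # exact max-rescale

  single <- eigenvector_centrality(bipartite_net("WT", "g", "A", 7.3))
  expect_equal(single$eig_centrality, c(1, 1), tolerance = 1e-10)
})

test_that("power iteration equals the dense eigendecomposition oracle", {
  set.seed(99)
  for (rep in 1:40) {
    net <- random_bipartite(sample(2:6, 1), sample(2:6, 1))
    ce <- eigenvector_centrality(net)
    v <- oracle_centrality(regulomeShift:::adjacency_of(net))
    expect_equal(ce$eig_centrality, unname(v), tolerance = 1e-8)
  }
})

test_that("centrality is invariant under uniform weight scaling", {
  set.seed(7)
  net <- random_bipartite(5, 4)
  base <- eigenvector_centrality(net)$eig_centrality
  for (cc in c(0.001, 3, 1e6)) {
    scaled <- bipartite_net("WT", net$edges$gene, net$edges$bp,
                            net$edges$weight * cc)
    expect_equal(eigenvector_centrality(scaled)$eig_centrality, base,
                 tolerance = 1e-10)
  }
})

test_that("raising one gene's representation does not reduce its centrality", {
  set.seed(21)
  for (rep in 1:15) {
    net <- random_bipartite(5, 4)
    g <- sample(net$gene_nodes, 1)
    before <- eigenvector_centrality(net)
    w2 <- net$edges$weight
    w2[net$edges$gene == g] <- w2[net$edges$gene == g] * 2
    after <- eigenvector_centrality(
      bipartite_net("WT", net$edges$gene, net$edges$bp, w2))
    expect_gte(after$eig_centrality[after$node == g] -
                 before$eig_centrality[before$node == g], -1e-9)
  }
})

test_that("rate of change is zero against itself and follows the formula", {
  set.seed(3)
  net <- random_bipartite(6, 4)
  ce <- eigenvector_centrality(net)
  self <- centrality_rate_of_change(ce, ce)
  expect_equal(self$rate_of_change, rep(0, nrow(self)))
  expect_true(all(self$label == "unclassified"))

  mk <- function(nodes, vals) data.frame(node = nodes, part = "gene",
                                         eig_centrality = vals,
                                         relative_importance = 100 * vals,
                                         weighted_degree = 1)
  rep2 <- centrality_rate_of_change(mk(c("a", "b"), c(0.1, 0.5)),
                                    mk(c("a", "c"), c(1.1, 0.2)))
  expect_equal(rep2$rate_of_change[rep2$gene_id == "a"], 1000)
  expect_equal(rep2$label[rep2$gene_id == "c"], "novel_in_ko")
  expect_true(is.infinite(rep2$rate_of_change[rep2$gene_id == "c"]))
  expect_equal(rep2$rate_of_change[rep2$gene_id == "b"], -100)
  expect_equal(rep2$label[rep2$gene_id == "b"], "absent_in_ko")
})

test_that("functional complements need a >1000% gain and up-regulation", {
  rep1 <- data.frame(gene_id = c("IGLL1", "PRG2", "PRTN3", "EPX", "dn", "lo"),
                     c_wt = c(.01, .02, .03, .04, .05, .5),
                     c_ko = c(.9, .8, .7, .9, .9, .6),
                     rate_of_change = c(8900, 3900, 2233, 2150, 1700, 20),
                     label = "unclassified")
  de <- data.frame(gene_id = rep1$gene_id,
                   log2fc = c(8, 6, 5, 5, -1, 0.5))
  expect_setequal(classify_functional_complements(rep1, de),
                  c("IGLL1", "PRG2", "PRTN3", "EPX"))
  # without the up-regulation requirement the down-regulated gene enters
  expect_setequal(classify_functional_complements(rep1, require_up = FALSE),
                  c("IGLL1", "PRG2", "PRTN3", "EPX", "dn"))
  # exactly 1000% is not enough; 1500% with positive fold change is
  rep2 <- data.frame(gene_id = c("x", "y"), c_wt = c(.1, .1), c_ko = c(1.1, 1.6),
                     rate_of_change = c(1000, 1500), label = "unclassified")
  de2 <- data.frame(gene_id = c("x", "y"), log2fc = c(3, 3))
  expect_equal(classify_functional_complements(rep2, de2), "y")
})

test_that("reduced-importance genes fall strictly below the percent cutoff", {
  ko <- data.frame(node = c("KLF2", "at1", "hub"), part = "gene",
                   eig_centrality = c(0.0091, 0.01, 1),
                   relative_importance = c(0.91, 1.0, 100),
                   weighted_degree = 1)
  expect_equal(classify_reduced_importance(ko), "KLF2")
  expect_equal(length(classify_reduced_importance(ko[0, ])), 0L)
})

test_that("louvain communities split disconnected components and are deterministic", {
  two_stars <- bipartite_net("WT",
                             c("g1", "g2", "g3", "h1", "h2", "h3"),
                             c(rep("A", 3), rep("B", 3)), rep(1, 6))
  part <- louvain_communities(two_stars, seed = 4)
  expect_equal(part$n_communities, 2L)
  expect_equal(length(unique(part$membership[c("g1", "g2", "g3", "A")])), 1L)

  part2 <- louvain_communities(two_stars, seed = 4)
  expect_identical(part$membership, part2$membership)
})

test_that("louvain attains the enumerated maximum modularity on K22", {
  k22 <- bipartite_net("WT", c("g1", "g1", "g2", "g2"),
                       c("A", "B", "A", "B"), rep(1, 4))
  part <- louvain_communities(k22, seed = 1)
  nodes <- c("g1", "g2", "A", "B")
  # exhaustive enumeration of all partitions of 4 nodes (Bell number 15)
  parts <- list()
  for (a in 1:1) for (b in 1:2) for (cc in 1:3) for (d in 1:4)
    parts <- c(parts, list(setNames(c(a, b, cc, d), nodes)))
  best <- max(vapply(parts, function(m) oracle_modularity(k22, as.list(m)),
                     numeric(1)))
  got <- oracle_modularity(k22, as.list(part$membership[nodes]))
  expect_equal(got, best, tolerance = 1e-12)
  expect_equal(part$modularity, got, tolerance = 1e-9)
})

test_that("louvain modularity is at least the one-community baseline", {
  set.seed(17)
  for (rep in 1:5) {
    net <- random_bipartite(6, 5)
    part <- louvain_communities(net, seed = rep)
    one <- oracle_modularity(net, as.list(setNames(
      rep(1, length(c(net$gene_nodes, net$bp_nodes))),
      c(net$gene_nodes, net$bp_nodes))))
    expect_gte(part$modularity, one - 1e-12)
  }
})

test_that("the pipeline recovers planted complements from synthetic data", {
  sens <- fpr <- numeric(5)
  for (s in 1:5) {
    cfg <- synth_config(seed = 400 + s)
    ex <- gen_expression(cfg)
    an <- gen_annotations(cfg, ex$truth)
    de <- de_table(ex$matrix)
    cm <- condition_means(ex$matrix)
    wt <- eigenvector_centrality(build_network(cm, an$ann, "WT"))
    ko <- eigenvector_centrality(build_network(cm, an$ann, "KO"))
    found <- classify_functional_complements(
      centrality_rate_of_change(wt, ko), de)
    sens[s] <- mean(ex$truth$complements %in% found)
    fpr[s] <- sum(!found %in% ex$truth$complements) /
      (cfg$n_genes - cfg$n_complements)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.1)
})
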