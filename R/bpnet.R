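#' Construct a bipartite gene -> biological-process network
#'
#' @param condition `"WT"` or `"KO"`.
#' @param gene,bp Character vectors naming the endpoints of each edge
#'   (gene source, process target).
#' @param weight Positive finite edge weights (the gene's representation).
#' @return List of class `BipartiteNet` with `condition`, `gene_nodes`,
#'   `bp_nodes` and an `edges` data frame.
#' @export
bipartite_net <- function(condition, gene, bp, weight) {
  stopifnot(condition %in% c("WT", "KO"),
            length(gene) == length(bp), length(bp) == length(weight))
  if (length(weight) && (any(!is.finite(weight)) || any(weight <= 0)))
    stop("edge weights must be positive and finite")
  gene <- as.character(gene); bp <- as.character(bp)
  if (length(intersect(gene, bp)))
    stop("network is not bipartite; node(s) on both sides: ",
         paste(intersect(gene, bp), collapse = ", "))
  edges <- data.frame(gene = gene, bp = bp, weight = as.numeric(weight),
                      stringsAsFactors = FALSE)
  structure(list(condition = condition,
                 gene_nodes = unique(gene),
                 bp_nodes = unique(bp),
                 edges = edges),
            class = "BipartiteNet")
}

#' @export
print.BipartiteNet <- function(x, ...) {
  cat(sprintf("BipartiteNet [%s]: %d genes, %d processes, %d edges\n",
              x$condition, length(x$gene_nodes), length(x$bp_nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Build the per-condition network from representations and annotations
#'
#' One directed edge per (gene, annotated process) pair, weighted by the
#' gene's representation (mean expression) in the condition. Genes at or
#' below `min_weight` are excluded, as are processes left without any
#' incident edge. Annotation rows for genes absent from `means` are
#' dropped (a message reports how many).
#'
#' @param means Named numeric vector gene id -> representation (>= 0),
#'   or a data frame with columns `gene_id` and one of `mean_wt`/`mean_ko`
#'   picked by `condition`.
#' @param ann An [annotation_table()].
#' @param condition `"WT"` or `"KO"`.
#' @param min_weight Exclusion threshold: genes with representation
#'   `<= min_weight` are dropped (default 0, i.e. only unexpressed genes).
#' @return A [bipartite_net()].
#' @export
build_network <- function(means, ann, condition = "WT", min_weight = 0) {
  if (is.data.frame(means)) {
    col <- if (condition == "WT") "mean_wt" else "mean_ko"
    means <- stats::setNames(means[[col]], means$gene_id)
  }
  stopifnot(all(means >= 0))
  known <- ann$gene_id %in% names(means)
  n_drop <- sum(!known)
  if (n_drop > 0)
    message(n_drop, " annotation row(s) for genes absent from the ",
            "expression data were dropped")
  ann <- ann[known, , drop = FALSE]
  w <- means[ann$gene_id]
  keep <- w > min_weight
  bipartite_net(condition, ann$gene_id[keep], ann$term_id[keep], w[keep])
}

#' Convert a bipartite network to an igraph graph
#'
#' @param net A [bipartite_net()].
#' @param directed Keep the gene -> process direction (TRUE) or symmetrize
#'   (FALSE).
#' @return An igraph graph with vertex attribute `part` and edge weights.
#' @export
as_igraph <- function(net, directed = FALSE) {
  nodes <- data.frame(
    name = c(net$gene_nodes, net$bp_nodes),
    part = c(rep("gene", length(net$gene_nodes)),
             rep("bp", length(net$bp_nodes))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    net$edges[c("gene", "bp", "weight")],
    directed = directed, vertices = nodes)
}

# Symmetric weighted adjacency matrix of a bipartite net, gene rows/cols
# first. Used by the centrality power iteration and its test oracles.
adjacency_of <- function(net, weighted = TRUE) {
  nodes <- c(net$gene_nodes, net$bp_nodes)
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  w <- if (weighted) net$edges$weight else rep(1, nrow(net$edges))
  # accumulate in case of (theoretically impossible) duplicate edges
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$gene[k]; j <- net$edges$bp[k]
    A[i, j] <- A[i, j] + w[k]
    A[j, i] <- A[j, i] + w[k]
  }
  A
}

#' Weighted degree of a node
#'
#' Sum of incident edge weights: for a gene, its representation times the
#' number of processes it maps to; for a process, the summed
#' representations of the genes reaching it.
#'
#' @param net A [bipartite_net()].
#' @param node Node name (gene or process id).
#' @return Numeric weighted degree.
#' @export
weighted_degree <- function(net, node) {
  if (!node %in% c(net$gene_nodes, net$bp_nodes))
    stop("node '", node, "' is not in the network")
  sum(net$edges$weight[net$edges$gene == node | net$edges$bp == node])
}

#' Eigenvector centrality of every node
#'
#' Power iteration for the dominant eigenvector of the symmetrized
#' weighted adjacency. Because a bipartite adjacency has a symmetric
#' spectrum (+/- the spectral radius), the iteration runs on the shifted
#' matrix A + sI; the shift leaves eigenvectors unchanged while making
#' the dominant eigenvalue strictly largest in magnitude, so convergence
#' to the Perron vector is guaranteed. The shift is the running Rayleigh
#' quotient estimate of the dominant eigenvalue (for a positive iterate
#' it never exceeds it), which keeps the effective spectral gap wide.
#' Entries are made non-negative and rescaled so the top node scores
#' exactly 1; "relative importance" is this score as a percentage.
#'
#' @param net A non-empty [bipartite_net()].
#' @param weighted Use edge weights (default) or treat all edges as 1.
#' @param tol L2 convergence tolerance between successive iterates.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Data frame of class `NodeCentrality` with columns `node`,
#'   `part`, `eig_centrality`, `relative_importance`, `weighted_degree`.
#' @export
eigenvector_centrality <- function(net, weighted = TRUE, tol = 1e-10,
                                   max_iter = 1000) {
  if (nrow(net$edges) == 0) stop("network has no edges")
  A <- adjacency_of(net, weighted = weighted)
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  shift <- max(rowSums(A))          # initial upper bound on the radius
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u <- as.numeric(A %*% v)
    shift <- max(sum(v * u), .Machine$double.eps)   # Rayleigh quotient
    v_new <- u + shift * v
    v_new <- v_new / sqrt(sum(v_new^2))
    resid <- sqrt(sum((v_new - v)^2))
    v <- v_new
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("power iteration did not converge in %d iterations ",
                 max_iter), sprintf("(last residual %.3e)", resid))
  v <- abs(v)
  v <- v / max(v)
  deg <- rowSums(adjacency_of(net, weighted = TRUE))
  out <- data.frame(
    node = rownames(A),
    part = c(rep("gene", length(net$gene_nodes)),
             rep("bp", length(net$bp_nodes))),
    eig_centrality = v,
    relative_importance = 100 * v,
    weighted_degree = deg,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("NodeCentrality", "data.frame")
  out
}

#' Rate of change of gene centrality between conditions
#'
#' For each gene present in either condition network, the percent rate of
#' change R = 100 (c_KO - c_WT) / c_WT of its eigenvector centrality.
#' Genes absent from the WT network but present in KO are labelled
#' `novel_in_ko` (R = +Inf sentinel); genes absent from KO are labelled
#' `absent_in_ko` (R = -100). Remaining genes start `unclassified`; the
#' classifier helpers refine labels into `functional_complement` and
#' `reduced_importance`.
#'
#' @param wt,ko `NodeCentrality` data frames from
#'   [eigenvector_centrality()] computed with the same settings.
#' @return Data frame of class `CentralityChangeReport` with columns
#'   `gene_id`, `c_wt`, `c_ko`, `rate_of_change`, `label`.
#' @export
centrality_rate_of_change <- function(wt, ko) {
  wt <- wt[wt$part == "gene", ]
  ko <- ko[ko$part == "gene", ]
  genes <- union(wt$node, ko$node)
  c_wt <- stats::setNames(wt$eig_centrality, wt$node)[genes]
  c_ko <- stats::setNames(ko$eig_centrality, ko$node)[genes]
  in_wt <- genes %in% wt$node
  in_ko <- genes %in% ko$node
  r <- rep(NA_real_, length(genes))
  label <- rep("unclassified", length(genes))
  both <- in_wt & in_ko
  r[both] <- 100 * (c_ko[both] - c_wt[both]) / c_wt[both]
  r[!in_wt & in_ko] <- Inf
  label[!in_wt & in_ko] <- "novel_in_ko"
  r[in_wt & !in_ko] <- -100
  label[in_wt & !in_ko] <- "absent_in_ko"
  out <- data.frame(gene_id = genes,
                    c_wt = ifelse(in_wt, c_wt, NA_real_),
                    c_ko = ifelse(in_ko, c_ko, NA_real_),
                    rate_of_change = r,
                    label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("CentralityChangeReport", "data.frame")
  out
}

#' Candidate functional complements
#'
#' Genes whose network relative importance rises by more than
#' `increase_threshold` percent after knockdown (or that are new to the
#' KO network), optionally restricted to up-regulated genes
#' (`log2fc > 0`), are proposed as functional complements of the
#' knocked-down cofactor.
#'
#' @param report A [centrality_rate_of_change()] data frame.
#' @param de A [de_table()] data frame sharing gene ids (used when
#'   `require_up`).
#' @param increase_threshold Percent rate-of-change cutoff (strict).
#' @param require_up Require positive log2 fold change.
#' @return Character vector of gene ids.
#' @export
classify_functional_complements <- function(report, de = NULL,
                                            increase_threshold = 1000,
                                            require_up = TRUE) {
  gain <- report$rate_of_change > increase_threshold |
    report$label == "novel_in_ko"
  gain[is.na(gain)] <- FALSE
  if (require_up) {
    if (is.null(de))
      stop("require_up = TRUE needs a differential-expression table")
    lfc <- stats::setNames(de$log2fc, de$gene_id)[report$gene_id]
    gain <- gain & !is.na(lfc) & lfc > 0
  }
  report$gene_id[gain]
}

#' Genes of reduced network importance after knockdown
#'
#' Genes whose relative importance in the KO network falls strictly below
#' `threshold_pct` percent of the top node.
#'
#' @param ko A `NodeCentrality` data frame for the KO network.
#' @param threshold_pct Relative-importance cutoff in percent (strict).
#' @return Character vector of gene ids.
#' @export
classify_reduced_importance <- function(ko, threshold_pct = 1.0) {
  g <- ko[ko$part == "gene", ]
  g$node[g$relative_importance < threshold_pct]
}

#' Louvain communities of the bipartite network
#'
#' Greedy weighted-modularity (Louvain) community detection on the
#' symmetrized network. Ties in the greedy sweep depend on node order, so
#' vertices are shuffled with a seeded RNG to make the partition
#' deterministic for a given seed.
#'
#' @param net A non-empty [bipartite_net()].
#' @param resolution Modularity resolution parameter.
#' @param seed Integer seed for the node shuffle.
#' @return List of class `CommunityPartition` with `membership` (named
#'   integer vector), `modularity`, and `n_communities`.
#' @export
louvain_communities <- function(net, resolution = 1.0, seed = 1L) {
  if (nrow(net$edges) == 0) stop("network has no edges")
  g <- as_igraph(net, directed = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  memb <- memb[igraph::V(g)$name]
  structure(list(membership = memb,
                 modularity = igraph::modularity(
                   g, memb[igraph::V(g)$name],
                   weights = igraph::E(g)$weight),
                 n_communities = length(unique(memb))),
            class = "CommunityPartition")
}
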