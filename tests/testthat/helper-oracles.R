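# Independent oracles and small fixture builders shared across tests.

# Closed-form two-sample t (pooled or Welch), independent of the package.
oracle_t <- function(x, y, equal_variance = TRUE) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (equal_variance) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Dominant eigenvector of the symmetrized adjacency by dense
# eigendecomposition, max-normalized with non-negative entries.
oracle_centrality <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / max(v)
}

# Random connected weighted bipartite graph as a BipartiteNet plus its
# adjacency; node counts <= ng + nb.
random_bipartite <- function(ng, nb, p_extra = 0.4) {
  genes <- paste0("g", seq_len(ng))
  bps <- paste0("b", seq_len(nb))
  # spanning construction keeps the graph connected
  e_gene <- character(); e_bp <- character()
  nodes_in <- c(genes[1], bps[1])
  e_gene <- genes[1]; e_bp <- bps[1]
  for (g in genes[-1]) {
    e_gene <- c(e_gene, g)
    e_bp <- c(e_bp, sample(bps[bps %in% nodes_in], 1))
    nodes_in <- c(nodes_in, g)
  }
  for (b in bps[-1]) {
    e_gene <- c(e_gene, sample(genes, 1))
    e_bp <- c(e_bp, b)
    nodes_in <- c(nodes_in, b)
  }
  for (g in genes) for (b in bps)
    if (runif(1) < p_extra && !any(e_gene == g & e_bp == b)) {
      e_gene <- c(e_gene, g); e_bp <- c(e_bp, b)
    }
  w <- runif(length(e_gene), 0.1, 10)
  bipartite_net("WT", e_gene, e_bp, w)
}

# Toy 2-condition expression matrix with explicit values.
toy_matrix <- function(values, replicates = 3) {
  samples <- c(paste0("WT", seq_len(replicates)),
               paste0("KO", seq_len(replicates)))
  colnames(values) <- samples
  expression_matrix(values, setNames(rep(c("WT", "KO"), each = replicates),
                                     samples))
}

# Write a small OBO file from a parent list (term -> character vector of
# is_a parents); returns the path.
write_toy_obo <- function(parents, namespace = "biological_process",
                          obsolete = character(), ns_of = list()) {
  path <- tempfile(fileext = ".obo")
  con <- file(path, "w")
  writeLines("format-version: 1.2", con)
  for (id in names(parents)) {
    writeLines(c("", "[Term]", paste0("id: ", id)), con)
    ns <- if (id %in% names(ns_of)) ns_of[[id]] else namespace
    writeLines(paste0("namespace: ", ns), con)
    for (p in parents[[id]])
      writeLines(paste0("is_a: ", p, " ! parent"), con)
    if (id %in% obsolete) writeLines("is_obsolete: true", con)
  }
  close(con)
  path
}

# Brute-force BFS levels on a parent list (root level 1).
oracle_levels <- function(parents) {
  ids <- names(parents)
  lev <- setNames(rep(NA_integer_, length(ids)), ids)
  roots <- ids[lengths(parents) == 0]
  lev[roots] <- 1L
  repeat {
    changed <- FALSE
    for (id in ids) {
      pl <- lev[parents[[id]]]
      if (any(!is.na(pl))) {
        cand <- min(pl, na.rm = TRUE) + 1L
        if (is.na(lev[id]) || cand < lev[id]) { lev[id] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  lev[!is.na(lev)]
}

# Exact sequential perfusion mixing: inject v_inj of titrant, mix into
# constant cell volume v0, expel the overflow after mixing.
oracle_mixing <- function(p, i) {
  M <- p$cell_conc; X <- 0
  for (k in seq_len(i)) {
    keep <- p$v0 / (p$v0 + p$v_inj)
    M <- M * keep
    X <- (X * p$v0 + p$syringe_conc * p$v_inj) / (p$v0 + p$v_inj)
  }
  list(M_t = M, X_t = X)
}

# Mass-action equilibrium occupancy by root finding on free ligand.
oracle_occupancy <- function(Ka, n, M_t, X_t) {
  if (X_t == 0) return(0)
  f <- function(xf) xf + n * M_t * Ka * xf / (1 + Ka * xf) - X_t
  xf <- uniroot(f, c(0, X_t), tol = 1e-15)$root
  Ka * xf / (1 + Ka * xf)
}

# Newman weighted modularity of a membership vector on a BipartiteNet.
oracle_modularity <- function(net, memb) {
  m2 <- 2 * sum(net$edges$weight)
  nodes <- c(net$gene_nodes, net$bp_nodes)
  deg <- sapply(nodes, function(v) weighted_degree(net, v))
  q <- 0
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$gene[k]; j <- net$edges$bp[k]
    if (memb[[i]] == memb[[j]]) q <- q + 2 * net$edges$weight[k] / m2
  }
  for (ci in unique(unlist(memb))) {
    dc <- sum(deg[names(memb)[unlist(memb) == ci]])
    q <- q - (dc / m2)^2
  }
  q
}
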