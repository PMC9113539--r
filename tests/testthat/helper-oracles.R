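# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (path enumeration, explicit branch bookkeeping,
# exhaustive permutation) so they never share code with the implementation
# they check.

# All tip-to-tip path lengths by shortest-path search on the edge graph.
bf_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  n <- length(tree$tip.label)
  out <- d[as.character(seq_len(n)), as.character(seq_len(n))]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Tips descending from each edge, by explicit traversal.
bf_edge_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below(tree$edge[e, 2]))
}

# Unweighted UniFrac by explicit branch enumeration.
bf_unifrac_pair <- function(tree, taxa1, taxa2) {
  tipsets <- bf_edge_tipsets(tree)
  uniq <- 0; tot <- 0
  for (e in seq_along(tipsets)) {
    in1 <- any(tipsets[[e]] %in% taxa1)
    in2 <- any(tipsets[[e]] %in% taxa2)
    if (in1 || in2) tot <- tot + tree$edge.length[e]
    if (xor(in1, in2)) uniq <- uniq + tree$edge.length[e]
  }
  uniq / tot
}

# beta-MNTD for one sample pair straight from the defining formula.
bf_bmntd_pair <- function(f1, f2, D) {
  s1 <- which(f1 > 0); s2 <- which(f2 > 0)
  t1 <- sum(vapply(s1, function(i) f1[i] * min(D[i, s2]), 1))
  t2 <- sum(vapply(s2, function(i) f2[i] * min(D[i, s1]), 1))
  0.5 * (t1 + t2)
}

# All permutations of 1..n (n! rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix((seq_len(n))[-i][sub], nrow(sub)))))
}

# ANOSIM R statistic from its definition (midranks of all distances).
bf_anosim_R <- function(dm, groups) {
  m <- as.matrix(dm)
  lt <- lower.tri(m)
  rk <- rank(m[lt])
  same <- outer(groups, groups, "==")[lt]
  n <- nrow(m)
  (mean(rk[!same]) - mean(rk[same])) / (n * (n - 1) / 4)
}

# IndVal max statistic per OTU for one grouping (matrix samples x OTUs).
bf_indval_max <- function(x, groups) {
  lv <- unique(groups)
  sapply(seq_len(ncol(x)), function(i) {
    mg <- sapply(lv, function(g) mean(x[groups == g, i]))
    A <- mg / sum(mg)
    B <- sapply(lv, function(g) mean(x[groups == g, i] > 0))
    max(sqrt(A * B))
  })
}

# Random raw-count fixture with guaranteed non-empty samples.
random_table <- function(n_samples, n_otus, seed, depth = 50) {
  set.seed(seed)
  repeat {
    x <- matrix(rpois(n_samples * n_otus, depth / n_otus),
                n_samples, n_otus,
                dimnames = list(paste0("s", seq_len(n_samples)),
                                paste0("t", seq_len(n_otus))))
    if (all(rowSums(x) > 0)) return(otu_table(x))
  }
}

# Random symmetric distance matrix as dist.
random_dm <- function(n, seed, labels = paste0("s", seq_len(n))) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  as.dist(m)
}
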