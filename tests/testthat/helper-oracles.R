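# Independent oracles kept deliberately naive: exhaustive enumeration,
# brute-force pair counting, and direct linear algebra.  They never call
# the code paths they are used to check.

# Exact joint distribution of (#DEG, #DEVG) in a uniformly random
# y-subset of a labeled N-gene universe, by enumerating all C(N, y)
# subsets.  Returns a (x1+1) x (x2+1) matrix of probabilities.
ht2_enum_dist <- function(N, x1, x2, y) {
  labels <- c(rep(1L, x1), rep(2L, x2), rep(0L, N - x1 - x2))
  P <- matrix(0, nrow = x1 + 1, ncol = x2 + 1)
  if (y == 0) {
    P[1, 1] <- 1
    return(P)
  }
  subsets <- utils::combn(N, y)
  L <- matrix(labels[subsets], nrow = y)
  k1 <- colSums(L == 1L)
  k2 <- colSums(L == 2L)
  tab <- table(factor(k1, levels = 0:x1), factor(k2, levels = 0:x2))
  P[, ] <- as.numeric(tab)
  P / ncol(subsets)
}

# Tail of an enumerated distribution under either convention.
ht2_enum_tail <- function(P, k1, k2, inclusive = FALSE) {
  lo1 <- if (inclusive) k1 + 1 else k1 + 2
  lo2 <- if (inclusive) k2 + 1 else k2 + 2
  if (lo1 > nrow(P) || lo2 > ncol(P)) return(0)
  sum(P[lo1:nrow(P), lo2:ncol(P)])
}

# Mann-Whitney AUC by brute-force pair counting over an ordered list.
brute_auc <- function(ranked, gold) {
  pos <- seq_along(ranked)
  g <- pos[ranked %in% gold]
  ng <- pos[!ranked %in% gold]
  wins <- 0
  for (i in g) for (j in ng)
    wins <- wins + (i < j) + 0.5 * (i == j)
  wins / (length(g) * length(ng))
}

# Best-modularity partition of a small graph by exhaustive search over
# all set partitions (feasible for <= 8 nodes).
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (g in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, g)
  }
  out
}

brute_modularity <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 8)
  best <- NULL; best_q <- -Inf
  for (p in set_partitions(n)) {
    q <- igraph::modularity(graph, p)
    if (q > best_q + 1e-12) { best_q <- q; best <- p }
  }
  list(membership = best, modularity = best_q)
}

# Steady state of the restart walk by direct linear solve of
# p = (1 - lambda) W p + lambda p0 with the column-stochastic operator.
rwr_solve <- function(network, seeds, config) {
  A <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  if (config$weighting == "correlation") {
    W <- igraph::as_adjacency_matrix(network, attr = "weight",
                                     sparse = FALSE)
    zero <- rowSums(W) == 0 & rowSums(A) > 0
    W[zero, ] <- A[zero, ]
    A <- W
  }
  T_ <- A / rowSums(A)
  nodes <- igraph::V(network)$name
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[intersect(seeds, nodes)] <- 1 / length(intersect(seeds, nodes))
  M <- diag(length(nodes)) - (1 - config$lambda) * t(T_)
  setNames(as.vector(solve(M, config$lambda * p0)), nodes)
}

# Random connected-ish test network with weights.
random_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  from <- c(nodes[-1], sample(nodes, n_edges, replace = TRUE))
  to <- c(nodes[-n_nodes], sample(nodes, n_edges, replace = TRUE))
  ok <- from != to
  df <- data.frame(from = from[ok], to = to[ok],
                   weight = runif(sum(ok), 0.1, 1))
  suppressMessages(gene_network(df))
}
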