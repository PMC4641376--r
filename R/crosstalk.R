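#' Random-walk-with-restart configuration
#'
#' @param lambda restart probability in (0, 1]; default 0.7, a common
#'   choice in network gene prioritization.
#' @param weighting `"topology"` (uniform over neighbors) or
#'   `"correlation"` (edge `weight` attribute; rows whose weights are all
#'   zero fall back to uniform).
#' @param tol L1 convergence tolerance (> 0).
#' @param max_iter maximal number of iterations.
#' @param top_frac fraction of non-seed nodes considered "high-ranked"
#'   when collecting crosstalk partner genes (default 0.05).
#' @param as_printed apply the row-normalized transition matrix without
#'   transposition.  This reproduces the update `P_{k+1} =
#'   (1-lambda) T P_k + lambda P_0` with row-stochastic `T` literally,
#'   which does not conserve probability mass; the default (`FALSE`)
#'   applies the transpose, the standard mass-conserving RWR contract.
#' @param include_seeds also count seed genes of the source pathway that
#'   belong to the queried pathway as partners (default `FALSE`; seeds
#'   are dysregulated by construction, so including them biases the
#'   crosstalk test towards significance).
#' @param inclusive tail convention for the crosstalk HT2 test
#'   (default `TRUE`: with the strict tail, a partner set consisting of
#'   a single dysregulated gene already scores exactly 0 and would be
#'   accepted at any threshold; the inclusive tail removes that
#'   degeneracy).
#' @return A list of class `RWRConfig`.
#' @export
rwr_config <- function(lambda = 0.7,
                       weighting = c("topology", "correlation"),
                       tol = 1e-10, max_iter = 10000L,
                       top_frac = 0.05, as_printed = FALSE,
                       include_seeds = FALSE, inclusive = TRUE) {
  weighting <- match.arg(weighting)
  if (!(lambda > 0 && lambda <= 1)) stop("'lambda' must be in (0, 1]")
  if (tol <= 0) stop("'tol' must be > 0")
  structure(list(lambda = lambda, weighting = weighting, tol = tol,
                 max_iter = as.integer(max_iter), top_frac = top_frac,
                 as_printed = as_printed, include_seeds = include_seeds,
                 inclusive = inclusive),
            class = "RWRConfig")
}

transition_matrix <- function(network, weighting = "topology") {
  A <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  if (weighting == "correlation") {
    if (!"weight" %in% igraph::edge_attr_names(network))
      stop("correlation weighting needs an edge 'weight' attribute")
    W <- igraph::as_adjacency_matrix(network, attr = "weight",
                                     sparse = FALSE)
    zero_rows <- rowSums(W) == 0 & rowSums(A) > 0
    W[zero_rows, ] <- A[zero_rows, ]  # uniform fallback over neighbors
    A <- W
  }
  d <- rowSums(A)
  if (any(d == 0))
    stop("network has node(s) with no usable edges")
  A / d
}

#' Random walk with restart on a gene network
#'
#' Iterates `P_{k+1} = (1 - lambda) * t(T) %*% P_k + lambda * P_0` with
#' row-stochastic transition matrix `T` (applied column-stochastically,
#' so that the probability vector keeps summing to one) until the L1
#' change drops below `config$tol`.  `P_0` puts equal mass on the seed
#' genes present in the network; seeds absent from the network are
#' dropped with a warning.
#'
#' @param network a [gene_network] graph.
#' @param seeds character vector of seed gene ids.
#' @param config an [rwr_config].
#' @return A list of class `PropagationResult` with `p` (named
#'   steady-state probabilities), `p0`, `seeds` (retained seeds),
#'   `iterations`, `deltas` (L1 change per iteration) and `converged`.
#' @export
rwr <- function(network, seeds, config = rwr_config()) {
  nodes <- igraph::V(network)$name
  seeds <- unique(as.character(seeds))
  kept <- intersect(seeds, nodes)
  if (length(kept) == 0)
    stop("no seed is present in the network")
  if (length(kept) < length(seeds))
    warning(length(seeds) - length(kept),
            " seed(s) absent from the network dropped")
  T_ <- transition_matrix(network, config$weighting)
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[kept] <- 1 / length(kept)
  p <- p0
  deltas <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    step <- if (config$as_printed) T_ %*% p else crossprod(T_, p)
    p_new <- (1 - config$lambda) * as.vector(step) + config$lambda * p0
    names(p_new) <- nodes
    delta <- sum(abs(p_new - p))
    deltas <- c(deltas, delta)
    p <- p_new
    if (delta < config$tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("RWR did not converge within ", config$max_iter, " iterations")
  structure(list(p = p, p0 = p0, seeds = kept, iterations = it,
                 deltas = deltas, converged = converged),
            class = "PropagationResult")
}

#' @export
print.PropagationResult <- function(x, ...) {
  cat("PropagationResult:", length(x$p), "nodes,", length(x$seeds),
      "seeds,", x$iterations, "iterations\n")
  invisible(x)
}

rank_nonseed <- function(prop) {
  nonseed <- setdiff(names(prop$p), prop$seeds)
  nonseed[order(-prop$p[nonseed], nonseed)]
}

#' Partner genes of a pathway under two-way RWR
#'
#' Runs [rwr] from the seed genes, ranks the non-seed network nodes by
#' steady-state probability (ties broken by gene id), keeps the top
#' `ceiling(top_frac * n_non_seed)` as "high-ranked", and returns their
#' intersection with the queried pathway's genes.
#'
#' @inheritParams rwr
#' @param pathway_genes gene ids of the queried pathway.
#' @return Character vector of partner genes (possibly empty).
#' @export
twrwr_partners <- function(network, seeds, pathway_genes,
                           config = rwr_config()) {
  prop <- rwr(network, seeds, config)
  partners_from_propagation(prop, pathway_genes, config)
}

partners_from_propagation <- function(prop, pathway_genes, config) {
  ranked <- rank_nonseed(prop)
  n_top <- ceiling(config$top_frac * length(ranked))
  hi <- head(ranked, n_top)
  intersect(hi, pathway_genes)
}

#' Directional crosstalk score between two pathways
#'
#' Seeds the walk with the dysregulated (DEG or DEVG) genes of pathway
#' `u` present in the network, collects the high-ranked partner genes
#' falling in pathway `v`, and scores their enrichment with the HT2 test
#' on the network universe: `N` = network nodes, `x1`/`x2` = network-wide
#' DEG/DEVG counts, `y` = number of partners, `k1`/`k2` = dysregulated
#' partners.  Pathways without seeds in the network, or with an empty
#' partner set, score 1 (no evidence of crosstalk).
#'
#' @param genes_u gene ids of the source pathway.
#' @param genes_v gene ids of the queried pathway.
#' @param labeling a `GeneLabeling`.
#' @inheritParams rwr
#' @return The directional score `E_uv` (an HT2 p-value), with the
#'   partner count in attribute `n_partners`.
#' @export
crosstalk_score <- function(genes_u, genes_v, labeling, network,
                            config = rwr_config()) {
  nodes <- igraph::V(network)$name
  seeds <- intersect(intersect(union(labeling$deg, labeling$devg),
                               genes_u), nodes)
  if (length(seeds) == 0) {
    warning("source pathway has no dysregulated gene in the network; ",
            "score set to 1")
    return(structure(1, n_partners = 0L))
  }
  prop <- rwr(network, seeds, config)
  score_from_propagation(prop, genes_v, labeling, nodes, config)
}

score_from_propagation <- function(prop, genes_v, labeling, nodes,
                                   config) {
  S <- partners_from_propagation(prop, genes_v, config)
  if (config$include_seeds)
    S <- union(S, intersect(prop$seeds, genes_v))
  y <- length(S)
  if (y == 0) return(structure(1, n_partners = 0L))
  N <- length(nodes)
  deg <- intersect(labeling$deg, nodes)
  devg <- intersect(labeling$devg, nodes)
  p <- ht2_pvalue(N, length(deg), length(devg), y,
                  length(intersect(S, deg)), length(intersect(S, devg)),
                  inclusive = config$inclusive)
  structure(p, n_partners = y)
}

#' Build the map of pathways from pairwise crosstalk scores
#'
#' Scores every unordered pathway pair in both directions (one RWR run
#' per source pathway, reused across queries) and accepts an edge only
#' when both directional scores fall below `alpha`.  Pathways without an
#' accepted edge are excluded from the map unless `keep_isolated`.
#'
#' @param collection a [GeneSetCollection].
#' @param labeling a `GeneLabeling`.
#' @inheritParams rwr
#' @param alpha significance threshold on both directional scores
#'   (default 0.001).
#' @param keep_isolated keep pathways without accepted crosstalk as
#'   isolated map nodes (default `FALSE`).
#' @return A list of class `PathwayMap` with `scores` (all scored pairs:
#'   `u`, `v`, `e_uv`, `e_vu`, `partners_uv`, `partners_vu`, `accepted`),
#'   `edges` (the accepted subset), `graph` (igraph of the map) and
#'   `modules` (`NULL` until [detect_modules]).
#' @export
build_pathway_map <- function(collection, labeling, network,
                              config = rwr_config(), alpha = 0.001,
                              keep_isolated = FALSE) {
  nms <- sort(names(collection))
  nodes <- igraph::V(network)$name
  dys <- union(labeling$deg, labeling$devg)
  props <- setNames(vector("list", length(nms)), nms)
  for (nm in nms) {
    seeds <- intersect(intersect(dys, collection[[nm]]), nodes)
    if (length(seeds) > 0)
      props[[nm]] <- rwr(network, seeds, config)
  }
  pairs <- if (length(nms) >= 2) utils::combn(nms, 2) else
    matrix(character(0), nrow = 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    u <- pairs[1, j]; v <- pairs[2, j]
    e_uv <- if (is.null(props[[u]])) structure(1, n_partners = 0L) else
      score_from_propagation(props[[u]], collection[[v]], labeling,
                             nodes, config)
    e_vu <- if (is.null(props[[v]])) structure(1, n_partners = 0L) else
      score_from_propagation(props[[v]], collection[[u]], labeling,
                             nodes, config)
    data.frame(u = u, v = v,
               e_uv = as.numeric(e_uv), e_vu = as.numeric(e_vu),
               partners_uv = attr(e_uv, "n_partners"),
               partners_vu = attr(e_vu, "n_partners"),
               accepted = as.numeric(e_uv) < alpha &
                 as.numeric(e_vu) < alpha,
               stringsAsFactors = FALSE)
  })
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(u = character(0), v = character(0), e_uv = numeric(0),
               e_vu = numeric(0), partners_uv = integer(0),
               partners_vu = integer(0), accepted = logical(0))
  edges <- scores[scores$accepted, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v")], directed = FALSE,
    vertices = if (keep_isolated) nms else
      sort(unique(c(edges$u, edges$v))))
  if (nrow(edges) > 0) {
    igraph::E(g)$e_uv <- edges$e_uv
    igraph::E(g)$e_vu <- edges$e_vu
  }
  structure(list(scores = scores, edges = edges, graph = g,
                 alpha = alpha, modules = NULL),
            class = "PathwayMap")
}

#' @export
print.PathwayMap <- function(x, ...) {
  cat("PathwayMap:", igraph::vcount(x$graph), "pathways,",
      nrow(x$edges), "crosstalk edge(s) at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Detect modules of inter-connected pathways in a map
#'
#' Greedy modularity-maximizing agglomerative clustering (fast-greedy)
#' of the pathway map; singleton components form singleton modules.
#' Deterministic for a fixed map.
#'
#' @param map a `PathwayMap`.
#' @return The map with `modules` filled: a named integer vector
#'   assigning every map node to a module.
#' @export
detect_modules <- function(map) {
  g <- map$graph
  if (igraph::vcount(g) == 0) {
    map$modules <- setNames(integer(0), character(0))
    return(map)
  }
  comm <- igraph::cluster_fast_greedy(g)
  map$modules <- setNames(igraph::membership(comm), igraph::V(g)$name)
  map
}

#' Differential network of condition-dependent co-expression
#'
#' Keeps the edges of `network` whose Pearson correlation differs
#' significantly between the two conditions: per edge, correlations are
#' compared with the Fisher z statistic
#' `Z = (atanh(r_case) - atanh(r_control)) / sqrt(1/(n_case-3) +
#' 1/(n_control-3))` and the edge is retained iff the two-sided normal
#' p-value is below `alpha_edge`.  Edges with an unmeasured endpoint or a
#' zero-variance gene are dropped and counted.
#'
#' @param network a [gene_network] graph.
#' @param dataset an [ExpressionDataset].
#' @param alpha_edge edge-level significance threshold (default 0.05).
#' @return The subgraph of retained edges (isolated nodes dropped);
#'   attributes `n_unmeasured`, `n_degenerate`, `n_tested`, `n_kept`.
#' @export
differential_network <- function(network, dataset, alpha_edge = 0.05) {
  x <- condition_values(dataset, "control")
  y <- condition_values(dataset, "case")
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 4 || n2 < 4)
    stop("differential network needs >= 4 samples per condition")
  if (n1 < 10 || n2 < 10)
    warning("fewer than 10 samples in a condition; ",
            "correlation differences are unstable")
  el <- igraph::as_edgelist(network)
  measured <- rownames(dataset$values)
  ok <- el[, 1] %in% measured & el[, 2] %in% measured
  n_unmeasured <- sum(!ok)
  el <- el[ok, , drop = FALSE]
  clamp <- 1 - 1e-12
  n_degenerate <- 0L
  keep <- logical(nrow(el))
  pvals <- rep(NA_real_, nrow(el))
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    if (sd(x[a, ]) == 0 || sd(x[b, ]) == 0 ||
        sd(y[a, ]) == 0 || sd(y[b, ]) == 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    r1 <- cor(x[a, ], x[b, ])
    r2 <- cor(y[a, ], y[b, ])
    z <- (atanh(pmin(pmax(r2, -clamp), clamp)) -
          atanh(pmin(pmax(r1, -clamp), clamp))) /
      sqrt(1 / (n2 - 3) + 1 / (n1 - 3))
    pvals[i] <- 2 * pnorm(-abs(z))
    keep[i] <- pvals[i] < alpha_edge
  }
  if (n_degenerate > 0)
    warning(n_degenerate, " edge(s) with a zero-variance gene dropped")
  kept <- data.frame(from = el[keep, 1], to = el[keep, 2],
                     stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(kept, directed = FALSE)
  if (nrow(kept) > 0 &&
      "weight" %in% igraph::edge_attr_names(network)) {
    ids <- igraph::get_edge_ids(network, t(as.matrix(kept)))
    igraph::E(g)$weight <- igraph::E(network)$weight[ids]
  }
  class(g) <- unique(c(class(g), "GeneNetwork"))
  attr(g, "n_unmeasured") <- n_unmeasured
  attr(g, "n_degenerate") <- n_degenerate
  attr(g, "n_tested") <- nrow(el) - n_degenerate
  attr(g, "n_kept") <- nrow(kept)
  g
}

#' Absolute-correlation edge weights for correlation-weighted walks
#'
#' Sets each edge's `weight` to the absolute Pearson correlation of its
#' endpoint genes across all samples (0 for unmeasured endpoints).
#'
#' @inheritParams differential_network
#' @return The network with a `weight` edge attribute.
#' @export
correlation_weights <- function(network, dataset) {
  el <- igraph::as_edgelist(network)
  measured <- rownames(dataset$values)
  w <- numeric(nrow(el))
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    if (a %in% measured && b %in% measured) {
      va <- dataset$values[a, ]; vb <- dataset$values[b, ]
      if (sd(va) > 0 && sd(vb) > 0) w[i] <- abs(cor(va, vb))
    }
  }
  igraph::E(network)$weight <- w
  network
}

#' Rank-list AUC against a gold-standard gene set
#'
#' Probability that a uniformly chosen gold gene outranks a uniformly
#' chosen non-gold gene (the normalized Mann-Whitney U), with tied
#' scores counted 1/2.
#'
#' @param ranked either a character vector of gene ids ordered best
#'   first, or a named numeric vector of scores (larger = better).
#' @param gold_set character vector of gold-standard gene ids.
#' @return AUC in `[0, 1]`.
#' @export
ranked_auc <- function(ranked, gold_set) {
  if (is.character(ranked)) {
    score <- setNames(rev(seq_along(ranked)), ranked)
  } else if (is.numeric(ranked) && !is.null(names(ranked))) {
    score <- ranked
  } else stop("'ranked' must be an ordered character vector ",
              "or a named numeric score vector")
  gold <- names(score) %in% gold_set
  m <- sum(gold)
  if (m == 0) stop("gold set does not intersect the ranked list")
  if (m == length(score))
    stop("gold set covers the entire ranked list")
  r <- rank(score, ties.method = "average")
  (sum(r[gold]) - m * (m + 1) / 2) / (m * (length(score) - m))
}

#' Export a pathway map as node/edge TSV and GraphML
#'
#' @param map a `PathwayMap` (modules detected on the fly if absent).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`nodes.tsv`, `edges.tsv`,
#'   `map.graphml`).
#' @export
write_pathway_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(map$modules)) map <- detect_modules(map)
  nodes <- data.frame(pathway = names(map$modules),
                      module = as.integer(map$modules),
                      stringsAsFactors = FALSE)
  p_nodes <- file.path(dir, "nodes.tsv")
  p_edges <- file.path(dir, "edges.tsv")
  p_gml <- file.path(dir, "map.graphml")
  write_table(nodes, p_nodes)
  write_table(map$edges[, c("u", "v", "e_uv", "e_vu",
                            "partners_uv", "partners_vu")], p_edges)
  igraph::write_graph(map$graph, p_gml, format = "graphml")
  invisible(c(p_nodes, p_edges, p_gml))
}
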