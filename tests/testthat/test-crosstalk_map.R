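test_that("rwr reproduces the two-node fixed point and conserves mass", {
  g <- gene_network(data.frame(from = "A", to = "B"))
  res <- rwr(g, "A", rwr_config(lambda = 0.5, tol = 1e-14))
  # solve p = 0.5 T' p + 0.5 p0 directly: p = (2/3, 1/3)
  expect_equal(unname(res$p[c("A", "B")]), c(2 / 3, 1 / 3),
               tolerance = 1e-10)
  expect_equal(sum(res$p), 1, tolerance = 1e-12)
  # complete graph with all nodes seeded: uniform fixed point
  k5 <- gene_network(as.data.frame(t(utils::combn(LETTERS[1:5], 2)),
                                   stringsAsFactors = FALSE))
  r5 <- rwr(k5, LETTERS[1:5], rwr_config(lambda = 0.3))
  expect_equal(unname(r5$p), rep(0.2, 5), tolerance = 1e-10)
  # pure restart returns p0 exactly
  r1 <- rwr(g, "A", rwr_config(lambda = 1))
  expect_identical(unname(r1$p), c(1, 0))
  # seeds outside the network are dropped with a warning; all absent errors
  expect_warning(rwr(g, c("A", "ZZ")), "dropped")
  expect_error(suppressWarnings(rwr(g, "ZZ")), "seed")
})

test_that("iterative propagation matches the direct linear solve on random networks", {
  cfg_t <- rwr_config(lambda = 0.7, tol = 1e-13)
  cfg_c <- rwr_config(lambda = 0.7, weighting = "correlation",
                      tol = 1e-13)
  for (s in 1:10) {
    n <- sample(20:100, 1)
    g <- random_network(n, 2 * n, seed = 1000 + s)
    seeds <- sample(igraph::V(g)$name, 3)
    for (cfg in list(cfg_t, cfg_c)) {
      it <- rwr(g, seeds, cfg)
      direct <- rwr_solve(g, seeds, cfg)
      expect_lt(sum(abs(it$p - direct[names(it$p)])), 1e-8)
      # contraction: successive L1 changes shrink at least by (1-lambda)
      d <- it$deltas
      if (length(d) > 1)
        expect_true(all(d[-1] <= (1 - cfg$lambda) * d[-length(d)] +
                          1e-12))
    }
  }
})

test_that("the as-printed row-stochastic update differs and loses mass conservation", {
  g <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C")))
  std <- rwr(g, "A", rwr_config(lambda = 0.5))
  lit <- rwr(g, "A", rwr_config(lambda = 0.5, as_printed = TRUE))
  expect_equal(sum(std$p), 1, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(unname(std$p), unname(lit$p))))
})

test_that("partner collection respects the top fraction and pathway membership", {
  # star around the seed: spokes all tie, pathway v holds some spokes
  spokes <- sprintf("S%02d", 1:10)
  g <- gene_network(data.frame(from = "HUB", to = spokes))
  cfg <- rwr_config(top_frac = 1.0)
  expect_setequal(twrwr_partners(g, "HUB", spokes[1:4], cfg),
                  spokes[1:4])
  # disjoint pathway: empty partner set
  expect_length(twrwr_partners(g, "HUB", c("X", "Y"), cfg), 0)
  # top fraction cuts by rank with ties broken by gene id
  cfg2 <- rwr_config(top_frac = 0.3)  # ceil(0.3*10) = 3 of the spokes
  expect_equal(twrwr_partners(g, "HUB", spokes, cfg2), spokes[1:3])
})

test_that("crosstalk scores handle empty seeds, empty partners and boundary tails", {
  g <- gene_network(data.frame(from = c("A", "B", "C"),
                               to = c("B", "C", "D")))
  lab <- labeling_from_sets(c("A", "B", "C", "D", "E"),
                            deg = c("A", "B"), devg = "C")
  # no dysregulated gene of u in the network -> score 1 with warning
  expect_warning(s <- crosstalk_score("E", c("B"), lab, g), "no dys")
  expect_equal(as.numeric(s), 1)
  # partner set empty -> 1
  s2 <- crosstalk_score(c("A"), "ZZ", lab, g,
                        rwr_config(top_frac = 1))
  expect_equal(as.numeric(s2), 1)
  # strict tail at the maximal observation is 0, inclusive is positive
  cfg_strict <- rwr_config(top_frac = 1, inclusive = FALSE)
  cfg_incl <- rwr_config(top_frac = 1, inclusive = TRUE)
  s3 <- crosstalk_score("A", c("B", "C", "D"), lab, g, cfg_strict)
  s4 <- crosstalk_score("A", c("B", "C", "D"), lab, g, cfg_incl)
  expect_gte(as.numeric(s4), as.numeric(s3))
})

test_that("map edges require both directions significant", {
  sim <- simulate_iea(spec_crosstalk_study(5))
  lab <- as_gene_labeling(sim$truth$gene_label)
  map <- build_pathway_map(sim$collection, lab, sim$network)
  sc <- map$scores
  expect_true(all(sc$accepted == (sc$e_uv < map$alpha &
                                    sc$e_vu < map$alpha)))
  # single-pathway collection: empty map
  m1 <- build_pathway_map(sim$collection[1], lab, sim$network)
  expect_equal(nrow(m1$edges), 0)
})

test_that("map construction is invariant under pathway relabeling", {
  sim <- simulate_iea(spec_crosstalk_study(3))
  lab <- as_gene_labeling(sim$truth$gene_label)
  coll <- sim$collection
  map1 <- build_pathway_map(coll, lab, sim$network)
  # permute pathway names
  perm <- rev(names(coll))
  coll2 <- GeneSetCollection(setNames(lapply(names(coll),
                                             function(n) coll[[n]]),
                                      perm))
  map2 <- build_pathway_map(coll2, lab, sim$network)
  rename <- setNames(perm, names(coll))
  key1 <- sort(apply(map1$edges[, c("u", "v")], 1, function(r)
    paste(sort(rename[r]), collapse = "|")))
  key2 <- sort(apply(map2$edges[, c("u", "v")], 1, function(r)
    paste(sort(r), collapse = "|")))
  expect_equal(key1, key2)
})

test_that("module detection recovers planted cliques and handles tiny maps", {
  clique_edges <- function(nodes)
    as.data.frame(t(utils::combn(nodes, 2)), stringsAsFactors = FALSE)
  e <- rbind(clique_edges(paste0("A", 1:4)),
             clique_edges(paste0("B", 1:4)),
             data.frame(V1 = "A1", V2 = "B1"))
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  map <- structure(list(graph = g, edges = e, alpha = 0.001,
                        modules = NULL), class = "PathwayMap")
  map <- detect_modules(map)
  # oracle: exhaustive modularity maximization on the 8 nodes
  oracle <- brute_modularity(g)
  expect_equal(igraph::modularity(g, map$modules[igraph::V(g)$name]),
               oracle$modularity, tolerance = 1e-10)
  a_mods <- unique(map$modules[paste0("A", 1:4)])
  b_mods <- unique(map$modules[paste0("B", 1:4)])
  expect_length(a_mods, 1)
  expect_length(b_mods, 1)
  expect_false(a_mods == b_mods)
  # disconnected pairs become separate modules
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("P", "R"), to = c("Q", "S")), directed = FALSE)
  map2 <- detect_modules(structure(list(graph = g2), class = "PathwayMap"))
  expect_equal(unname(map2$modules[["P"]]), unname(map2$modules[["Q"]]))
  expect_false(map2$modules[["P"]] == map2$modules[["R"]])
  # empty map
  map0 <- detect_modules(structure(
    list(graph = igraph::make_empty_graph(0, directed = FALSE)),
    class = "PathwayMap"))
  expect_length(map0$modules, 0)
})

test_that("differential network keeps rewired edges and drops degenerate ones", {
  set.seed(31)
  n <- 50
  base <- rnorm(n)
  ctrl <- rbind(A = base + rnorm(n, 0, 0.2),
                B = base + rnorm(n, 0, 0.2),
                C = rnorm(n), D = rnorm(n), E = rep(3, n))
  case <- rbind(A = rnorm(n), B = rnorm(n),
                C = rnorm(n), D = rnorm(n), E = rep(3, n))
  ds <- make_dataset(ctrl, case)
  g <- gene_network(data.frame(from = c("A", "C", "E", "A"),
                               to = c("B", "D", "A", "ZZ")))
  dn <- suppressWarnings(differential_network(g, ds))
  # A-B decorrelates (r ~ 0.9 -> ~0): kept; oracle = Fisher z by hand
  r1 <- cor(ctrl["A", ], ctrl["B", ]); r2 <- cor(case["A", ], case["B", ])
  z <- (atanh(r2) - atanh(r1)) / sqrt(2 / (n - 3))
  expect_lt(2 * pnorm(-abs(z)), 1e-6)
  expect_true(igraph::are_adjacent(dn, "A", "B"))
  # C-D uncorrelated in both: dropped
  expect_false("C" %in% igraph::V(dn)$name &&
                 "D" %in% igraph::V(dn)$name &&
                 igraph::are_adjacent(dn, "C", "D"))
  # constant gene E: degenerate, counted
  expect_equal(attr(dn, "n_degenerate"), 1L)
  # unmeasured endpoint ZZ: counted
  expect_equal(attr(dn, "n_unmeasured"), 1L)
  # identical correlation in both conditions: Z = 0, edge dropped
  ds2 <- make_dataset(cbind(ctrl, ctrl), cbind(ctrl, ctrl))
  g2 <- gene_network(data.frame(from = "A", to = "B"))
  dn2 <- suppressWarnings(differential_network(g2, ds2))
  expect_equal(igraph::ecount(dn2), 0)
  # too-small conditions are an error
  expect_error(differential_network(
    g2, make_dataset(ctrl[, 1:3], case[, 1:3])), ">= 4")
})

test_that("ranked_auc equals brute-force pair counting and hits the extremes", {
  genes <- sprintf("R%02d", 1:20)
  expect_equal(ranked_auc(genes, genes[1:5]), 1.0)
  expect_equal(ranked_auc(genes, genes[16:20]), 0.0)
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    lst <- sample(sprintf("X%03d", seq_len(n)))
    gold <- sample(lst, sample(seq_len(n - 1), 1))
    expect_equal(ranked_auc(lst, gold), brute_auc(lst, gold),
                 tolerance = 1e-12)
  }
  # tied scores count a half
  sc <- c(A = 2, B = 1, C = 1, D = 0)
  # pairs (A,C)=1 (A,D)=1 (B,C)=0.5 (B,D)=1 -> 3.5/4
  expect_equal(ranked_auc(sc, c("A", "B")), 3.5 / 4)
  expect_error(ranked_auc(genes, character(0)), "gold")
  expect_error(ranked_auc(genes, genes), "entire")
})
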