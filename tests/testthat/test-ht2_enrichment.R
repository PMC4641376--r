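test_that("ht2_pmf matches exhaustive enumeration on the worked example", {
  # N=5, y=2, x1=1, x2=1: all C(5,2)=10 draws equally likely
  P <- ht2_enum_dist(5, 1, 1, 2)
  expect_equal(ht2_pmf(5, 1, 1, 2, 0, 0), P[1, 1])  # 0.3
  expect_equal(ht2_pmf(5, 1, 1, 2, 1, 0), P[2, 1])  # 0.3
  expect_equal(ht2_pmf(5, 1, 1, 2, 0, 1), P[1, 2])  # 0.3
  expect_equal(ht2_pmf(5, 1, 1, 2, 1, 1), P[2, 2])  # 0.1
  # empty draw
  expect_equal(ht2_pmf(9, 3, 2, 0, 0, 0), 1)
  expect_equal(ht2_pmf(9, 3, 2, 0, 1, 0), 0)
  # x2 = 0 reduces to the one-category hypergeometric mass
  for (i in 0:3)
    expect_equal(ht2_pmf(10, 3, 0, 4, i, 0), dhyper(i, 3, 7, 4),
                 tolerance = 1e-14)
  # invariant violations are named errors
  expect_error(ht2_pmf(5, 4, 3, 2, 0, 0), "x1 \\+ x2")
  expect_error(ht2_pvalue(5, 1, 1, 6, 0, 0), "y")
  expect_error(ht2_pvalue(5, 1, 1, 2, 2, 0), "k1")
})

test_that("strict and inclusive tails agree with enumeration and behave at bounds", {
  expect_equal(ht2_pvalue(4, 1, 1, 2, 0, 0), 1 / 6, tolerance = 1e-12)
  # empty strict tail at the maximal observation
  expect_equal(ht2_pvalue(4, 1, 1, 2, 1, 0), 0)
  expect_equal(ht2_pvalue(4, 1, 1, 2, 0, 1), 0)
  # inclusive at (0,0) is certain when every gene is drawn
  expect_equal(ht2_pvalue(6, 2, 3, 6, 0, 0, inclusive = TRUE), 1,
               tolerance = 1e-12)
  # inclusive dominates strict
  for (k1 in 0:2) for (k2 in 0:2)
    expect_gte(ht2_pvalue(12, 4, 4, 6, k1, k2, inclusive = TRUE) + 1e-15,
               ht2_pvalue(12, 4, 4, 6, k1, k2))
})

test_that("pmf normalizes and the joint tail is monotone in both counts", {
  for (prm in list(c(8, 3, 2, 4), c(12, 5, 4, 7), c(20, 6, 6, 10),
                   c(30, 10, 8, 13))) {
    N <- prm[1]; x1 <- prm[2]; x2 <- prm[3]; y <- prm[4]
    grid <- expand.grid(k1 = 0:x1, k2 = 0:x2)
    expect_equal(sum(ht2_pmf(N, x1, x2, y, grid$k1, grid$k2)), 1,
                 tolerance = 1e-12)
    # monotone non-increasing tails over the feasible (k1, k2) region
    for (k2 in 0:min(x2, y)) {
      ks <- 0:min(x1, y - k2)
      tails <- vapply(ks, function(k1)
        ht2_pvalue(N, x1, x2, y, k1, k2), numeric(1))
      expect_true(all(diff(tails) <= 1e-12))
    }
  }
})

test_that("ora_pvalue is the hypergeometric upper tail and the x2=0 reduction of HT2", {
  expect_equal(ora_pvalue(10, 5, 5, 0), 1)
  expect_equal(ora_pvalue(10, 5, 5, 5), 1 / choose(10, 5),
               tolerance = 1e-12)
  for (k in 0:4)
    expect_equal(ora_pvalue(12, 4, 6, k),
                 ht2_pvalue(12, 4, 0, 6, k, 0, inclusive = TRUE),
                 tolerance = 1e-12)
})

test_that("pathway scoring counts, ranks and flags correctly", {
  universe <- sprintf("U%02d", 1:12)
  lab <- labeling_from_sets(universe, deg = universe[1:3],
                            devg = universe[4:5])
  coll <- GeneSetCollection(list(
    HIT = universe[1:5],       # the entire DEG+DEVG set, y = x1 + x2
    COPY1 = universe[6:9],
    COPY2 = universe[6:9],     # identical twin: tied records
    MISS = c("ZZZ1", "ZZZ2")))  # disjoint from the universe
  enr <- suppressMessages(
    enrich_pathways(lab, coll, background = universe))
  expect_equal(attr(enr, "n_skipped"), 1L)  # MISS dropped
  hit <- enr[enr$pathway == "HIT", ]
  expect_equal(c(hit$y, hit$k1, hit$k2), c(5, 3, 2))
  # brute force: HIT has the minimal strict-tail p among all size-5
  # pathways in this universe
  P <- ht2_enum_dist(12, 3, 2, 5)
  subsets <- utils::combn(12, 5)
  all_p <- apply(subsets, 2, function(s) {
    k1 <- sum(s <= 3); k2 <- sum(s > 3 & s <= 5)
    ht2_pvalue(12, 3, 2, 5, k1, k2)
  })
  expect_equal(hit$p_ht2, min(all_p), tolerance = 1e-12)
  # a pathway disjoint from DEG+DEVG scores the enumerated null tail
  c1 <- enr[enr$pathway == "COPY1", ]
  expect_equal(c1$p_ht2, ht2_enum_tail(ht2_enum_dist(12, 3, 2, 4), 0, 0),
               tolerance = 1e-12)
  # identical pathways give identical records and tied mean ranks
  c2 <- enr[enr$pathway == "COPY2", ]
  expect_equal(c1$p_ht2, c2$p_ht2)
  expect_equal(c1$rank, c2$rank)
  # ranks are a permutation-with-ties of 1..n
  expect_equal(sum(enr$rank), sum(seq_len(nrow(enr))))
})

test_that("gene distribution fractions are consistent with disjoint labels", {
  universe <- sprintf("V%02d", 1:10)
  lab <- labeling_from_sets(universe, deg = universe[1:4],
                            devg = universe[5:6])
  coll <- GeneSetCollection(list(ALL = universe,
                                 NONE = universe[7:10]))
  gd <- gene_distribution(lab, coll, background = universe)
  expect_equal(gd$frac_deg[gd$pathway == "ALL"], 0.4)
  expect_equal(gd$frac_devg[gd$pathway == "ALL"], 0.2)
  expect_equal(gd$frac_deg[gd$pathway == "NONE"], 0)
  expect_true(all(gd$frac_deg + gd$frac_devg <= 1))
})

test_that("target_rank reports mean-rank positions and rejects unknown targets", {
  universe <- sprintf("W%02d", 1:30)
  lab <- labeling_from_sets(universe, deg = universe[1:6],
                            devg = universe[7:9])
  sets <- c(list(T1 = universe[1:6]),
            setNames(lapply(1:8, function(i) universe[10 + (1:4) + i]),
                     paste0("N", 1:8)))
  enr <- enrich_pathways(lab, GeneSetCollection(sets),
                         background = universe)
  tr <- target_rank(enr, "T1")
  expect_equal(tr$rank, 1)
  expect_equal(tr$norm_rank, 100 / 9)
  expect_error(target_rank(enr, "ABSENT"), "ABSENT")
  # all-tied records get the mean rank (n+1)/2
  lab0 <- labeling_from_sets(universe, deg = character(0),
                             devg = character(0))
  same <- GeneSetCollection(setNames(
    lapply(1:5, function(i) universe[1:4]), paste0("S", 1:5)))
  enr0 <- enrich_pathways(lab0, same, background = universe)
  expect_equal(target_rank(enr0, "S3")$rank, 3)
})
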