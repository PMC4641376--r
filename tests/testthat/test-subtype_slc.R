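test_that("binarize thresholds against the reference group mean with ties to zero", {
  m <- rbind(G1 = c(5, 5, 5, 5, 6.1, 4.2),
             G2 = c(1, 1, 1, 1, 1, 1))
  colnames(m) <- c(paste0("C", 1:4), paste0("D", 1:2))
  ds <- ExpressionDataset(m, c(rep("control", 4), rep("case", 2)))
  B <- binarize(ds, c("G1", "G2"))
  expect_equal(unname(B[, "G1"]), c(1L, 0L))
  expect_equal(unname(B[, "G2"]), c(0L, 0L))   # constant gene: all 0
  # exact tie gives 0
  m2 <- m; m2["G1", "D1"] <- 5
  ds2 <- ExpressionDataset(m2, c(rep("control", 4), rep("case", 2)))
  expect_equal(unname(binarize(ds2, "G1")[, 1]), c(0L, 0L))
  expect_error(binarize(ds, character(0)), "empty")
  expect_error(binarize(ds, "NOPE"), "NOPE")
})

test_that("binarize is exactly invariant under affine rescaling of both groups", {
  set.seed(51)
  ds <- make_dataset(matrix(rnorm(40), 4), matrix(rnorm(40), 4))
  genes <- rownames(ds$values)
  B1 <- binarize(ds, genes)
  ds2 <- ds
  ds2$values <- 2.5 * ds$values + 7
  expect_identical(binarize(ds2, genes), B1)
})

test_that("slc clustering separates block-structured bits and flags degenerate input", {
  B <- matrix(c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1), nrow = 4,
              byrow = TRUE,
              dimnames = list(paste0("S", 1:4), paste0("g", 1:3)))
  cl <- slc_cluster(B)
  expect_equal(unname(cl["S1"]), unname(cl["S2"]))
  expect_equal(unname(cl["S3"]), unname(cl["S4"]))
  expect_false(cl[["S1"]] == cl[["S3"]])
  # kmeans agrees on this trivially separable input
  clk <- slc_cluster(B, method = "kmeans")
  expect_equal(length(unique(clk)), 2)
  # identical vectors: single cluster with a warning
  expect_warning(one <- slc_cluster(B[c(1, 2), , drop = FALSE]),
                 "identical")
  expect_equal(unique(one), 1L)
  expect_error(slc_cluster(B[1, , drop = FALSE]), "2 samples")
})

test_that("planted two-block binary matrices are recovered despite bit flips", {
  ari <- function(a, b) {
    t <- table(a, b); n <- sum(t)
    si <- sum(choose(rowSums(t), 2)); sj <- sum(choose(colSums(t), 2))
    sij <- sum(choose(t, 2)); e <- si * sj / choose(n, 2)
    (sij - e) / ((si + sj) / 2 - e)
  }
  set.seed(52)
  scores <- replicate(10, {
    truth <- rep(1:2, each = 10)
    B <- matrix(rep(truth - 1, 8), nrow = 20)
    flip <- matrix(runif(length(B)) < 0.1, nrow = 20)
    B[flip] <- 1 - B[flip]
    rownames(B) <- paste0("S", 1:20)
    ari(slc_cluster(B), truth)
  })
  expect_gte(mean(scores), 0.9)
})

test_that("clinical association uses exact rank-sum and Fisher tests appropriately", {
  cl <- clinical_table(
    data.frame(age = c(70, 72, 75, 71, 30, 31, 29, 33),
               grp = c("a", "a", "b", "b", "a", "a", "b", "b"),
               flat = rep(1, 8)),
    paste0("S", 1:8),
    c(age = "continuous", grp = "categorical", flat = "continuous"))
  assign <- setNames(rep(1:2, each = 4), paste0("S", 1:8))
  # fully separated 4+4 continuous index: exact p = 2/C(8,4) = 2/70
  expect_equal(clinical_association(assign, cl, "age"), 2 / 70,
               tolerance = 1e-12)
  # identical values in both clusters: p = 1
  expect_equal(clinical_association(assign, cl, "flat"), 1)
  # balanced categorical index: Fisher p = 1
  expect_equal(clinical_association(assign, cl, "grp"), 1)
  # missing values shrinking a cluster below the floor: NA with reason
  cl2 <- cl; cl2$age[1:2] <- NA
  out <- clinical_association(assign, cl2, "age")
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "min_cluster")
  expect_error(clinical_association(assign, cl, "nope"), "unknown")
})

test_that("the subtype screen flags the planted pathway for the linked index only", {
  sim <- simulate_iea(spec_subtype_study(8))
  lab <- classify_genes(sim$dataset, min_genes = 20)
  sf <- screen_subtype_factors(sim$dataset, lab, sim$collection,
                               sim$clinical)
  planted <- names(sim$truth$pathway_status)[
    sim$truth$pathway_status == "mixed"]
  for (pw in planted)
    expect_true(any(sf$flagged[sf$pathway == pw & sf$index == "age"]))
  # pathways with too few DEVGs are skipped
  coll2 <- GeneSetCollection(list(TINY = sim$collection[[1]][1:2]))
  sf2 <- screen_subtype_factors(sim$dataset, lab, coll2, sim$clinical)
  expect_equal(nrow(sf2), 0)
  expect_equal(attr(sf2, "n_skipped"), 1L)
  # a constant clinical index can never be flagged
  const <- sim$clinical
  const$bmi <- 0
  sf3 <- screen_subtype_factors(sim$dataset, lab, sim$collection, const)
  expect_true(all(sf3$p[sf3$index == "bmi"] == 1))
})

test_that("PGC screens raw expression, skips absent pathways, agrees on strong signal", {
  sim <- simulate_iea(spec_subtype_study(9))
  lab <- classify_genes(sim$dataset, min_genes = 20)
  sf <- screen_subtype_factors(sim$dataset, lab, sim$collection,
                               sim$clinical)
  pg <- pgc_baseline(sim$dataset, sim$collection, sim$clinical)
  expect_true(all(pg$method == "PGC"))
  planted <- names(sim$truth$pathway_status)[
    sim$truth$pathway_status == "mixed"]
  # the planted subtype also separates raw expression strongly here,
  # so both strategies flag the planted pathways
  for (pw in planted) {
    expect_true(any(sf$flagged[sf$pathway == pw & sf$index == "age"]))
    expect_true(any(pg$flagged[pg$pathway == pw & pg$index == "age"]))
  }
  # pathway absent from the expression data is skipped
  coll2 <- GeneSetCollection(list(GHOST = c("NO1", "NO2", "NO3")))
  pg2 <- pgc_baseline(sim$dataset, coll2, sim$clinical)
  expect_equal(nrow(pg2), 0)
})

test_that("two identical screens give byte-identical output tables", {
  sim <- simulate_iea(spec_subtype_study(10))
  lab <- classify_genes(sim$dataset, min_genes = 20)
  f1 <- tempfile(); f2 <- tempfile()
  write_table(screen_subtype_factors(sim$dataset, lab, sim$collection,
                                     sim$clinical), f1)
  write_table(screen_subtype_factors(sim$dataset, lab, sim$collection,
                                     sim$clinical), f2)
  expect_identical(readLines(f1), readLines(f2))
})
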