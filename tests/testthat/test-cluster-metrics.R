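test_that("average linkage reproduces the hand-computed UPGMA tree", {
  fm <- matrix(c(0, 1, 10, 11), ncol = 1)
  tree <- linkageAverage(fm)
  # pairs (0,1) and (10,11) merge at height 1; the final merge joins the two
  # pairs at the average inter-set distance (9+10+10+11)/4 = 10
  expect_equal(sort(tree$height), c(1, 1, 10))
  expect_identical(cutClusters(tree, 2), c(1L, 1L, 2L, 2L))
  expect_identical(cutClusters(tree, 4), 1:4)
  expect_identical(cutClusters(tree, 1), rep(1L, 4))
  # duplicated points merge at height zero
  treeDup <- linkageAverage(matrix(c(3, 3, 8), ncol = 1))
  expect_equal(min(treeDup$height), 0)
  expect_error(linkageAverage(matrix(1, 1, 1)), "at least 2")
})

test_that("cophenetic distances are ultrametric and CCC matches direct evaluation", {
  set.seed(41)
  for (rep in 1:8) {
    x <- matrix(rnorm(sample(5:25, 1) * 3), ncol = 3)
    tree <- linkageAverage(x)
    expect_equal(copheneticCorrelation(x, tree), cccOracle(x, tree),
                 tolerance = 1e-12)
    # ultrametric inequality on all triples of cophenetic distances
    tm <- as.matrix(stats::cophenetic(tree))
    n <- nrow(tm)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (l in (j + 1):n)
      expect_lte(tm[i, j], max(tm[i, l], tm[j, l]) + 1e-12)
  }
})

test_that("CCC is exactly 1 on ultrametric configurations and label-order invariant", {
  # isoceles triangle: two equal long sides make the metric ultrametric
  iso <- rbind(c(0, 0), c(1, 0), c(0.5, 8))
  expect_equal(copheneticCorrelation(iso, linkageAverage(iso)), 1,
               tolerance = 1e-12)
  # two blobs of duplicated points: within-blob distances all equal (zero)
  blobs <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(copheneticCorrelation(blobs, linkageAverage(blobs)), 1,
               tolerance = 1e-12)
  # permuting the objects leaves CCC unchanged
  set.seed(43)
  x <- matrix(rnorm(36), ncol = 3)
  ref <- copheneticCorrelation(x, linkageAverage(x))
  for (rep in 1:5) {
    p <- sample(nrow(x))
    xp <- x[p, , drop = FALSE]
    expect_equal(copheneticCorrelation(xp, linkageAverage(xp)), ref,
                 tolerance = 1e-12)
  }
  expect_error(copheneticCorrelation(blobs[c(1, 2), ], NULL), "at least 3")
})

test_that("S_Dbw equals the naive term-by-term oracle on random partitions", {
  set.seed(47)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    p <- sample(2:8, 1)
    k <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), ncol = p)
    labels <- sample(c(seq_len(k), sample(k, n - k, replace = TRUE)))
    labels <- as.integer(match(labels, unique(labels)))
    for (variant in c("printed", "rootMean")) {
      expect_equal(sDbw(x, labels, variant = variant),
                   sdbwOracle(x, labels, variant = variant)$value,
                   tolerance = 1e-10)
    }
  }
})

test_that("S_Dbw honors its degenerate conventions and separation behavior", {
  # two singleton clusters at distinct points: zero scattering, zero density
  expect_equal(sDbw(rbind(c(0, 0), c(3, 4)), c(1L, 2L)), 0)
  expect_error(sDbw(matrix(rnorm(20), ncol = 2), rep(1L, 10)), "at least 2")
  expect_error(sDbw(matrix(1, 6, 2), rep(1:2, 3)), "degenerate dataset")
  # moving two clusters apart cannot increase the inter-cluster density term
  set.seed(53)
  a <- matrix(rnorm(40, sd = 0.8), ncol = 2)
  b <- matrix(rnorm(40, sd = 0.8), ncol = 2)
  labels <- rep(1:2, each = 20)
  densities <- vapply(c(2, 4, 8, 16, 32), function(sep) {
    x <- rbind(a, b + sep)
    sdbwOracle(x, labels)$dens
  }, numeric(1))
  expect_true(all(diff(densities) <= 1e-12))
})

test_that("NMI follows the geometric-mean convention", {
  expect_equal(nmi(c(1, 1, 2, 2, 3), c(5, 5, 7, 7, 9)), 1)
  expect_equal(nmi(rep(1, 10), sample(2, 10, replace = TRUE)), 0)
  set.seed(59)
  for (rep in 1:10) {
    a <- sample(3, 30, replace = TRUE)
    b <- sample(3, 30, replace = TRUE)
    expect_equal(nmi(a, b), nmiOracle(a, b), tolerance = 1e-12)
  }
  expect_error(nmi(1:4, 1:5), "equal length")
})
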