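test_that("the CCC gate picks the first candidate that clears the threshold", {
  g <- fixtureSignal(seed = 3, T = 30L * 256L, duration = 640L)
  cfg <- searchConfig(d = 32, candidateSizes = c(48, 64, 96), ipt = 512)
  picked <- selectMinWindow(g$signal, cfg)
  gate <- attr(picked, "gate")
  # componentwise oracle: recompute CCC per candidate independently
  for (r in seq_len(nrow(gate))) {
    fm <- featureMatrix(g$signal, makeWindows(g$signal, gate$Lw[r], 32))
    expect_equal(gate$CCC[r], copheneticCorrelation(fm, linkageAverage(fm)),
                 tolerance = 1e-12)
  }
  pass <- gate$CCC >= 0.85 - 0.001
  expect_identical(as.integer(picked), gate$Lw[which(pass)[1]])
  # an unreachable threshold reports every candidate with its CCC
  cfgHigh <- searchConfig(d = 32, candidateSizes = c(48, 64), U = 0.999,
                          cccTol = 0, ipt = 512)
  expect_error(selectMinWindow(g$signal, cfgHigh), "Lw = 64")
})

test_that("grid search records consistent per-size optima", {
  g <- fixtureSignal(seed = 5, T = 30L * 256L, duration = 640L)
  cfg <- searchConfig(d = 32, DL = 16, NL = 2, NG = 9, ipt = 512,
                      maxExtend = 0)
  scan <- suppressWarnings(gridSearch(g$signal, 64L, cfg))
  grid <- scanGrid(scan)
  expect_identical(grid$Lw, c(64L, 80L, 96L))
  expect_equal(scan@MInH, min(grid$MIn))
  expect_identical(optimalWindow(scan), grid$Lw[which.min(grid$MIn)])
  # the stored curve belongs to the optimal size and attains MInH
  expect_equal(min(scan@sdbwCurve$SDbw), scan@MInH)
  expect_identical(scan@sdbwCurve$g[which.min(scan@sdbwCurve$SDbw)],
                   optimalGroups(scan))
  # per-size No/MIn equal an independent re-scoring of that size
  for (r in seq_len(nrow(grid))) {
    fm <- featureMatrix(g$signal, makeWindows(g$signal, grid$Lw[r], 32))
    tree <- linkageAverage(fm)
    vals <- vapply(2:10, function(k) sDbw(fm, cutClusters(tree, k)),
                   numeric(1))
    expect_equal(grid$MIn[r], min(vals), tolerance = 1e-12)
    expect_identical(grid$No[r], (2:10)[which.min(vals)])
  }
  # single-size grid: the optimum is that size
  one <- suppressWarnings(
    gridSearch(g$signal, 64L, searchConfig(d = 32, NL = 0, NG = 9,
                                           ipt = 512, maxExtend = 0)))
  expect_identical(optimalWindow(one), 64L)
  expect_equal(one@MInH, grid$MIn[1], tolerance = 1e-12)
})

test_that("the scan is deterministic and classifyOptimal re-cuts the stored tree", {
  g <- fixtureSignal(seed = 8, T = 30L * 256L, duration = 640L)
  cfg <- searchConfig(d = 32, DL = 16, NL = 1, NG = 9, ipt = 512,
                      maxExtend = 0)
  s1 <- suppressWarnings(gridSearch(g$signal, 64L, cfg))
  s2 <- suppressWarnings(gridSearch(g$signal, 64L, cfg))
  expect_identical(scanGrid(s1), scanGrid(s2))
  expect_identical(s1@labels, s2@labels)
  lab <- classifyOptimal(s1)
  expect_identical(lab, cutClusters(s1@tree, optimalGroups(s1)))
  expect_identical(lab, s1@labels)
  # labels are numbered by first appearance along the time axis
  expect_identical(unique(lab), seq_len(max(lab)))
})

test_that("a known event-free period forbids windows that overrun it", {
  g <- fixtureSignal(seed = 9, T = 20L * 256L, duration = 640L)
  cfg <- searchConfig(d = 32, DL = 64, NL = 7, ipt = 512)
  expect_error(gridSearch(g$signal, 128L, cfg), "event-free initial period")
})

test_that("an unknown event-free period prepends a synthetic prefix", {
  g <- fixtureSignal(seed = 10, T = 20L * 256L, duration = 640L)
  cfg <- searchConfig(d = 32, DL = 16, NL = 1, NG = 9, ipt = NA,
                      maxExtend = 0)
  set.seed(1)
  scan <- suppressWarnings(gridSearch(g$signal, 64L, cfg))
  expect_identical(scan@prefixLength, 80L + 32L)   # max Lw + d
  expect_identical(numWindows(scan@features),
                   (nSamples(g$signal) + 112L - optimalWindow(scan)) %/% 32L + 1L)
})

test_that("incremental classification inherits labels and flags novel regimes", {
  ref <- blobReference(seed = 1)
  scan <- blobScan(ref, k = 3)
  set.seed(1)
  nearTwo <- uniformBlob(5, 6, 0)       # inside the second blob's support
  res <- incrementalClassify(scan, nearTwo)
  expect_identical(res$k, 3L)
  expect_false(any(res$isNew))
  expect_identical(res$labels, rep(scan@labels[19], 5))
  # stopping index equals a naive scan for the first rise of the index
  vals <- vapply(3:9, function(g) {
    ds <- rbind(ref, nearTwo)
    tr <- linkageAverage(ds)
    sDbw(ds, cutClusters(tr, g))
  }, numeric(1))
  firstRise <- (3:9)[which(diff(vals) > 0)[1]]
  expect_identical(res$k, firstRise)

  set.seed(1)
  farAway <- uniformBlob(6, 7, 7)
  res2 <- incrementalClassify(scan, farAway)
  expect_gte(res2$k, 4L)
  expect_true(all(res2$isNew))
  expect_true(all(res2$labels > 3L))
  vals2 <- vapply(3:9, function(g) {
    ds <- rbind(ref, farAway)
    tr <- linkageAverage(ds)
    sDbw(ds, cutClusters(tr, g))
  }, numeric(1))
  expect_identical(res2$k, (3:9)[which(diff(vals2) > 0)[1]])

  expect_error(incrementalClassify(scan, matrix(0, 2, 5)),
               "dimension mismatch")
})

test_that("the full pipeline recovers planted events at the right locations", {
  g <- fixtureSignal(seed = 11)
  cfg <- searchConfig(d = 32, candidateSizes = c(64, 96, 128), DL = 8,
                      NL = 6, NG = 9, ipt = 512, maxExtend = 1)
  res <- suppressWarnings(detectEvents(g$signal, cfg))
  ev <- eventTable(res$events)
  # every planted event overlaps a detected long-duration state
  long <- ev[ev$dE > 1, ]
  expect_identical(nrow(long), 3L)
  for (r in seq_len(3)) {
    tr <- g$truth@events[r, ]
    expect_true(any(long$startSample < tr$end & long$endSample > tr$start))
  }
})
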