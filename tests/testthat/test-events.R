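test_that("consecutive-run grouping matches a left-to-right scan", {
  scanOracle <- function(labels) {
    out <- list()
    start <- 1
    for (i in seq_along(labels)) {
      if (i == length(labels) || labels[i + 1] != labels[i]) {
        out[[length(out) + 1]] <- data.frame(label = labels[start],
                                             i = start, j = i)
        start <- i + 1
      }
    }
    do.call(rbind, out)
  }
  set.seed(61)
  for (rep in 1:10) {
    labels <- sample(3, 40, replace = TRUE)
    runs <- groupConsecutive(labels)
    oracle <- scanOracle(labels)
    expect_equal(runs$label, oracle$label)
    expect_identical(runs$i, as.integer(oracle$i))
    expect_identical(runs$j, as.integer(oracle$j))
    # partition property: runs cover every interval exactly once
    expect_identical(sum(runs$j - runs$i + 1L), 40L)
  }
  expect_identical(nrow(groupConsecutive(rep(2, 7))), 1L)

  # two adjacent same-label groups separated by a label change
  labels <- rep(1L, 1460)
  labels[1447:1449] <- 6L
  labels[1450:1454] <- 7L
  runs <- groupConsecutive(labels)
  expect_identical(runs$i[runs$label == 6L], 1447L)
  expect_identical(runs$j[runs$label == 6L], 1449L)
  expect_identical(runs$i[runs$label == 7L], 1450L)
  expect_identical(runs$j[runs$label == 7L], 1454L)
})

test_that("run localization follows the late-window anchor arithmetic", {
  span <- localizeRun(1, 1, d = 32, Lw = 128)
  expect_equal(span[1, "start"], 6 / 7 * 128 - 16, ignore_attr = TRUE)
  expect_equal(span[1, "end"], 6 / 7 * 128 + 16, ignore_attr = TRUE)
  expect_equal(unname(span[1, "end"] - span[1, "start"]), 32)
  # span width is always (j - i + 1) * d, whatever Lw and M
  set.seed(67)
  for (rep in 1:20) {
    i <- sample(500, 1)
    j <- i + sample(0:50, 1)
    d <- sample(c(8, 32, 64), 1)
    Lw <- sample(c(64, 128, 155), 1)
    s <- localizeRun(i, j, d = d, Lw = Lw)
    expect_equal(unname(s[1, "end"] - s[1, "start"]), (j - i + 1) * d)
  }
  expect_error(localizeRun(5, 4, 32, 128), "i <= j")
})

test_that("adjacent runs abut exactly after localization", {
  labels <- c(1, 1, 2, 2, 2, 1, 3, 3, 1, 1)
  runs <- groupConsecutive(labels)
  spans <- localizeRun(runs$i, runs$j, d = 32, Lw = 128)
  expect_equal(spans[-1, "start"], spans[-nrow(spans), "end"],
               ignore_attr = TRUE)
})

test_that("buildSequence assembles time-ordered states with exact durations", {
  labels <- c(rep(1L, 20), rep(2L, 3), rep(1L, 10), rep(3L, 5), rep(1L, 12))
  runs <- groupConsecutive(labels)
  seq <- buildSequence(runs, d = 32, Lw = 128, fs = 256)
  expect_s4_class(seq, "EventSequence")
  expect_identical(seq@baselineLabel, 1L)     # most populous group
  st <- eventTable(seq)
  expect_identical(st$label, c(2L, 3L))
  # states equal the elementwise localization, expressed in seconds
  for (r in seq_len(nrow(st))) {
    span <- localizeRun(st$i[r], st$j[r], d = 32, Lw = 128)
    expect_equal(st$startSample[r], unname(span[1, "start"]))
    expect_equal(st$tE[r], unname(span[1, "start"]) / 256)
    expect_equal(st$dE[r], (st$j[r] - st$i[r] + 1) * 32 / 256)
  }
  # baseline runs are kept apart as event-free portions
  expect_identical(nrow(baselineTable(seq)), 3L)
  expect_identical(seq@nIntervals, 50L)
})

test_that("a synthetic prefix shifts, clips and drops localized runs", {
  labels <- c(rep(4L, 6), rep(1L, 30), rep(2L, 4))
  runs <- groupConsecutive(labels)
  seq <- buildSequence(runs, d = 32, Lw = 64, fs = 256, prefixLength = 300L,
                       baselineLabel = 1L)
  st <- eventTable(seq)
  # the prefix-only run (label 4) ends before real sample 0 and is dropped
  expect_identical(st$label, 2L)
  expect_true(all(st$startSample >= 0))
  expect_true(all(baselineTable(seq)$startSample >= 0))
})

test_that("durations display truncated while machine values stay exact", {
  expect_identical(truncateSeconds(c(0.375, 0.625, 1.999)),
                   c(0.37, 0.62, 1.99))
  labels <- c(rep(1L, 1446), rep(6L, 3), rep(7L, 5), rep(1L, 6))
  runs <- groupConsecutive(labels)
  seq <- buildSequence(runs, d = 32, Lw = 155, fs = 256)
  st <- eventTable(seq)
  expect_equal(st$dE, c(0.375, 0.625))
  expect_identical(truncateSeconds(st$dE), c(0.37, 0.62))
})

test_that("event statistics count occurrences and span-wise group presence", {
  labels <- c(rep(1L, 10), rep(2L, 3), rep(1L, 8), rep(3L, 4), rep(1L, 5),
              rep(2L, 2), rep(1L, 8))
  runs <- groupConsecutive(labels)
  seq <- buildSequence(runs, d = 32, Lw = 64, fs = 256)
  stats <- eventStats(seq)
  expect_identical(stats$perLabel$label, c(2L, 3L))
  expect_identical(stats$perLabel$count, c(2L, 1L))
  # counts agree with a recount of the runs per label
  for (r in seq_len(nrow(stats$perLabel))) {
    lab <- stats$perLabel$label[r]
    expect_identical(stats$perLabel$count[r],
                     sum(runs$label == lab & runs$label != 1L))
    expect_equal(stats$perLabel$totalDuration[r],
                 sum((runs$j - runs$i + 1)[runs$label == lab]) * 32 / 256)
  }
  expect_identical(stats$nic, 3L)     # two event types plus baseline
  # a span holding one event type has two groups; an empty sequence has one
  early <- eventStats(seq, from = 0, to = eventTable(seq)$endSec[1])
  expect_identical(early$nic, 2L)
  empty <- buildSequence(groupConsecutive(rep(1L, 10)), d = 32, Lw = 64,
                         fs = 256)
  expect_identical(eventStats(empty)$nic, 1L)
  expect_identical(nrow(eventStats(empty)$perLabel), 0L)
})
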