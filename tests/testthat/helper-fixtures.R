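# Shared fixtures, built in code at test time.

# Frozen AR(2) regime set used across tests: a lowpass background and three
# spectrally distinct event regimes, all far apart in (a1, a2) space.
fixtureRegimes <- function(duration = 1280L, occurrences = 1L) {
  list(baseline = regimeSpec("base", c(0.5, -0.2)),
       events = list(
         regimeSpec("A", c(-1.2, -0.6), duration = duration,
                    occurrences = occurrences),
         regimeSpec("B", c(1.6, -0.8), duration = duration,
                    occurrences = occurrences),
         regimeSpec("C", c(0.0, 0.8), duration = duration,
                    occurrences = occurrences)))
}

fixtureSignal <- function(seed, Q = 4L, T = 60L * 256L, duration = 1280L,
                          occurrences = 1L, mode = "replace") {
  r <- fixtureRegimes(duration, occurrences)
  generateSignal(r$baseline, r$events, Q = Q, T = T, fs = 256,
                 seed = seed, mode = mode)
}

# compact uniform blobs in 2-D: bounded support, so hierarchical cuts must
# split blobs rather than peel stragglers
uniformBlob <- function(n, cx, cy, halfwidth = 1) {
  cbind(runif(n, cx - halfwidth, cx + halfwidth),
        runif(n, cy - halfwidth, cy + halfwidth))
}

blobReference <- function(seed = 1L, nPer = 18L) {
  set.seed(seed)
  rbind(uniformBlob(nPer, 0, 0), uniformBlob(nPer, 6, 0),
        uniformBlob(nPer, 0, 6))
}

# wrap a plain matrix as a FeatureMatrix (one synthetic channel, order 2)
asFeatureMatrix <- function(m, Lw = 8L, d = 4L) {
  n <- nrow(m)
  ws <- new("WindowSet", Lw = as.integer(Lw), d = as.integer(d),
            starts = (seq_len(n) - 1L) * as.integer(d),
            T = as.integer(Lw + d * (n - 1L)))
  new("FeatureMatrix", values = as.matrix(m), windowSet = ws,
      channelLabels = "CH1", order = 2L)
}

# a self-consistent ScanResult over an externally supplied feature matrix
blobScan <- function(ref, k = 3L) {
  fm <- asFeatureMatrix(ref)
  tree <- linkageAverage(fm)
  labels <- cutClusters(tree, k)
  mins <- sDbw(fm, labels)
  new("ScanResult",
      grid = data.frame(Lw = 8L, CCC = copheneticCorrelation(fm, tree),
                        No = as.integer(k), MIn = mins),
      LwH = 8L, NoH = as.integer(k), MInH = mins,
      CCCH = copheneticCorrelation(fm, tree), features = fm, tree = tree,
      labels = labels,
      sdbwCurve = data.frame(g = as.integer(k), SDbw = mins),
      prefixLength = 0L, fs = 256, d = 4L)
}
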