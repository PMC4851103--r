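# S4 containers for the multichannel event-detection pipeline.

#' Multichannel signal
#'
#' A multichannel recording: a Q x T matrix of samples (channels in rows),
#' a sampling rate in Hz and one unique label per channel. This is the input
#' object of the whole pipeline; see [readSignal()] and [generateSignal()]
#' for the two ways of obtaining one.
#'
#' @slot samples numeric matrix, Q channels x T samples, all finite.
#' @slot fs sampling rate in Hz (> 0).
#' @slot channelLabels character vector of Q unique channel names.
#' @slot tStart time of sample 1 in seconds (default 0).
#'
#' @aliases nChannels,MultichannelSignal-method
#'   nSamples,MultichannelSignal-method samplingRate,MultichannelSignal-method
#'   channelLabels,MultichannelSignal-method
#'   signalMatrix,MultichannelSignal-method show,MultichannelSignal-method
#' @export
setClass("MultichannelSignal",
  representation(samples = "matrix", fs = "numeric",
                 channelLabels = "character", tStart = "numeric"),
  prototype(tStart = 0))

setValidity("MultichannelSignal", function(object) {
  msg <- character(0)
  m <- object@samples
  if (!is.numeric(m)) msg <- c(msg, "samples must be a numeric matrix")
  if (nrow(m) < 1L) msg <- c(msg, "at least one channel is required")
  if (ncol(m) < 2L) msg <- c(msg, "at least two samples are required")
  if (is.numeric(m) && !all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf("non-finite sample in channel %d at sample %d",
                          bad[1L], bad[2L]))
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelLabels) != nrow(m))
    msg <- c(msg, "channelLabels must have one entry per channel")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channelLabels must be unique")
  if (length(object@tStart) != 1L || !is.finite(object@tStart))
    msg <- c(msg, "tStart must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a MultichannelSignal
#'
#' @param samples numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channelLabels optional channel names; defaults to `CH1..CHQ`.
#' @param tStart time of the first sample in seconds.
#' @return A [MultichannelSignal-class] object.
#' @examples
#' sig <- MultichannelSignal(matrix(rnorm(512), nrow = 2), fs = 256)
#' nChannels(sig)
#' @export
MultichannelSignal <- function(samples, fs, channelLabels = NULL, tStart = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  if (is.null(channelLabels))
    channelLabels <- paste0("CH", seq_len(nrow(samples)))
  new("MultichannelSignal", samples = samples, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels), tStart = as.numeric(tStart))
}

#' @export
setMethod("nChannels", "MultichannelSignal", function(x) nrow(x@samples))
#' @export
setMethod("nSamples", "MultichannelSignal", function(x) ncol(x@samples))
#' @export
setMethod("samplingRate", "MultichannelSignal", function(x) x@fs)
#' @export
setMethod("channelLabels", "MultichannelSignal", function(x) x@channelLabels)
#' @export
setMethod("signalMatrix", "MultichannelSignal", function(x) {
  m <- x@samples
  rownames(m) <- x@channelLabels
  m
})

setMethod("show", "MultichannelSignal", function(object) {
  cat(sprintf("MultichannelSignal: %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              ncol(object@samples) / object@fs))
  cat("  channels:", paste(utils::head(object@channelLabels, 6L),
                           collapse = ", "),
      if (length(object@channelLabels) > 6L) "..." else "", "\n")
})

#' Sliding-window set
#'
#' The set of IN fully-contained sliding windows of length `Lw` advanced by
#' `d` samples over a signal of length T. Window starts are stored 0-based;
#' window numbers exposed to users (e.g. in event tables) are 1-based.
#'
#' @slot Lw window length in samples.
#' @slot d slide width in samples.
#' @slot starts integer vector of 0-based start samples, one per window.
#' @slot T total signal length the windows were built for.
#'
#' @aliases windowLength,WindowSet-method slideWidth,WindowSet-method
#'   numWindows,WindowSet-method windowStarts,WindowSet-method
#'   show,WindowSet-method
#' @export
setClass("WindowSet",
  representation(Lw = "integer", d = "integer", starts = "integer",
                 T = "integer"))

setValidity("WindowSet", function(object) {
  msg <- character(0)
  n <- length(object@starts)
  if (n < 1L) msg <- c(msg, "at least one window is required")
  if (object@Lw < 4L) msg <- c(msg, "Lw must be >= 4 samples")
  if (object@d < 1L) msg <- c(msg, "d must be >= 1 sample")
  if (n > 1L && any(diff(object@starts) != object@d))
    msg <- c(msg, "window starts must be spaced by d")
  if (n >= 1L && object@starts[n] + object@Lw > object@T)
    msg <- c(msg, "last window overruns the signal")
  expected <- (object@T - object@Lw) %/% object@d + 1L
  if (n != expected)
    msg <- c(msg, sprintf("window count %d != floor((T - Lw)/d) + 1 = %d",
                          n, expected))
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("windowLength", "WindowSet", function(x) x@Lw)
#' @export
setMethod("slideWidth", "WindowSet", function(x) x@d)
#' @export
setMethod("numWindows", "WindowSet", function(x) length(x@starts))
#' @export
setMethod("windowStarts", "WindowSet", function(x) x@starts)

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows of %d samples, slide %d, over T = %d\n",
              length(object@starts), object@Lw, object@d, object@T))
})

#' Window feature matrix
#'
#' IN x S matrix of per-window features: for each window, the per-channel
#' AR coefficient vectors concatenated channel-major
#' (`ch1:a1, ch1:a2, ch2:a1, ...`). Rows correspond to windows in temporal
#' order.
#'
#' @slot values numeric IN x S matrix, all entries finite.
#' @slot windowSet the generating [WindowSet-class].
#' @slot channelLabels channel names, in concatenation order.
#' @slot order the AR model order used per channel (default 2).
#'
#' @aliases featureValues,FeatureMatrix-method numWindows,FeatureMatrix-method
#'   show,FeatureMatrix-method
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", windowSet = "WindowSet",
                 channelLabels = "character", order = "integer"))

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all feature values must be finite")
  if (nrow(object@values) != numWindows(object@windowSet))
    msg <- c(msg, "one row per window is required")
  if (ncol(object@values) != length(object@channelLabels) * object@order)
    msg <- c(msg, "S must equal Q x order")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @export
setMethod("numWindows", "FeatureMatrix", function(x) nrow(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d windows x %d features (AR(%d), %d channels)\n",
              nrow(object@values), ncol(object@values), object@order,
              length(object@channelLabels)))
})

#' Search configuration
#'
#' Tuning parameters of the window-size / cluster-count search. See
#' [searchConfig()] for defaults and meanings.
#'
#' @slot d slide width in samples.
#' @slot U cophenetic-correlation gate threshold in (0, 1).
#' @slot candidateSizes increasing candidate window sizes for the gate stage
#'   (empty = automatic schedule).
#' @slot DL grid step in samples.
#' @slot NL number of grid increments (sizes tested: `Lw0 + 0:NL * DL`).
#' @slot NG partitions tested are `2..NG+1` groups.
#' @slot ipt length in samples of the known event-free initial period
#'   (`NA` = unknown; a synthetic event-free prefix is then prepended).
#' @slot cccTol slack below U still accepted by the gate.
#' @slot sdbwVariant `"printed"` or `"rootMean"`; see [sDbw()].
#' @slot maxExtend maximum automatic grid-extension rounds.
#'
#' @aliases show,SearchConfig-method
#' @export
setClass("SearchConfig",
  representation(d = "integer", U = "numeric", candidateSizes = "integer",
                 DL = "integer", NL = "integer", NG = "integer",
                 ipt = "numeric", cccTol = "numeric", sdbwVariant = "character",
                 maxExtend = "integer"))

setValidity("SearchConfig", function(object) {
  msg <- character(0)
  if (object@d < 1L) msg <- c(msg, "d must be >= 1")
  if (object@U <= 0 || object@U >= 1) msg <- c(msg, "U must be in (0, 1)")
  if (object@DL < 1L) msg <- c(msg, "DL must be >= 1")
  if (object@NL < 0L) msg <- c(msg, "NL must be >= 0")
  if (object@NG < 2L) msg <- c(msg, "NG must be >= 2")
  if (is.unsorted(object@candidateSizes, strictly = TRUE))
    msg <- c(msg, "candidateSizes must be strictly increasing")
  if (object@cccTol < 0) msg <- c(msg, "cccTol must be >= 0")
  if (!object@sdbwVariant %in% c("printed", "rootMean"))
    msg <- c(msg, "sdbwVariant must be 'printed' or 'rootMean'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SearchConfig", function(object) {
  cat(sprintf(paste0("SearchConfig: d=%d, U=%g (tol %g), grid DL=%d NL=%d ",
                     "NG=%d, ipt=%s, S_Dbw variant=%s\n"),
              object@d, object@U, object@cccTol, object@DL, object@NL,
              object@NG,
              if (is.na(object@ipt)) "unknown" else as.character(object@ipt),
              object@sdbwVariant))
})

#' Scan result
#'
#' Outcome of the joint search over window sizes and cluster counts: the
#' per-size table (window size, cophenetic correlation, optimal group count,
#' minimum S_Dbw), the optimum, and the clustering artifacts (feature matrix,
#' average-linkage tree, labels) at the optimal size.
#'
#' @slot grid data.frame with one row per window size tried: `Lw`, `CCC`,
#'   `No` (argmin group count), `MIn` (min S_Dbw over group counts).
#' @slot LwH optimal window size (samples).
#' @slot NoH optimal number of groups.
#' @slot MInH minimum S_Dbw at the optimum.
#' @slot CCCH cophenetic correlation at the optimal size.
#' @slot features [FeatureMatrix-class] at the optimal size.
#' @slot tree the `hclust` tree at the optimal size.
#' @slot labels integer group label per window at the optimum (1-based,
#'   numbered by first appearance in time).
#' @slot sdbwCurve data.frame (`g`, `SDbw`) of the index per group count at
#'   the optimal window size, for inspecting the shape of the curve.
#' @slot prefixLength samples of synthetic event-free prefix prepended before
#'   windowing (0 if none).
#' @slot fs sampling rate of the scanned signal.
#' @slot d slide width used.
#'
#' @aliases scanGrid,ScanResult-method optimalWindow,ScanResult-method
#'   optimalGroups,ScanResult-method numWindows,ScanResult-method
#'   show,ScanResult-method
#' @export
setClass("ScanResult",
  representation(grid = "data.frame", LwH = "integer", NoH = "integer",
                 MInH = "numeric", CCCH = "numeric",
                 features = "FeatureMatrix", tree = "ANY",
                 labels = "integer", sdbwCurve = "data.frame",
                 prefixLength = "integer",
                 fs = "numeric", d = "integer"))

setValidity("ScanResult", function(object) {
  msg <- character(0)
  need <- c("Lw", "CCC", "No", "MIn")
  if (!all(need %in% names(object@grid)))
    msg <- c(msg, "grid must have columns Lw, CCC, No, MIn")
  else {
    i <- which.min(object@grid$MIn)
    if (abs(object@grid$MIn[i] - object@MInH) > 1e-12)
      msg <- c(msg, "MInH must be the minimum of grid$MIn")
  }
  if (!inherits(object@tree, "hclust")) msg <- c(msg, "tree must be an hclust")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("scanGrid", "ScanResult", function(x) x@grid)
#' @export
setMethod("optimalWindow", "ScanResult", function(x) x@LwH)
#' @export
setMethod("optimalGroups", "ScanResult", function(x) x@NoH)
#' @export
setMethod("numWindows", "ScanResult", function(x) length(x@labels))

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult over %d window size(s):\n", nrow(object@grid)))
  print(object@grid, row.names = FALSE)
  cat(sprintf("optimum: Lw = %d samples, No = %d groups, MIn = %.4g, CCC = %.4f\n",
              object@LwH, object@NoH, object@MInH, object@CCCH))
  if (object@prefixLength > 0L)
    cat(sprintf("  (synthetic event-free prefix of %d samples prepended)\n",
                object@prefixLength))
})

#' Temporal event sequence
#'
#' The detector's output: an ordered sequence of states `(E, tE, dE)` — one
#' per maximal run of consecutive non-baseline intervals — localized on the
#' signal, plus the baseline (event-free) spans kept separately.
#'
#' @slot states data.frame, one row per event state: `label`, `i`, `j`
#'   (1-based first/last interval of the run), `startSample`, `endSample`
#'   (possibly fractional, 0-based), `tE`, `dE` and `endSec` (seconds).
#' @slot pwa data.frame of the same shape for baseline runs (portions
#'   without events).
#' @slot baselineLabel the group treated as event-free background.
#' @slot fs sampling rate (Hz).
#' @slot d slide width (samples).
#' @slot Lw window size used for localization (samples).
#' @slot M localization constant (default 6/7).
#' @slot nIntervals total number of classified intervals.
#'
#' @aliases eventTable,EventSequence-method baselineTable,EventSequence-method
#'   show,EventSequence-method
#' @export
setClass("EventSequence",
  representation(states = "data.frame", pwa = "data.frame",
                 baselineLabel = "integer", fs = "numeric", d = "integer",
                 Lw = "integer", M = "numeric", nIntervals = "integer"))

setValidity("EventSequence", function(object) {
  msg <- character(0)
  st <- object@states
  need <- c("label", "i", "j", "startSample", "endSample", "tE", "dE", "endSec")
  if (!all(need %in% names(st)))
    msg <- c(msg, paste("states must have columns:", paste(need, collapse = ", ")))
  else if (nrow(st) > 1L) {
    if (any(st$tE[-1L] + 1e-9 < (st$tE + st$dE)[-nrow(st)]))
      msg <- c(msg, "states must be time-ordered and non-overlapping")
  }
  if (nrow(st) > 0L && any(st$i > st$j))
    msg <- c(msg, "each run needs i <= j")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("eventTable", "EventSequence", function(x) x@states)
#' @export
setMethod("baselineTable", "EventSequence", function(x) x@pwa)

setMethod("show", "EventSequence", function(object) {
  cat(sprintf("EventSequence: %d event(s) over %d intervals (baseline group %d)\n",
              nrow(object@states), object@nIntervals, object@baselineLabel))
  if (nrow(object@states)) {
    df <- object@states
    # display truncates durations to 2 decimals; slots keep full precision
    df$dE <- truncateSeconds(df$dE)
    print(df[, c("label", "i", "j", "tE", "dE")], row.names = FALSE)
  }
})

#' 2-D principal-component projection
#'
#' Display-only PCA of a feature matrix (the clustering itself always runs on
#' the full feature space). Coordinates are `nComponents x n`; column k is
#' window k's projected feature vector.
#'
#' @slot coordinates numeric matrix, components x windows.
#' @slot explainedFraction fraction of total variance carried by the kept
#'   components, in [0, 1].
#' @slot rotation matrix whose rows are the kept eigenvectors (orthonormal),
#'   ordered by decreasing eigenvalue.
#' @slot eigenvalues all eigenvalues of the covariance, decreasing.
#'
#' @aliases show,Projection2D-method
#' @export
setClass("Projection2D",
  representation(coordinates = "matrix", explainedFraction = "numeric",
                 rotation = "matrix", eigenvalues = "numeric"))

setValidity("Projection2D", function(object) {
  msg <- character(0)
  if (object@explainedFraction < -1e-12 || object@explainedFraction > 1 + 1e-12)
    msg <- c(msg, "explainedFraction must be in [0, 1]")
  g <- object@rotation %*% t(object@rotation)
  if (max(abs(g - diag(nrow(g)))) > 1e-8)
    msg <- c(msg, "rotation rows must be orthonormal")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Projection2D", function(object) {
  cat(sprintf("Projection2D: %d components x %d points, %.1f%% variance explained\n",
              nrow(object@coordinates), ncol(object@coordinates),
              100 * object@explainedFraction))
})

#' Autoregressive regime specification
#'
#' One signal regime for the synthetic generator: a stationary AR(2) process
#' with a label, an amplitude gain, a duration and an occurrence count.
#' Stationarity requires `(a1, a2)` inside the triangle `|a2| < 1`,
#' `a1 + a2 < 1`, `a2 - a1 < 1`.
#'
#' @slot label regime name.
#' @slot ar numeric AR coefficient vector `(a1, a2)`.
#' @slot gain amplitude multiplier applied to the regime's samples.
#' @slot duration event duration in samples (ignored for the baseline).
#' @slot occurrences number of times the event is planted.
#'
#' @aliases show,RegimeSpec-method
#' @export
setClass("RegimeSpec",
  representation(label = "character", ar = "numeric", gain = "numeric",
                 duration = "integer", occurrences = "integer"))

setValidity("RegimeSpec", function(object) {
  msg <- character(0)
  a <- object@ar
  if (length(a) != 2L || !all(is.finite(a)))
    msg <- c(msg, "ar must be two finite coefficients (a1, a2)")
  else if (abs(a[2L]) >= 1 || a[1L] + a[2L] >= 1 || a[2L] - a[1L] >= 1)
    msg <- c(msg, sprintf(
      "AR(2) regime '%s' is not stationary: need |a2| < 1, a1 + a2 < 1, a2 - a1 < 1",
      object@label))
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
  if (object@duration < 0L) msg <- c(msg, "duration must be >= 0")
  if (object@occurrences < 0L) msg <- c(msg, "occurrences must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegimeSpec", function(object) {
  cat(sprintf("RegimeSpec '%s': AR(2) = (%g, %g), gain %g, %d x %d samples\n",
              object@label, object@ar[1L], object@ar[2L], object@gain,
              object@occurrences, object@duration))
})

#' Ground truth of a generated signal
#'
#' Per-sample regime labels and the planted event list of a synthetic
#' multichannel signal; [intervalLabels()] derives per-window labels for any
#' window layout by majority occupancy.
#'
#' @slot sampleLabels character vector, one regime label per sample.
#' @slot events data.frame with `label`, `start`, `end` (0-based sample
#'   spans, end exclusive) per planted event.
#'
#' @aliases show,GroundTruth-method
#' @export
setClass("GroundTruth",
  representation(sampleLabels = "character", events = "data.frame"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d samples, %d planted event(s), regimes: %s\n",
              length(object@sampleLabels), nrow(object@events),
              paste(unique(object@sampleLabels), collapse = ", ")))
})
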