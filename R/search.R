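# Joint optimization of window size and cluster count, and the incremental
# classification of new interval batches against a reference clustering.

#' Build a search configuration
#'
#' @param d slide width in samples (never optimized; default 32).
#' @param U cophenetic-correlation gate threshold (default 0.85). A window
#'   size passes the gate when its CCC reaches `U - cccTol`.
#' @param candidateSizes increasing window sizes scanned by the gate stage;
#'   empty (default) uses an automatic schedule: 32, 64, then every 32
#'   samples up to one second of samples.
#' @param DL grid step in samples for the size search (default 5).
#' @param NL number of size increments: sizes `Lw0 + 0:NL * DL` are scored
#'   (default 6, i.e. 7 sizes).
#' @param NG partitions of `2..NG+1` groups are scored per size (default 9).
#' @param ipt length in samples of the known event-free initial period of the
#'   signal. `NA` (default) means unknown: a synthetic event-free white-noise
#'   prefix (variance-matched per channel) is prepended before windowing and
#'   excluded from event reporting.
#' @param cccTol slack accepted below `U` (default 0.001).
#' @param sdbwVariant S_Dbw threshold convention, see [sDbw()].
#' @param maxExtend maximum automatic grid-extension rounds when the optimum
#'   lands on a grid boundary (default 3).
#' @return A [SearchConfig-class].
#' @export
searchConfig <- function(d = 32L, U = 0.85, candidateSizes = integer(0),
                         DL = 5L, NL = 6L, NG = 9L, ipt = NA_real_,
                         cccTol = 0.001, sdbwVariant = "printed",
                         maxExtend = 3L) {
  new("SearchConfig", d = as.integer(d), U = U,
      candidateSizes = as.integer(candidateSizes), DL = as.integer(DL),
      NL = as.integer(NL), NG = as.integer(NG), ipt = as.numeric(ipt),
      cccTol = cccTol, sdbwVariant = sdbwVariant,
      maxExtend = as.integer(maxExtend))
}

candidateSchedule <- function(fs, T) {
  top <- max(96, round(fs))
  sizes <- unique(c(32, 64, seq(96, top, by = 32)))
  sizes <- sizes[sizes <= T]
  if (!length(sizes)) stop("signal too short for any candidate window size")
  as.integer(sizes)
}

#' Select the minimum usable window size by the CCC gate
#'
#' Scans the candidate window sizes in increasing order; for each, builds
#' the AR feature matrix and its average-linkage tree and computes the
#' cophenetic correlation. The first size whose CCC reaches `U - cccTol` is
#' returned: small windows give noisy AR features whose distances cluster
#' poorly, and this gate fixes the lower end of the size grid.
#'
#' @param signal a [MultichannelSignal-class].
#' @param cfg a [SearchConfig-class].
#' @return The selected window size (integer, samples), with the per-size
#'   gate table in attribute `"gate"` (columns `Lw`, `CCC`).
#' @export
selectMinWindow <- function(signal, cfg = searchConfig()) {
  stopifnot(is(signal, "MultichannelSignal"), is(cfg, "SearchConfig"))
  cand <- if (length(cfg@candidateSizes)) cfg@candidateSizes
          else candidateSchedule(samplingRate(signal), nSamples(signal))
  if (any(cand > nSamples(signal)))
    stop("candidate window sizes exceed the signal length")
  tried <- data.frame(Lw = integer(0), CCC = numeric(0))
  for (Lw in cand) {
    fm <- featureMatrix(signal, makeWindows(signal, Lw, cfg@d))
    ccc <- copheneticCorrelation(fm, linkageAverage(fm))
    tried <- rbind(tried, data.frame(Lw = Lw, CCC = ccc))
    if (ccc >= cfg@U - cfg@cccTol) {
      out <- as.integer(Lw)
      attr(out, "gate") <- tried
      return(out)
    }
  }
  stop("no candidate window size reached CCC >= ", cfg@U - cfg@cccTol, ":\n",
       paste(sprintf("  Lw = %d: CCC = %.4f", tried$Lw, tried$CCC),
             collapse = "\n"),
       "\nextend candidateSizes to larger windows")
}

# white-noise event-free prefix, variance matched per channel to the signal's
# opening stretch; used when the event-free initial period is unknown
prefixSignal <- function(signal, maxLw, d) {
  P <- as.integer(maxLw + d)
  ref <- signal@samples[, seq_len(min(maxLw, nSamples(signal))), drop = FALSE]
  sds <- apply(ref, 1L, stats::sd)
  sds[sds == 0] <- 1
  pre <- matrix(stats::rnorm(nrow(ref) * P, sd = rep(sds, times = P)),
                nrow = nrow(ref))
  MultichannelSignal(cbind(pre, signal@samples), fs = signal@fs,
                     channelLabels = signal@channelLabels,
                     tStart = signal@tStart - P / signal@fs)
}

# score one window size: CCC plus S_Dbw over 2..gmax groups, extending the
# group range while the argmin touches the upper boundary
scoreWindowSize <- function(signal, Lw, cfg) {
  ws <- makeWindows(signal, Lw, cfg@d)
  fm <- tryCatch(featureMatrix(signal, ws), error = function(e)
    stop(sprintf("Lw = %d: %s", Lw, conditionMessage(e)), call. = FALSE))
  tree <- linkageAverage(fm)
  ccc <- copheneticCorrelation(fm, tree)
  n <- numWindows(ws)
  gmax <- min(cfg@NG + 1L, n)
  gs <- 2:gmax
  vals <- vapply(gs, function(g)
    sDbw(fm, cutClusters(tree, g), variant = cfg@sdbwVariant), numeric(1L))
  rounds <- 0L
  boundary <- FALSE
  repeat {
    No <- gs[which.min(vals)]
    if (No < gmax || gmax >= n) break
    if (rounds >= cfg@maxExtend) {
      boundary <- TRUE
      break
    }
    newMax <- min(gmax + cfg@NG, n)
    extra <- (gmax + 1L):newMax
    vals <- c(vals, vapply(extra, function(g)
      sDbw(fm, cutClusters(tree, g), variant = cfg@sdbwVariant), numeric(1L)))
    gs <- c(gs, extra)
    gmax <- newMax
    rounds <- rounds + 1L
  }
  list(Lw = as.integer(Lw), CCC = ccc, No = as.integer(No),
       MIn = min(vals), fm = fm, tree = tree, sdbw = vals, groups = gs,
       boundary = boundary)
}

#' Grid search over window sizes and cluster counts
#'
#' Scores the sizes `Lw0 + 0:NL * DL`: for each, the AR feature matrix is
#' clustered once (average linkage) and the tree is cut into `2..NG+1`
#' groups; the minimum S_Dbw over group counts gives that size's `No` and
#' `MIn`, and the size with the smallest `MIn` is the optimum. When an
#' argmin lands on a boundary (group count at `NG+1`, or size at the top of
#' the grid) the grid is automatically extended, up to `maxExtend` rounds;
#' if it still sits on the boundary after the cap, the boundary optimum is
#' accepted with a prominent warning (on cleanly separated data the S_Dbw
#' curve can decay indefinitely with the group count — inspect the
#' `sdbwCurve` slot for the elbow in that case). Ties prefer fewer groups
#' and the smaller window (better temporal precision).
#'
#' If the event-free initial period is unknown (`ipt = NA`), a variance-
#' matched white-noise prefix of `max(Lw) + d` samples is prepended before
#' windowing (and recorded in the result, so event reporting can exclude
#' it); if `ipt` is known, all tested sizes must stay below it.
#'
#' @param signal a [MultichannelSignal-class].
#' @param Lw0 starting window size, normally from [selectMinWindow()].
#' @param cfg a [SearchConfig-class].
#' @return A [ScanResult-class].
#' @export
gridSearch <- function(signal, Lw0, cfg = searchConfig()) {
  stopifnot(is(signal, "MultichannelSignal"), is(cfg, "SearchConfig"))
  Lw0 <- as.integer(Lw0)
  sizes <- Lw0 + 0:cfg@NL * cfg@DL
  cache <- new.env(parent = emptyenv())
  rounds <- 0L
  repeat {
    maxLw <- max(sizes)
    if (!is.na(cfg@ipt)) {
      if (maxLw >= cfg@ipt)
        stop("largest tested window (", maxLw, ") must stay below the ",
             "event-free initial period (ipt = ", cfg@ipt, ")")
      work <- signal
      prefixLen <- 0L
    } else {
      work <- prefixSignal(signal, maxLw, cfg@d)
      prefixLen <- nSamples(work) - nSamples(signal)
    }
    key <- function(Lw) sprintf("%d@%d", Lw, prefixLen)
    res <- lapply(sizes, function(Lw) {
      k <- key(Lw)
      if (is.null(cache[[k]])) cache[[k]] <- scoreWindowSize(work, Lw, cfg)
      cache[[k]]
    })
    mins <- vapply(res, `[[`, numeric(1L), "MIn")
    best <- which.min(mins)          # ties resolve to the smaller Lw
    if (best < length(sizes)) break
    extra <- maxLw + seq_len(cfg@NL) * cfg@DL
    extra <- extra[extra + 2L * cfg@d <= nSamples(signal)]
    if (!is.na(cfg@ipt)) extra <- extra[extra < cfg@ipt]
    if (rounds >= cfg@maxExtend || !length(extra)) {
      warning("optimal window size sits at the top of the size grid (Lw = ",
              sizes[best], ") after ", rounds, " extension round(s); ",
              "accepting the boundary optimum", call. = FALSE)
      break
    }
    sizes <- c(sizes, extra)
    rounds <- rounds + 1L
  }
  atBoundary <- vapply(res, `[[`, logical(1L), "boundary")
  if (any(atBoundary))
    warning("optimal group count sits at the partition boundary for window ",
            "size(s) ",
            paste(vapply(res, `[[`, integer(1L), "Lw")[atBoundary],
                  collapse = ", "),
            " after the capped extensions; the S_Dbw curve decays with the ",
            "group count on this data - inspect sdbwCurve for the elbow",
            call. = FALSE)
  opt <- res[[best]]
  grid <- data.frame(Lw = vapply(res, `[[`, integer(1L), "Lw"),
                     CCC = vapply(res, `[[`, numeric(1L), "CCC"),
                     No = vapply(res, `[[`, integer(1L), "No"),
                     MIn = mins)
  if (opt$CCC < cfg@U - cfg@cccTol)
    warning(sprintf("CCC at the optimal window (%.4f) is below U = %g",
                    opt$CCC, cfg@U))
  new("ScanResult", grid = grid, LwH = opt$Lw, NoH = opt$No, MInH = opt$MIn,
      CCCH = opt$CCC, features = opt$fm, tree = opt$tree,
      labels = cutClusters(opt$tree, opt$No),
      sdbwCurve = data.frame(g = opt$groups, SDbw = opt$sdbw),
      prefixLength = as.integer(prefixLen),
      fs = samplingRate(signal), d = cfg@d)
}

#' Final clustering at the optimal window size and group count
#'
#' Cuts the optimal-size dendrogram into the optimal number of groups; labels
#' are numbered by first appearance along the time axis.
#'
#' @param scan a [ScanResult-class].
#' @return Integer label vector, one per interval.
#' @export
classifyOptimal <- function(scan) {
  stopifnot(is(scan, "ScanResult"))
  cutClusters(scan@tree, scan@NoH)
}

#' Incrementally classify new intervals against a reference clustering
#'
#' Appends a batch of new interval feature rows (computed with the reference
#' window size and slide) to the reference dataset, then compares the S_Dbw
#' index at successive group counts `No, No+1, ...` and stops at the first
#' count whose index is smaller than the next one's. The tree is cut at that
#' count: new rows falling in clusters that contain reference rows inherit
#' the majority reference label; new rows forming reference-free clusters
#' are flagged as new event types (and are the ones worth retaining in the
#' reference dataset).
#'
#' @param scan the reference [ScanResult-class].
#' @param newFeatures numeric matrix (or [FeatureMatrix-class]) of new rows
#'   with the same feature dimension as the reference.
#' @param maxExtra how far past the reference group count to scan before
#'   giving up (default 5).
#' @param variant S_Dbw threshold convention, see [sDbw()].
#' @return A list: `labels` (per new row; inherited reference label or a new
#'   label past the reference range), `isNew` (logical per new row),
#'   `k` (group count used), `IndN` (the S_Dbw values scanned).
#' @export
incrementalClassify <- function(scan, newFeatures, maxExtra = 5L,
                                variant = c("printed", "rootMean")) {
  stopifnot(is(scan, "ScanResult"))
  variant <- match.arg(variant)
  newRows <- featureRows(newFeatures)
  ref <- scan@features@values
  if (ncol(newRows) != ncol(ref))
    stop("feature dimension mismatch: reference has ", ncol(ref),
         " columns, new rows have ", ncol(newRows))
  nRef <- nrow(ref)
  ds2 <- rbind(ref, newRows)
  tree <- linkageAverage(ds2)
  No <- scan@NoH
  idx <- function(g) sDbw(ds2, cutClusters(tree, g), variant = variant)
  gTop <- min(No + maxExtra + 1L, nrow(ds2))
  vals <- vapply(No:gTop, function(g) idx(g), numeric(1L))
  names(vals) <- No:gTop
  kStar <- NA_integer_
  for (i in seq_len(length(vals) - 1L)) {
    if (vals[i] < vals[i + 1L]) { kStar <- No + i - 1L; break }
  }
  if (is.na(kStar))
    stop("S_Dbw still decreasing at ", gTop, " groups; raise maxExtra")
  lab2 <- cutClusters(tree, kStar)
  refLab <- scan@labels
  newLab <- integer(nrow(newRows))
  isNew <- logical(nrow(newRows))
  nextNew <- max(refLab)
  for (cl in unique(lab2)) {
    members <- which(lab2 == cl)
    refMembers <- members[members <= nRef]
    newMembers <- members[members > nRef] - nRef
    if (!length(newMembers)) next
    if (length(refMembers)) {
      tab <- table(refLab[refMembers])
      newLab[newMembers] <- as.integer(names(tab)[which.max(tab)])
    } else {
      nextNew <- nextNew + 1L
      newLab[newMembers] <- nextNew
      isNew[newMembers] <- TRUE
    }
  }
  list(labels = newLab, isNew = isNew, k = kStar, IndN = vals)
}

#' Run the full detection pipeline
#'
#' Convenience wrapper: CCC-gated minimum window ([selectMinWindow()]), grid
#' search ([gridSearch()]), optimal classification, consecutive-run grouping
#' and event localization.
#'
#' @param signal a [MultichannelSignal-class].
#' @param cfg a [SearchConfig-class].
#' @param M localization constant (default 6/7; see [localizeRun()]).
#' @param baselineLabel group treated as event-free background; default the
#'   most populous group.
#' @return A list with elements `scan` (a [ScanResult-class]) and `events`
#'   (an [EventSequence-class]).
#' @export
detectEvents <- function(signal, cfg = searchConfig(), M = 6 / 7,
                         baselineLabel = NULL) {
  Lw0 <- selectMinWindow(signal, cfg)
  scan <- gridSearch(signal, Lw0, cfg)
  labels <- classifyOptimal(scan)
  runs <- groupConsecutive(labels)
  events <- buildSequence(runs, d = scan@d, Lw = scan@LwH,
                          fs = samplingRate(signal),
                          baselineLabel = baselineLabel, M = M,
                          prefixLength = scan@prefixLength,
                          tStart = signal@tStart)
  list(scan = scan, events = events)
}
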