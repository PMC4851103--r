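# From interval labels to a localized temporal event sequence.

#' Group consecutive same-label intervals into runs
#'
#' @param labels label vector over the IN intervals, in temporal order.
#' @return data.frame with one row per maximal run: `label`, `i`, `j`
#'   (1-based first and last interval). Every interval belongs to exactly
#'   one run.
#' @export
groupConsecutive <- function(labels) {
  if (!length(labels)) stop("need at least one interval")
  r <- rle(as.vector(labels))
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, i = ends - r$lengths + 1L, j = ends)
}

#' Localize an interval run on the signal
#'
#' A run of intervals `i..j` (windows of `Lw` samples advanced by `d`)
#' occupies the sample span
#' `[(i-1)*d + M*Lw - d/2, (j-1)*d + M*Lw + d/2]`,
#' so each interval contributes exactly `d` samples and adjacent runs abut
#' without overlap. The anchor constant `M = 6/7` places the span around the
#' late part of the window, which marks event onsets more accurately than
#' the window midpoint. Fractional sample positions are preserved.
#'
#' @param i,j 1-based first and last interval numbers (vectors allowed).
#' @param d slide width in samples.
#' @param Lw window size in samples.
#' @param M anchor constant, default 6/7.
#' @return A 2-column matrix with columns `start`, `end` (samples, 0-based,
#'   possibly fractional); `end - start == (j - i + 1) * d`.
#' @examples
#' localizeRun(1447, 1449, d = 32, Lw = 155)
#' @export
localizeRun <- function(i, j, d, Lw, M = 6 / 7) {
  if (any(i > j)) stop("need i <= j")
  if (any(i < 1L)) stop("interval numbers are 1-based")
  if (d <= 0 || Lw <= 0) stop("d and Lw must be positive")
  cbind(start = (i - 1) * d + M * Lw - d / 2,
        end = (j - 1) * d + M * Lw + d / 2)
}

#' Build the temporal event sequence from labeled runs
#'
#' Localizes every run with [localizeRun()] and expresses it in seconds.
#' Runs of the baseline group (by default the most populous one — the
#' event-free background) are kept apart as portions without events. When a
#' synthetic event-free prefix was prepended during the scan, spans are
#' shifted back to real-signal coordinates, runs entirely inside the prefix
#' are dropped and spans reaching into it are clipped at sample 0.
#'
#' @param runs data.frame from [groupConsecutive()].
#' @param d slide width (samples).
#' @param Lw window size (samples).
#' @param fs sampling rate (Hz).
#' @param baselineLabel baseline group; `NULL` picks the label covering the
#'   most intervals.
#' @param M anchor constant, see [localizeRun()].
#' @param prefixLength samples of synthetic prefix to subtract (default 0).
#' @param tStart time of real-signal sample 0 in seconds.
#' @return An [EventSequence-class].
#' @export
buildSequence <- function(runs, d, Lw, fs, baselineLabel = NULL, M = 6 / 7,
                          prefixLength = 0L, tStart = 0) {
  stopifnot(is.data.frame(runs), all(c("label", "i", "j") %in% names(runs)))
  if (is.null(baselineLabel)) {
    cover <- tapply(runs$j - runs$i + 1L, runs$label, sum)
    baselineLabel <- names(cover)[which.max(cover)]
  }
  span <- localizeRun(runs$i, runs$j, d = d, Lw = Lw, M = M)
  start <- span[, "start"] - prefixLength
  end <- span[, "end"] - prefixLength
  keep <- end > 0
  start <- pmax(start, 0)

  mk <- function(sel) {
    df <- data.frame(label = as.integer(as.character(runs$label[sel])),
                     i = runs$i[sel], j = runs$j[sel],
                     startSample = start[sel], endSample = end[sel],
                     tE = tStart + start[sel] / fs,
                     dE = (end[sel] - start[sel]) / fs,
                     endSec = tStart + end[sel] / fs)
    rownames(df) <- NULL
    df
  }
  isBase <- as.character(runs$label) == as.character(baselineLabel)
  new("EventSequence",
      states = mk(keep & !isBase), pwa = mk(keep & isBase),
      baselineLabel = as.integer(as.character(baselineLabel)),
      fs = as.numeric(fs), d = as.integer(d), Lw = as.integer(Lw),
      M = M, nIntervals = as.integer(sum(runs$j - runs$i + 1L)))
}

#' Truncate seconds for display
#'
#' Durations are displayed truncated (not rounded) to two decimals, e.g.
#' 0.375 s prints as 0.37 s; machine-readable output keeps full precision.
#'
#' @param x numeric vector of non-negative durations (seconds).
#' @param digits decimals kept (default 2).
#' @return Truncated values.
#' @export
truncateSeconds <- function(x, digits = 2L) {
  f <- 10^digits
  floor(x * f) / f
}

#' Per-event-type statistics and cluster count of a span
#'
#' Counts occurrences and durations per event label, and the number of
#' distinct groups present (baseline included) — the number of independent
#' components a downstream ICA would need for that span. An empty sequence
#' has `nic = 1` (baseline only).
#'
#' @param x an [EventSequence-class].
#' @param from,to optional span bounds in seconds; default the whole
#'   recording. An event counts if its `[tE, tE + dE]` intersects the span.
#' @return A list: `perLabel` (data.frame with `label`, `count`,
#'   `totalDuration`, `meanDuration`) and `nic`.
#' @export
setMethod("eventStats", "EventSequence", function(x, from = -Inf, to = Inf) {
  st <- x@states
  inSpan <- function(df) df$tE <= to & (df$tE + df$dE) >= from
  st <- st[nrow(st) > 0 & inSpan(st), , drop = FALSE]
  if (nrow(st)) {
    agg <- do.call(rbind, lapply(split(st, st$label), function(g)
      data.frame(label = g$label[1L], count = nrow(g),
                 totalDuration = sum(g$dE), meanDuration = mean(g$dE))))
    agg <- agg[order(agg$label), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(label = integer(0), count = integer(0),
                      totalDuration = numeric(0), meanDuration = numeric(0))
  }
  pw <- x@pwa
  baseIn <- nrow(pw) == 0L || any(inSpan(pw))
  list(perLabel = agg, nic = nrow(agg) + as.integer(baseIn))
})
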