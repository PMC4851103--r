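# Synthetic multichannel signals with planted AR(2) event regimes and
# ground-truth labels. The generator is the package's test bed: every other
# module can be exercised against known truth without any external recording.

#' Specify an AR(2) regime
#'
#' @param label regime name.
#' @param ar AR coefficients `(a1, a2)`; must satisfy the stationarity
#'   triangle `|a2| < 1`, `a1 + a2 < 1`, `a2 - a1 < 1`.
#' @param gain amplitude multiplier (irrelevant to AR features, which are
#'   scale-invariant, but visible in the waveform and in additive mode).
#' @param duration event duration in samples (ignored for the baseline).
#' @param occurrences how many times the event is planted.
#' @return A [RegimeSpec-class].
#' @examples
#' regimeSpec("blink", ar = c(1.7, -0.72), duration = 640)
#' @export
regimeSpec <- function(label, ar, gain = 1, duration = 0L, occurrences = 1L) {
  new("RegimeSpec", label = as.character(label), ar = as.numeric(ar),
      gain = as.numeric(gain), duration = as.integer(duration),
      occurrences = as.integer(occurrences))
}

simAR <- function(ar, n, sd) {
  as.numeric(stats::arima.sim(model = list(ar = ar), n = n, sd = sd))
}

#' Generate a multichannel signal with planted event regimes
#'
#' Every channel follows the baseline AR(2) process; event occurrences are
#' placed (identically across channels, emulating the cross-channel
#' correlation of real event timing) with an event-free prefix of at least
#' `minGap` samples first and gaps of at least `minGap` between events. In
#' `"replace"` mode (default) the event segment's samples are an independent
#' realization of the event regime, so window features are cleanly
#' regime-determined; in `"additive"` mode the event realization is added on
#' top of the baseline, closer to how real EEG artifacts superimpose on
#' brain activity and deliberately harder to detect.
#'
#' Runs with the same seed are bit-reproducible. Passing explicit
#' `eventStarts` fixes the event skeleton so that different seeds vary only
#' the sample paths.
#'
#' @param baseline a [RegimeSpec-class] for the event-free background.
#' @param events list of [RegimeSpec-class] event regimes.
#' @param Q number of channels.
#' @param T total length in samples.
#' @param fs sampling rate in Hz.
#' @param noiseSd innovation standard deviation.
#' @param minGap minimum event-free stretch before and between events, in
#'   samples; default `2 * fs` (twice a one-second window, so events stay
#'   resolvable by any window the default search schedule can pick).
#' @param seed integer seed; required, for reproducibility.
#' @param mode `"replace"` or `"additive"`.
#' @param eventStarts optional integer vector of 0-based start samples, one
#'   per planted occurrence (ordered), overriding random placement.
#' @return A list with elements `signal` ([MultichannelSignal-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
generateSignal <- function(baseline, events = list(), Q = 4L, T, fs = 256,
                           noiseSd = 1, minGap = NULL, seed,
                           mode = c("replace", "additive"),
                           eventStarts = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(baseline, "RegimeSpec"))
  for (ev in events) stopifnot(is(ev, "RegimeSpec"))
  T <- as.integer(T)
  if (is.null(minGap)) minGap <- 2L * round(fs)
  minGap <- as.integer(minGap)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  occ <- do.call(rbind, lapply(events, function(ev) {
    if (ev@occurrences == 0L) return(NULL)
    data.frame(label = ev@label, duration = ev@duration,
               spec = I(replicate(ev@occurrences, ev, simplify = FALSE)))
  }))
  nEv <- if (is.null(occ)) 0L else nrow(occ)

  if (nEv > 0L) {
    if (is.null(eventStarts)) {
      occ <- occ[sample.int(nEv), , drop = FALSE]
      slack <- T - sum(occ$duration) - (nEv + 1L) * minGap
      if (slack < 0L)
        stop("overcrowded timeline: events plus minimum gaps exceed T")
      pad <- as.integer(stats::rmultinom(1L, slack, rep(1, nEv + 1L)))
      starts <- integer(nEv)
      pos <- 0L
      for (e in seq_len(nEv)) {
        pos <- pos + minGap + pad[e]
        starts[e] <- pos
        pos <- pos + occ$duration[e]
      }
    } else {
      if (length(eventStarts) != nEv)
        stop("eventStarts must have one entry per planted occurrence")
      ord <- order(eventStarts)
      occ <- occ[ord, , drop = FALSE]
      starts <- as.integer(sort(eventStarts))
      if (starts[1L] < minGap)
        stop("an event-free prefix of at least minGap samples is required")
      ends <- starts + occ$duration
      if (any(starts[-1L] < ends[-nEv]) || ends[nEv] > T)
        stop("events overlap or overrun the signal")
    }
  } else starts <- integer(0)

  samples <- matrix(NA_real_, nrow = Q, ncol = T)
  for (q in seq_len(Q)) {
    ch <- simAR(baseline@ar, T, noiseSd) * baseline@gain
    if (nEv > 0L) for (e in seq_len(nEv)) {
      ev <- occ$spec[[e]]
      idx <- (starts[e] + 1L):(starts[e] + ev@duration)
      seg <- simAR(ev@ar, ev@duration, noiseSd) * ev@gain
      ch[idx] <- if (mode == "replace") seg else ch[idx] + seg
    }
    samples[q, ] <- ch
  }

  sampleLabels <- rep(baseline@label, T)
  evdf <- data.frame(label = character(0), start = integer(0),
                     end = integer(0))
  if (nEv > 0L) {
    for (e in seq_len(nEv))
      sampleLabels[(starts[e] + 1L):(starts[e] + occ$duration[e])] <-
        occ$label[e]
    evdf <- data.frame(label = occ$label, start = starts,
                       end = starts + occ$duration)
  }
  list(signal = MultichannelSignal(samples, fs = fs),
       truth = new("GroundTruth", sampleLabels = sampleLabels,
                   events = evdf))
}

#' Majority ground-truth label per window
#'
#' For each window of a [WindowSet-class], the regime occupying the most
#' samples of the window (ties go to the regime encountered first within the
#' window).
#'
#' @param x a [GroundTruth-class].
#' @param windows a [WindowSet-class] over the same signal.
#' @return Character vector of one regime label per window.
#' @aliases intervalLabels,GroundTruth-method
#' @export
setMethod("intervalLabels", "GroundTruth", function(x, windows) {
  stopifnot(is(windows, "WindowSet"))
  if (windows@T != length(x@sampleLabels))
    stop("window set was built for a different signal length")
  vapply(seq_len(numWindows(windows)), function(i) {
    lab <- x@sampleLabels[(windows@starts[i] + 1L):
                          (windows@starts[i] + windows@Lw)]
    tab <- table(factor(lab, levels = unique(lab)))
    names(tab)[which.max(tab)]
  }, "")
})
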