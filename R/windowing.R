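# Sliding windows and per-window AR feature extraction.

#' Build the sliding-window set
#'
#' Places windows of `Lw` samples every `d` samples from the start of the
#' signal; a trailing partial window is discarded, so the number of windows
#' is `floor((T - Lw)/d) + 1`.
#'
#' @param signal a [MultichannelSignal-class] (only its length is used).
#' @param Lw window length in samples (4 <= Lw <= T).
#' @param d slide width in samples (>= 1).
#' @return A [WindowSet-class].
#' @examples
#' sig <- MultichannelSignal(matrix(rnorm(2 * 1000), nrow = 2), fs = 256)
#' numWindows(makeWindows(sig, Lw = 128, d = 32))
#' @export
makeWindows <- function(signal, Lw, d) {
  stopifnot(is(signal, "MultichannelSignal"))
  Lw <- as.integer(Lw); d <- as.integer(d)
  T <- nSamples(signal)
  if (Lw > T) stop("window exceeds signal: Lw = ", Lw, " > T = ", T)
  if (Lw < 4L) stop("Lw must be >= 4 samples")
  if (d < 1L) stop("d must be >= 1 sample")
  IN <- (T - Lw) %/% d + 1L
  new("WindowSet", Lw = Lw, d = d, starts = (seq_len(IN) - 1L) * d,
      T = as.integer(T))
}

#' Burg autoregressive coefficient estimate
#'
#' Order-p Burg (forward-backward, reflection-coefficient) estimate of the
#' AR coefficients of a single demeaned series, in the convention
#' `x_t = a1 x_(t-1) + ... + ap x_(t-p) + e_t` (coefficients on the
#' right-hand side, matching `stats::ar.burg`'s `$ar`).
#'
#' @param x numeric vector of at least `2 * order` samples.
#' @param order AR model order (default 2, the feature used by the detector).
#' @return Numeric vector of `order` coefficients.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = c(1.0, -0.5)), n = 2048))
#' burgAR(x)
#' @export
burgAR <- function(x, order = 2L) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  N <- length(x)
  if (N < 2L * order) stop("need at least 2*order samples")
  x <- x - mean(x)
  if (sum(x * x) == 0) stop("degenerate window: zero variance")
  f <- x[2:N]
  b <- x[1:(N - 1L)]
  a <- numeric(0)
  for (m in seq_len(order)) {
    den <- sum(f * f) + sum(b * b)
    if (den == 0) stop("degenerate window: prediction error vanished")
    k <- -2 * sum(f * b) / den
    a <- c(a + k * rev(a), k)
    fn <- f + k * b
    bn <- b + k * f
    f <- fn[-1L]
    b <- bn[-length(bn)]
  }
  -a
}

#' Per-window, per-channel AR feature matrix
#'
#' For every window and every channel, the window's samples are summarized by
#' their Burg AR coefficients ([burgAR()]); the per-channel vectors are
#' concatenated channel-major (`ch1:a1, ch1:a2, ch2:a1, ...`) into one row
#' per window. AR coefficients are scale- and location-invariant, so channel
#' gains and offsets do not affect the features.
#'
#' @param signal a [MultichannelSignal-class].
#' @param windows a [WindowSet-class] built for the same signal length.
#' @param order AR order per channel (default 2).
#' @return A [FeatureMatrix-class] of size `IN x (Q * order)`.
#' @export
featureMatrix <- function(signal, windows, order = 2L) {
  stopifnot(is(signal, "MultichannelSignal"), is(windows, "WindowSet"))
  order <- as.integer(order)
  if (windows@T != nSamples(signal))
    stop("window set was built for a signal of length ", windows@T,
         ", not ", nSamples(signal))
  Q <- nChannels(signal)
  IN <- numWindows(windows)
  vals <- matrix(NA_real_, nrow = IN, ncol = Q * order)
  m <- signal@samples
  starts <- windows@starts
  Lw <- windows@Lw
  for (i in seq_len(IN)) {
    idx <- (starts[i] + 1L):(starts[i] + Lw)
    for (q in seq_len(Q)) {
      co <- tryCatch(burgAR(m[q, idx], order = order), error = function(e)
        stop(sprintf("window %d, channel %s: %s", i,
                     signal@channelLabels[q], conditionMessage(e)),
             call. = FALSE))
      vals[i, ((q - 1L) * order + 1L):(q * order)] <- co
    }
  }
  colnames(vals) <- paste0(rep(signal@channelLabels, each = order), ":a",
                           rep(seq_len(order), Q))
  new("FeatureMatrix", values = vals, windowSet = windows,
      channelLabels = signal@channelLabels, order = order)
}
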