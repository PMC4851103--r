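# Display-only principal-component projection of window features.
#
# The detector always clusters the full feature space; the projection exists
# to draw and compare classifications, never to feed clustering.

#' Principal-component projection of a feature matrix
#'
#' Stores the windows as columns of `O = t(FV)` (features x windows),
#' centers them, and eigendecomposes the population covariance
#' `C = (1/n) O Ot`. The kept components are the top eigenvectors, each with
#' its sign fixed so that its largest-magnitude loading is positive
#' (deterministic output); the coordinates are the projections of the
#' centered columns.
#'
#' @param x a [FeatureMatrix-class] or numeric matrix (rows = windows).
#' @param nComponents number of components kept (default 2).
#' @return A [Projection2D-class].
#' @export
pcaProject <- function(x, nComponents = 2L) {
  v <- featureRows(x)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 windows")
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > min(ncol(v), n))
    stop("nComponents must be between 1 and min(features, windows)")
  O <- t(v)
  Oc <- O - rowMeans(O)
  C <- Oc %*% t(Oc) / n
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (sum(vals) == 0) stop("zero-variance data: projection undefined")
  A <- t(e$vectors)
  for (r in seq_len(nrow(A))) {
    if (A[r, which.max(abs(A[r, ]))] < 0) A[r, ] <- -A[r, ]
  }
  A <- A[seq_len(nComponents), , drop = FALSE]
  new("Projection2D",
      coordinates = A %*% Oc,
      explainedFraction = min(1, sum(vals[seq_len(nComponents)]) / sum(vals)),
      rotation = A,
      eigenvalues = vals)
}

#' Scatter plot of projected windows colored by group
#'
#' @param proj a [Projection2D-class] from [pcaProject()].
#' @param labels optional group label per window (colors/symbols).
#' @param ... passed to [graphics::plot()].
#' @return `proj`, invisibly.
#' @export
plotProjection <- function(proj, labels = NULL, ...) {
  stopifnot(is(proj, "Projection2D"))
  xy <- t(proj@coordinates[1:2, , drop = FALSE])
  col <- if (is.null(labels)) 1L else as.integer(factor(labels))
  graphics::plot(xy, col = col, pch = if (is.null(labels)) 1L
                 else (col - 1L) %% 25L + 1L,
                 xlab = "PC1", ylab = "PC2",
                 main = sprintf("%.0f%% of variance",
                                100 * proj@explainedFraction), ...)
  invisible(proj)
}
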