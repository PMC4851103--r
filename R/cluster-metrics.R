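# Hierarchical clustering, cophenetic correlation, the S_Dbw validity index
# and normalized mutual information.

featureRows <- function(x) {
  if (is(x, "FeatureMatrix")) x@values else as.matrix(x)
}

#' Average-linkage (UPGMA) tree of window features
#'
#' Agglomerative hierarchical clustering of the feature rows with Euclidean
#' point-to-point distances and average linkage (mean pairwise distance
#' between clusters).
#'
#' @param x a [FeatureMatrix-class] or a plain numeric matrix (rows = objects).
#' @return An object of class `stats::hclust`.
#' @export
linkageAverage <- function(x) {
  v <- featureRows(x)
  if (nrow(v) < 2L) stop("need at least 2 rows to cluster")
  stats::hclust(stats::dist(v), method = "average")
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise Euclidean distances of
#' the rows and the cophenetic distances of the tree (the merge height at
#' which each pair first joins). Values near 1 mean the dendrogram preserves
#' the original distances faithfully; the detector uses this to gate the
#' minimum usable window size.
#'
#' @param x the data the tree was built from ([FeatureMatrix-class] or matrix).
#' @param tree the `hclust` tree from [linkageAverage()].
#' @return A single number in [-1, 1].
#' @export
copheneticCorrelation <- function(x, tree) {
  v <- featureRows(x)
  if (nrow(v) < 3L) stop("CCC needs at least 3 objects")
  d <- stats::dist(v)
  t <- stats::cophenetic(tree)
  if (stats::sd(d) == 0 || stats::sd(t) == 0)
    stop("CCC undefined: zero variance in a distance vector")
  stats::cor(as.numeric(d), as.numeric(t))
}

#' Cut a tree into k groups
#'
#' Removes the k-1 highest links and returns integer group labels renumbered
#' in order of first appearance along the object (time) axis, so group 1 is
#' always the group of the first window.
#'
#' @param tree an `hclust` tree.
#' @param k number of groups, `1 <= k <= n`.
#' @return Integer vector of labels in `1..k`.
#' @export
cutClusters <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must be between 1 and the number of objects")
  cl <- stats::cutree(tree, k = k)
  as.integer(match(cl, unique(cl)))
}

# population (1/n) per-dimension variance of a row subset
.popVar <- function(m) {
  mu <- colMeans(m)
  colSums((m - rep(mu, each = nrow(m)))^2) / nrow(m)
}

#' S_Dbw cluster validity index
#'
#' Sum of the average intra-cluster scattering and the inter-cluster density:
#' `S_Dbw(k) = Scat(k) + Dens_bw(k)`. `Scat` averages `||sigma(G_i)|| /
#' ||sigma(DS)||` over clusters, where `sigma(.)` is the per-dimension
#' (population) variance vector and `||.||` its Euclidean norm. `Dens_bw`
#' counts, for every ordered cluster pair, the points of the two clusters
#' within a threshold distance of the midpoint of their centers, relative to
#' the denser of the two clusters around its own center. Lower is better.
#'
#' The counting threshold is `(1/k) * sqrt(sum_i ||sigma(G_i)||)`
#' (`variant = "printed"`). `variant = "rootMean"` instead uses
#' `sqrt(mean_i ||sigma(G_i)||)`, the form found in parts of the S_Dbw
#' literature. A pair whose two clusters both have zero own-density
#' contributes 0.
#'
#' @param x a [FeatureMatrix-class] or numeric matrix (rows = objects).
#' @param labels integer cluster labels `1..k`, every group non-empty.
#' @param variant threshold convention, `"printed"` (default) or
#'   `"rootMean"`.
#' @return A single non-negative number.
#' @export
sDbw <- function(x, labels, variant = c("printed", "rootMean")) {
  variant <- match.arg(variant)
  v <- featureRows(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(v)) stop("one label per row is required")
  k <- max(labels)
  if (k < 2L) stop("S_Dbw needs at least 2 clusters")
  if (!setequal(unique(labels), seq_len(k)))
    stop("labels must cover 1..k with no empty group")

  groups <- split(seq_len(nrow(v)), labels)
  centers <- t(vapply(groups, function(idx)
    colMeans(v[idx, , drop = FALSE]), numeric(ncol(v))))
  sigNorm <- vapply(groups, function(idx)
    sqrt(sum(.popVar(v[idx, , drop = FALSE])^2)), numeric(1L))
  dsNorm <- sqrt(sum(.popVar(v)^2))
  if (dsNorm == 0) stop("degenerate dataset: zero variance")
  scat <- mean(sigNorm) / dsNorm

  thr <- if (variant == "printed") sqrt(sum(sigNorm)) / k
         else sqrt(mean(sigNorm))

  countNear <- function(idx, mu) {
    pts <- v[idx, , drop = FALSE]
    dd <- sqrt(rowSums((pts - rep(mu, each = nrow(pts)))^2))
    sum(dd <= thr)
  }
  own <- vapply(seq_len(k), function(i) countNear(groups[[i]], centers[i, ]),
                numeric(1L))
  dens <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      mx <- max(own[i], own[j])
      if (mx == 0) next       # both ultra-tight: vacuously separated
      mid <- (centers[i, ] + centers[j, ]) / 2
      uij <- countNear(c(groups[[i]], groups[[j]]), mid)
      dens <- dens + uij / mx
    }
  }
  scat + dens / (k * (k - 1))
}

#' Normalized mutual information of two labelings
#'
#' Mutual information of the label contingency table normalized by the
#' geometric mean of the two label entropies. 1 means identical partitions
#' (up to relabeling); if either labeling is constant (zero entropy) the
#' value is defined as 0.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in [0, 1].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  n <- length(a)
  if (n == 0L) stop("empty labelings")
  tab <- table(a, b)
  pij <- tab / n
  pi <- rowSums(pij)
  pj <- colSums(pij)
  hi <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (hi == 0 || hj == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  min(1, mi / sqrt(hi * hj))
}
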