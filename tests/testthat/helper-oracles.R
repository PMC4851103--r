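# Independent, deliberately naive reference implementations used as oracles.
# These must stay loop-based and structurally different from the package code.

# S_Dbw evaluated term by term with explicit loops; returns the components too
sdbwOracle <- function(x, labels, variant = "printed") {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  k <- max(labels)
  popVarVec <- function(rows) {
    out <- numeric(p)
    for (j in seq_len(p)) {
      mu <- mean(x[rows, j])
      s <- 0
      for (r in rows) s <- s + (x[r, j] - mu)^2
      out[j] <- s / length(rows)
    }
    out
  }
  normVec <- function(v) sqrt(sum(v^2))
  sigNorm <- numeric(k)
  centers <- matrix(0, k, p)
  for (ci in seq_len(k)) {
    rows <- which(labels == ci)
    sigNorm[ci] <- normVec(popVarVec(rows))
    for (j in seq_len(p)) centers[ci, j] <- mean(x[rows, j])
  }
  dsNorm <- normVec(popVarVec(seq_len(n)))
  scat <- 0
  for (ci in seq_len(k)) scat <- scat + sigNorm[ci] / dsNorm
  scat <- scat / k
  thr <- if (variant == "printed") (1 / k) * sqrt(sum(sigNorm))
         else sqrt(mean(sigNorm))
  f <- function(row, mu) {
    dd <- 0
    for (j in seq_len(p)) dd <- dd + (x[row, j] - mu[j])^2
    if (sqrt(dd) > thr) 0 else 1
  }
  density <- function(rows, mu) {
    s <- 0
    for (r in rows) s <- s + f(r, mu)
    s
  }
  dens <- 0
  for (ci in seq_len(k)) {
    for (cj in seq_len(k)) {
      if (ci == cj) next
      di <- density(which(labels == ci), centers[ci, ])
      dj <- density(which(labels == cj), centers[cj, ])
      if (max(di, dj) == 0) next
      mid <- (centers[ci, ] + centers[cj, ]) / 2
      dij <- density(which(labels %in% c(ci, cj)), mid)
      dens <- dens + dij / max(di, dj)
    }
  }
  dens <- dens / (k * (k - 1))
  list(value = scat + dens, scat = scat, dens = dens)
}

# Pearson correlation of original vs cophenetic distances, from first
# principles over the object pairs
cccOracle <- function(x, tree) {
  x <- as.matrix(x)
  n <- nrow(x)
  tmat <- as.matrix(stats::cophenetic(tree))
  xs <- ts <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xs <- c(xs, sqrt(sum((x[i, ] - x[j, ])^2)))
      ts <- c(ts, tmat[i, j])
    }
  }
  xb <- mean(xs)
  tb <- mean(ts)
  sum((xs - xb) * (ts - tb)) /
    sqrt(sum((xs - xb)^2) * sum((ts - tb)^2))
}

# geometric-mean NMI from a contingency table built by explicit counting
nmiOracle <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n <- length(a)
  cont <- matrix(0, length(ua), length(ub))
  for (i in seq_len(n))
    cont[match(a[i], ua), match(b[i], ub)] <-
      cont[match(a[i], ua), match(b[i], ub)] + 1
  pa <- rowSums(cont) / n
  pb <- colSums(cont) / n
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (i in seq_along(ua)) {
    for (j in seq_along(ub)) {
      pij <- cont[i, j] / n
      if (pij > 0) mi <- mi + pij * log(pij / (pa[i] * pb[j]))
    }
  }
  mi / sqrt(ha * hb)
}

# place windows one by one until the next would overrun the signal
windowCountOracle <- function(T, Lw, d) {
  count <- 0L
  start <- 0
  while (start + Lw <= T) {
    count <- count + 1L
    start <- start + d
  }
  count
}

# Yule-Walker solution from the *true* autocovariance of an AR(2) process:
# rho1 = a1/(1-a2), rho2 = a2 + a1*rho1; solving the YW system returns
# exactly (a1, a2), the oracle target for Burg estimates
yuleWalkerTruth <- function(a1, a2) {
  rho1 <- a1 / (1 - a2)
  rho2 <- a2 + a1 * rho1
  R <- matrix(c(1, rho1, rho1, 1), 2, 2)
  as.numeric(solve(R, c(rho1, rho2)))
}
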