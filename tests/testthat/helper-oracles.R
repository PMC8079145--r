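## Independent oracles used to cross-check the package implementations.
## They deliberately take the slow, obvious route.

## e^{-x} (I0(x) + I1(x)) via the integral representation
## I_n(x) = (1/pi) int_0^pi e^{x cos(theta)} cos(n theta) d(theta),
## evaluated with adaptive quadrature on the scaled integrand.
besselScaledSumOracle <- function(x) {
  ## split at the width of the large-x Gaussian peak near theta = 0 so the
  ## quadrature resolves it at any argument
  cut <- min(pi / 2, 20 / sqrt(max(x, 1)))
  quad <- function(f)
    stats::integrate(f, 0, cut, rel.tol = 1e-13, abs.tol = 1e-15,
                     subdivisions = 5000L)$value +
    stats::integrate(f, cut, pi, rel.tol = 1e-13, abs.tol = 1e-15,
                     subdivisions = 5000L)$value
  i0 <- quad(function(th) exp(x * (cos(th) - 1)))
  i1 <- quad(function(th) exp(x * (cos(th) - 1)) * cos(th))
  (i0 + i1) / pi
}

## Brute-force DBSCAN on the full distance matrix: BFS over core points in
## increasing index order, border points to the lowest-index core neighbour.
bruteDbscan <- function(x, y, eps, minPts) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  isCore <- lengths(nb) >= minPts
  labels <- integer(n)
  cid <- 0L
  for (i in which(isCore)) {
    if (labels[i] == 0L) {
      cid <- cid + 1L
      queue <- i
      labels[i] <- cid
      while (length(queue)) {
        j <- queue[1]
        queue <- queue[-1]
        nxt <- nb[[j]][isCore[nb[[j]]] & labels[nb[[j]]] == 0L]
        labels[nxt] <- cid
        queue <- c(queue, nxt)
      }
    }
  }
  for (i in which(!isCore)) {
    cn <- nb[[i]][isCore[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

## Brute-force nearest-neighbour distances with cutoff.
bruteNN <- function(from, to, cutoff, self = FALSE) {
  out <- numeric(0)
  for (i in seq_len(nrow(from))) {
    d <- sqrt((to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2)
    if (self) d <- d[-i]
    m <- min(d)
    if (m <= cutoff) out <- c(out, m)
  }
  out
}

## Brute-force circular-ROI mean over a frame (pixel-center membership,
## explicit double loop).
bruteRoiMean <- function(frame, cx, cy, r) {
  acc <- c()
  for (i in seq_len(nrow(frame)))
    for (j in seq_len(ncol(frame)))
      if ((j - cx)^2 + (i - cy)^2 <= r^2) acc <- c(acc, frame[i, j])
  mean(acc)
}

## Distances drawn from the lambda = 67 Poisson null by inverse transform.
.sampleNullOracle <- function(n) {
  set.seed(123)
  sqrt(-log(stats::runif(n)) / (67 * pi)) * 1000
}

## LocalizationMap from a coordinate matrix (nm).
mkMap <- function(pts, area, channel = "chan1") {
  new("LocalizationMap", x = pts[, 1], y = pts[, 2],
      channel = factor(rep(channel, nrow(pts))), fieldArea = area)
}

## Dense blob of n points inside a disk of the given radius (nm).
mkBlob <- function(n, cx, cy, radius, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(cx + r * cos(a), cy + r * sin(a))
}

## Build a NormalizedTrace from post-bleach samples, with a flat baseline.
mkNormTrace <- function(t, f, nBaseline = 40L) {
  dt <- stats::median(diff(t))
  pre <- t[1] - dt * (nBaseline:1)
  memFRAP:::newNormalizedTrace(
    t = c(pre, t), f = c(rep(1, nBaseline), f),
    nBaseline = nBaseline, source = "helper")
}

## Build a simple raw trace set with unit reference and zero background.
mkRawTrace <- function(fBleach, bleachEnd, dt = 1,
                       background = 0, reference = 1) {
  n <- length(fBleach)
  memFRAP:::newRoiTraceSet(
    time = dt * (seq_len(n) - 1),
    bleach = fBleach,
    background = rep_len(background, n),
    reference = rep_len(reference, n),
    bleachEnd = bleachEnd)
}
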