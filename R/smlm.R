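## Grid-binned fixed-radius neighbour search. Returns, for each query index,
## the indices of points within eps (inclusive), the point itself included.
.cellKey <- function(cx, cy) paste(cx, cy, sep = ",")

.neighbourFinder <- function(x, y, eps) {
  cx <- floor(x / eps); cy <- floor(y / eps)
  cells <- split(seq_along(x), .cellKey(cx, cy))
  eps2 <- eps^2
  function(i) {
    keys <- .cellKey(rep(cx[i] + (-1:1), each = 3), rep(cy[i] + (-1:1), 3))
    cand <- unlist(cells[keys], use.names = FALSE)
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps2]
  }
}

#' Density-based clustering of a localization channel
#'
#' Standard density-based (DBSCAN) clustering of a 2D point pattern: a core
#' point has at least \code{minPts} points (itself included) within
#' \code{eps}; clusters are the connected components of core points together
#' with their border points; remaining points are noise. Border points
#' reachable from several clusters are assigned to the cluster of the
#' lowest-index core neighbour, and clusters are numbered by their lowest
#' member index — both choices make the labelling deterministic. Centroids
#' are arithmetic means of member coordinates.
#'
#' @param map a \code{\linkS4class{LocalizationMap}} (or a 2-column matrix of
#'   nm coordinates)
#' @param channel channel to cluster (default: the only/first channel)
#' @param eps neighbourhood radius in nm (default 100)
#' @param minPts minimum points per neighbourhood, point itself included
#'   (default 50)
#' @param area analysis area in um^2 (default: the map's field area)
#' @return a \code{\linkS4class{ClusterSet}}
#' @export
dbscanClusters <- function(map, channel = NULL, eps = 100, minPts = 50,
                           area = NULL) {
  if (is.matrix(map)) {
    x <- map[, 1]; y <- map[, 2]
    if (is.null(area))
      mfStop("area must be supplied with matrix input", "validation")
    chName <- if (is.null(channel)) "points" else channel
  } else {
    stopifnot(is(map, "LocalizationMap"))
    if (is.null(channel)) channel <- channels(map)[1]
    sel <- map@channel == channel
    if (!any(sel))
      mfStop(sprintf("no points in channel '%s'", channel), "validation")
    x <- map@x[sel]; y <- map@y[sel]
    if (is.null(area)) area <- map@fieldArea
    chName <- channel
  }
  .assertScalar(eps, "eps", 0, Inf, openLower = TRUE)
  n <- length(x)
  nb <- .neighbourFinder(x, y, eps)
  neighbours <- lapply(seq_len(n), nb)
  isCore <- lengths(neighbours) >= minPts

  ## union-find over core points; roots stay at the lowest member index
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(isCore)) {
    for (j in neighbours[[i]]) {
      if (isCore[j] && j > i) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }

  labels <- integer(n)  # 0 = noise
  if (any(isCore)) {
    roots <- vapply(which(isCore), findRoot, integer(1))
    ids <- match(roots, sort(unique(roots)))  # numbered by lowest core index
    labels[isCore] <- ids
    for (i in which(!isCore)) {
      coreNb <- neighbours[[i]][isCore[neighbours[[i]]]]
      if (length(coreNb)) labels[i] <- labels[min(coreNb)]
    }
  }
  k <- max(labels, 0L)
  centroids <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("x", "y")))
  sizes <- integer(k)
  for (cl in seq_len(k)) {
    m <- labels == cl
    centroids[cl, ] <- c(mean(x[m]), mean(y[m]))
    sizes[cl] <- sum(m)
  }
  new("ClusterSet", labels = labels, centroids = centroids, sizes = sizes,
      eps = eps, minPts = as.integer(minPts), area = as.numeric(area),
      channel = chName)
}

#' @rdname lambdaDensity
#' @param clusters a \code{\linkS4class{ClusterSet}}
#' @param area analysis area in um^2
#' @export
clusterDensity <- function(clusters, area = NULL) {
  if (is.null(area)) lambdaDensity(clusters) else lambdaDensity(clusters, area)
}

#' Nearest-neighbour distances between point sets
#'
#' Per source point, the Euclidean distance (nm) to the nearest target;
#' distances beyond the cutoff are discarded. Targets are typically cluster
#' centroids (molecule-to-cluster analysis) or the points of the same channel
#' with the source itself excluded (self analysis, \code{self = TRUE}).
#'
#' @param from numeric matrix (n x 2) of source coordinates in nm, or a
#'   \code{\linkS4class{LocalizationMap}} with \code{channel} given
#' @param to numeric matrix of target coordinates in nm, or a
#'   \code{\linkS4class{ClusterSet}} (centroids are used); defaults to the
#'   source set with \code{self = TRUE}
#' @param cutoff maximum distance retained, nm (default 500)
#' @param self logical; TRUE for a self analysis (source excluded from its
#'   own targets)
#' @param channel source channel when \code{from} is a localization map
#' @param margin minus-sampling edge correction: source points closer than
#'   \code{margin} nm to the bounding box of the combined pattern are
#'   dropped, so every retained source sees its full neighbourhood. Use
#'   \code{margin = cutoff} for an unbiased comparison with the Poisson
#'   null; 0 (default) disables the correction.
#' @return numeric vector of retained distances (nm)
#' @export
nnDistances <- function(from, to = NULL, cutoff = 500, self = FALSE,
                        channel = NULL, margin = 0) {
  if (is(from, "LocalizationMap")) {
    if (is.null(channel)) channel <- channels(from)[1]
    sel <- from@channel == channel
    from <- cbind(from@x[sel], from@y[sel])
  }
  if (is.null(to)) {
    to <- from
    self <- TRUE
  }
  if (is(to, "ClusterSet")) to <- clusterCentroids(to)
  from <- as.matrix(from); to <- as.matrix(to)
  if (nrow(from) < 1L || nrow(to) < 1L)
    mfStop("both point sets must be non-empty", "validation")
  if (self && nrow(to) < 2L)
    mfStop("self analysis needs at least two points", "validation")
  srcIdx <- seq_len(nrow(from))
  if (margin > 0) {
    ## minus sampling: sources restricted to the interior of the combined
    ## pattern's bounding box; all targets stay eligible
    allPts <- rbind(from, to)
    lo <- c(min(allPts[, 1]), min(allPts[, 2])) + margin
    hi <- c(max(allPts[, 1]), max(allPts[, 2])) - margin
    srcIdx <- srcIdx[from[, 1] >= lo[1] & from[, 1] <= hi[1] &
                     from[, 2] >= lo[2] & from[, 2] <= hi[2]]
    if (!length(srcIdx))
      mfStop("no source points remain inside the edge margin", "validation")
  }
  ## targets binned at the cutoff: anything farther is discarded anyway,
  ## so searching the 3x3 cell neighbourhood is exact
  tx <- to[, 1]; ty <- to[, 2]
  cells <- split(seq_along(tx), .cellKey(floor(tx / cutoff),
                                         floor(ty / cutoff)))
  out <- numeric(0)
  c2 <- cutoff^2
  for (i in srcIdx) {
    xi <- from[i, 1]; yi <- from[i, 2]
    keys <- .cellKey(rep(floor(xi / cutoff) + (-1:1), each = 3),
                     rep(floor(yi / cutoff) + (-1:1), 3))
    cand <- unlist(cells[keys], use.names = FALSE)
    if (self) cand <- cand[cand != i]
    if (!length(cand)) next
    d2 <- (tx[cand] - xi)^2 + (ty[cand] - yi)^2
    m <- min(d2)
    if (m <= c2) out <- c(out, sqrt(m))
  }
  out
}

#' Bin nearest-neighbour distances into a cumulative distribution
#'
#' Histogram of distances on [0, cutoff] with fixed-width bins (5 or 10 nm in
#' typical use) and the cumulative form normalized to the number of retained
#' distances. When the bin width does not divide the cutoff the last bin is
#' truncated and the distribution flagged. Supplying a target density
#' attaches the 2D Poisson-null CDF at the same bin edges.
#'
#' @param distances numeric vector of distances (nm)
#' @param binWidth bin width in nm (default 5)
#' @param cutoff maximum distance (nm, default 500)
#' @param lambda optional target density (per um^2) for the Poisson null
#' @return an \code{\linkS4class{NNDistribution}}
#' @export
nnDistribution <- function(distances, binWidth = 5, cutoff = 500,
                           lambda = NA_real_) {
  if (!length(distances))
    mfStop("at least one distance required", "validation")
  .assertScalar(binWidth, "binWidth", 0, Inf, openLower = TRUE)
  distances <- distances[distances <= cutoff]
  breaks <- unique(c(seq(0, cutoff, by = binWidth), cutoff))
  flags <- character(0)
  if (abs(cutoff / binWidth - round(cutoff / binWidth)) > 1e-9)
    flags <- "truncated_last_bin"
  counts <- as.integer(
    table(cut(distances, breaks, include.lowest = TRUE, right = TRUE)))
  ecdf <- cumsum(counts) / length(distances)
  nullCdf <- if (!is.na(lambda))
    poissonNullCdf(lambda, breaks[-1]) else numeric(0)
  new("NNDistribution", breaks = breaks, counts = counts, ecdf = ecdf,
      nullCdf = nullCdf, cutoff = cutoff, binWidth = binWidth,
      nDistances = length(distances), lambda = as.numeric(lambda),
      flags = flags)
}

#' Poisson-null nearest-neighbour CDF
#'
#' Theoretical nearest-neighbour distance distribution of a 2D Poisson point
#' process (evenly random scatter) of surface density \eqn{\lambda}:
#' \deqn{D(r) = 1 - \exp(-\lambda \pi r^2).}
#'
#' @param lambda density in points (or clusters) per um^2
#' @param r distances in nm
#' @return CDF values at \code{r}
#' @examples
#' poissonNullCdf(67, r = 50)
#' @export
poissonNullCdf <- function(lambda, r) {
  .assertScalar(lambda, "lambda", 0, Inf, openLower = TRUE)
  if (any(r < 0)) mfStop("r must be non-negative", "validation")
  1 - exp(-lambda * pi * (r / 1000)^2)
}

## Sample n nearest-neighbour distances (nm) from the Poisson null by inverse
## transform: r = sqrt(-log(1 - u) / (lambda * pi)) um.
.sampleNullDistances <- function(n, lambda) {
  sqrt(-log(stats::runif(n)) / (lambda * pi)) * 1000
}

#' Compare an empirical nearest-neighbour distribution with its Poisson null
#'
#' Divergence report between the empirical CDF and the attached Poisson-null
#' CDF: the signed area between the CDFs up to the cutoff (positive when the
#' empirical CDF lies above the null, i.e. distances are shorter than
#' random), the Kolmogorov-Smirnov statistic, and a direction verdict. The
#' verdict is \code{"association"} or \code{"dispersion"} only when the KS
#' statistic exceeds a seeded Monte-Carlo threshold obtained by redrawing
#' \code{nSim} distance sets of the observed size from the null (same cutoff
#' conditioning and binning); otherwise \code{"indistinguishable"}.
#'
#' @param empirical an \code{\linkS4class{NNDistribution}} with a null CDF
#'   attached (see \code{\link{nnDistribution}})
#' @param nSim Monte-Carlo null replicates (default 999)
#' @param seed RNG seed
#' @param level test level (default 0.05)
#' @return list with \code{verdict}, \code{ks}, \code{ksThreshold},
#'   \code{signedArea} (nm) and \code{nDistances}
#' @export
compareToNull <- function(empirical, nSim = 999L, seed = 1L, level = 0.05) {
  stopifnot(is(empirical, "NNDistribution"))
  if (!length(empirical@nullCdf))
    mfStop("no null CDF attached; supply lambda to nnDistribution()",
           "validation")
  diffCdf <- empirical@ecdf - empirical@nullCdf
  widths <- diff(empirical@breaks)
  signedArea <- sum(diffCdf * widths)
  ks <- max(abs(diffCdf))
  n <- empirical@nDistances
  lambda <- empirical@lambda
  ksNull <- .withSeed(seed, vapply(seq_len(nSim), function(b) {
    d <- .sampleNullDistances(n, lambda)
    d <- d[d <= empirical@cutoff]
    if (!length(d)) return(NA_real_)
    sim <- nnDistribution(d, empirical@binWidth, empirical@cutoff, lambda)
    max(abs(sim@ecdf - sim@nullCdf))
  }, numeric(1)))
  thr <- stats::quantile(ksNull, 1 - level, na.rm = TRUE, names = FALSE)
  verdict <- if (ks <= thr) "indistinguishable"
    else if (signedArea > 0) "association" else "dispersion"
  list(verdict = verdict, ks = ks, ksThreshold = thr,
       signedArea = signedArea, nDistances = n)
}
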