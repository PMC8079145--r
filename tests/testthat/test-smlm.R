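test_that("density clustering separates blobs and rejects undersized ones", {
  ## two 60-point blobs of 45 nm radius (all pairwise < 100 nm), 1 um apart
  pts <- rbind(mkBlob(60, 500, 500, 45, 1), mkBlob(60, 1500, 500, 45, 2))
  cs <- dbscanClusters(mkMap(pts, 4), eps = 100, minPts = 50)
  expect_equal(nrow(clusterCentroids(cs)), 2L)
  expect_equal(sort(cs@sizes), c(60L, 60L))
  expect_true(all(clusterLabels(cs) > 0L))

  ## 49 mutually-close points: below minPts, all noise
  pts49 <- mkBlob(49, 500, 500, 40, 3)
  cs49 <- dbscanClusters(mkMap(pts49, 4), eps = 100, minPts = 50)
  expect_equal(nrow(clusterCentroids(cs49)), 0L)
  expect_true(all(clusterLabels(cs49) == 0L))
  expect_equal(bruteDbscan(pts49[, 1], pts49[, 2], 100, 50),
               rep(0L, 49))
})

test_that("density clustering equals the brute-force reference on random instances", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- sample(50:500, 1)
    ## mix of uniform scatter and a few dense pockets
    pts <- cbind(stats::runif(n, 0, 2000), stats::runif(n, 0, 2000))
    k <- sample(2:4, 1)
    for (b in seq_len(k)) {
      m <- sample(10:60, 1)
      pts <- rbind(pts, mkBlob(m, stats::runif(1, 200, 1800),
                               stats::runif(1, 200, 1800), 60, 200 + s * b))
    }
    eps <- sample(c(60, 100, 150), 1)
    minPts <- sample(c(5, 10, 20), 1)
    got <- clusterLabels(dbscanClusters(mkMap(pts, 4), eps = eps,
                                        minPts = minPts))
    want <- bruteDbscan(pts[, 1], pts[, 2], eps, minPts)
    expect_identical(got, want)
  }
})

test_that("planted Thomas clusters are recovered at the planted count", {
  sim <- simulatePointPattern("thomas", area = 16, nParents = 20,
                              meanOffspring = 80, offspringSd = 30,
                              seed = 12)
  cs <- dbscanClusters(sim$map, eps = 100, minPts = 50)
  expect_true(abs(nrow(clusterCentroids(cs)) - 20) <= 2)
})

test_that("cluster density is count per area", {
  pts <- rbind(mkBlob(60, 300, 300, 40, 5), mkBlob(60, 1300, 300, 40, 6),
               mkBlob(60, 300, 1300, 40, 7), mkBlob(60, 1300, 1300, 40, 8),
               mkBlob(60, 800, 800, 40, 9))
  cs <- dbscanClusters(mkMap(pts, 0.25), eps = 100, minPts = 50)
  expect_equal(clusterDensity(cs, 0.25), 20)
  empty <- dbscanClusters(mkMap(mkBlob(10, 500, 500, 40, 10), 1),
                          eps = 100, minPts = 50)
  expect_equal(clusterDensity(empty, 1), 0)

  ## Poisson "cluster centers" at lambda = 67 per um^2 over 4 um^2
  sim <- simulatePointPattern("poisson", area = 4, lambda = 67, seed = 21)
  lamHat <- length(sim$map@x) / 4
  expect_lt(abs(lamHat - 67), 3 * sqrt(67 / 4))
})

test_that("nearest-neighbour distances match geometry and the brute-force oracle", {
  expect_equal(nnDistances(rbind(c(0, 0)), rbind(c(30, 40))), 50)
  two <- rbind(c(0, 0), c(10, 0))
  expect_equal(nnDistances(two, self = TRUE), c(10, 10))

  set.seed(77)
  from <- cbind(stats::runif(200, 0, 3000), stats::runif(200, 0, 3000))
  to <- cbind(stats::runif(150, 0, 3000), stats::runif(150, 0, 3000))
  expect_equal(nnDistances(from, to, cutoff = 500),
               bruteNN(from, to, 500))
  expect_equal(nnDistances(from, cutoff = 400, self = TRUE),
               bruteNN(from, from, 400, self = TRUE))
})

test_that("distance binning produces a normalized cumulative distribution", {
  nd <- nnDistribution(c(2, 7), binWidth = 5, cutoff = 500)
  expect_equal(nd@counts[1:3], c(1L, 1L, 0L))
  expect_equal(nd@ecdf[length(nd@ecdf)], 1)
  expect_equal(nd@ecdf[1:2], c(0.5, 1))

  same <- nnDistribution(rep(12, 10), binWidth = 5, cutoff = 500)
  expect_equal(unique(same@ecdf), c(0, 1))  # step CDF

  trunc <- nnDistribution(c(2, 7), binWidth = 7, cutoff = 500)
  expect_true("truncated_last_bin" %in% qualityFlags(trunc))
})

test_that("the Poisson null CDF follows 1 - exp(-lambda pi r^2)", {
  expect_equal(poissonNullCdf(67, 0), 0)
  rMed <- sqrt(log(2) / (67 * pi)) * 1000
  expect_equal(poissonNullCdf(67, rMed), 0.5, tolerance = 1e-12)
  expect_equal(poissonNullCdf(67, 50), 0.409, tolerance = 1e-3)
})

test_that("Poisson patterns are indistinguishable from the null; planted structure is not", {
  ## self nearest-neighbour analysis of Poisson patterns: the mean KS over
  ## replicate fields sits inside the single-sample 95% band
  ksP <- vapply(1:5, function(s) {
    sim <- simulatePointPattern("poisson", area = 16, lambda = 67, seed = s)
    lam <- length(sim$map@x) / 16
    d <- nnDistances(sim$map, cutoff = 500)
    nd <- nnDistribution(d, binWidth = 5, cutoff = 500, lambda = lam)
    max(abs(nd@ecdf - nd@nullCdf))
  }, numeric(1))
  expect_lt(mean(ksP), 1.36 / sqrt(67 * 16))

  ## verdicts over replicate null fields: the 5%-level test may flag at most
  ## a minority
  verdicts <- vapply(1:3, function(s) {
    sim <- simulatePointPattern("poisson", area = 16, lambda = 67, seed = s)
    lam <- length(sim$map@x) / 16
    d <- nnDistances(sim$map, cutoff = 500)
    nd <- nnDistribution(d, binWidth = 5, cutoff = 500, lambda = lam)
    compareToNull(nd, nSim = 299, seed = 11)$verdict
  }, character(1))
  expect_gte(sum(verdicts == "indistinguishable"), 2)

  ## exact-null distribution: KS = 0, indistinguishable
  ndExact <- nnDistribution(.sampleNullOracle(400), binWidth = 5,
                            cutoff = 500, lambda = 67)
  ndExact@nullCdf <- ndExact@ecdf
  cmp0 <- compareToNull(ndExact, nSim = 99, seed = 1)
  expect_equal(cmp0$ks, 0)
  expect_equal(cmp0$verdict, "indistinguishable")

  ## planted attraction between channels
  simA <- simulatePointPattern("associated", area = 16, lambda = 40,
                               lambda2 = 40, assocFraction = 0.8,
                               assocSd = 40, seed = 6)
  p1 <- cbind(simA$map@x, simA$map@y)[simA$map@channel == "chan1", ]
  p2 <- cbind(simA$map@x, simA$map@y)[simA$map@channel == "chan2", ]
  dA <- nnDistances(p2, p1, cutoff = 500)
  ndA <- nnDistribution(dA, binWidth = 5, cutoff = 500, lambda = 40)
  cmpA <- compareToNull(ndA, nSim = 499, seed = 11)
  expect_equal(cmpA$verdict, "association")
  expect_gt(cmpA$signedArea, 0)

  ## planted exclusion zone
  simR <- simulatePointPattern("repulsive", area = 16, lambda = 40,
                               lambda2 = 40, exclusionRadius = 120, seed = 6)
  p1 <- cbind(simR$map@x, simR$map@y)[simR$map@channel == "chan1", ]
  p2 <- cbind(simR$map@x, simR$map@y)[simR$map@channel == "chan2", ]
  dR <- nnDistances(p2, p1, cutoff = 500)
  ndR <- nnDistribution(dR, binWidth = 5, cutoff = 500, lambda = 40)
  cmpR <- compareToNull(ndR, nSim = 499, seed = 11)
  expect_equal(cmpR$verdict, "dispersion")
  expect_lt(cmpR$signedArea, 0)
})

test_that("the empirical NN CDF converges to the null as the sample grows", {
  ksAt <- function(area, seed) {
    sim <- simulatePointPattern("poisson", area = area, lambda = 67,
                                seed = seed)
    lam <- length(sim$map@x) / area
    d <- nnDistances(sim$map, cutoff = 500)
    nd <- nnDistribution(d, binWidth = 5, cutoff = 500, lambda = lam)
    max(abs(nd@ecdf - nd@nullCdf))
  }
  small <- mean(vapply(1:5, function(s) ksAt(4, 30 + s), numeric(1)))
  large <- mean(vapply(1:5, function(s) ksAt(64, 30 + s), numeric(1)))
  expect_lt(large, small)  # ~ n^{-1/2} decay (16x points -> ~4x smaller)
  expect_lt(large, 0.6 * small)
})
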