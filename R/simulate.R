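#' Simulate a whole-cell FRAP turnover trace
#'
#' Samples the closed-form turnover curve (\code{\link{turnoverCurve}}) on a
#' uniform frame grid with \code{nBaseline} pre-bleach frames at baseline,
#' the first post-bleach frame at t = 0, and optional i.i.d. Gaussian noise
#' on the post-bleach frames. In raw-channel mode consistent
#' bleach/background/reference triples are emitted (with a residual
#' post-bleach floor \code{bleachFloor} in the raw bleach channel) that
#' normalize back to the model curve through the standard pipeline.
#'
#' @param Cin intracellular fraction (default 0.30)
#' @param k1 insertion rate constant, 1/s (default 0.045)
#' @param kb residual photobleaching rate, 1/s (default 0)
#' @param frameInterval seconds per frame (default 1.644)
#' @param duration post-bleach observation time, seconds (default 300)
#' @param noiseSd Gaussian noise s.d. added to post-bleach frames (normalized
#'   units; default 0)
#' @param seed RNG seed (NULL leaves the RNG stream untouched)
#' @param rawChannels return the raw \code{\linkS4class{RoiTraceSet}} instead
#'   of the normalized trace
#' @param nBaseline pre-bleach frames (default 40)
#' @param bleachFloor residual raw fluorescence right after the bleach pulse,
#'   fraction of baseline (default 0.05)
#' @return a \code{\linkS4class{NormalizedTrace}} (default) or
#'   \code{\linkS4class{RoiTraceSet}} (\code{rawChannels = TRUE})
#' @examples
#' nt <- simulateTurnoverTrace(noiseSd = 0.01, seed = 7)
#' @export
simulateTurnoverTrace <- function(Cin = 0.30, k1 = 0.045, kb = 0,
                                  frameInterval = 1.644, duration = 300,
                                  noiseSd = 0, seed = NULL,
                                  rawChannels = FALSE, nBaseline = 40L,
                                  bleachFloor = 0.05) {
  .assertScalar(bleachFloor, "bleachFloor", 0, 0.99)
  if (duration < 3 / k1)
    warning(sprintf(
      "duration %.3g s is shorter than 3/k1 = %.3g s: plateau unresolved",
      duration, 3 / k1))
  nPost <- floor(duration / frameInterval) + 1L
  tPost <- frameInterval * (seq_len(nPost) - 1L)
  curve <- turnoverCurve(tPost, Cin, k1, kb)
  fPost <- bleachFloor + (1 - bleachFloor) * curve
  if (noiseSd > 0)
    fPost <- fPost + .withSeed(seed, stats::rnorm(nPost, 0, noiseSd))
  raw <- newRoiTraceSet(
    time = frameInterval * (seq_len(nBaseline + nPost) - 1L),
    bleach = c(rep(1, nBaseline), fPost),
    background = rep(0, nBaseline + nPost),
    reference = rep(1, nBaseline + nPost),
    bleachEnd = nBaseline + 1L,
    condition = "synthetic_turnover")
  if (rawChannels) raw else normalizeTrace(raw, 1L, nBaseline)
}

#' Simulate a pH-puff surface-fraction trace
#'
#' Emulates the acid / NH4Cl puff protocol used to separate surface from
#' intracellular pools of a pH-sensitive tag. With true surface fraction
#' \code{RTrue} and residual intracellular brightness \code{qIn} (default 0:
#' acidic compartments dark), the noiseless epoch levels are
#' baseline \code{RTrue + (1 - RTrue) qIn}, acid puff
#' \code{qIn (1 - RTrue)} (surface quenched) and NH4Cl puff 1 (all pools
#' fluorescent). Gaussian noise is added per frame.
#'
#' @param RTrue true surface fraction, in [0, 1]
#' @param epochs named list of frame-index ranges \code{c(first, last)} for
#'   \code{base}, \code{acid} and \code{nh4} (defaults give a 180-frame
#'   protocol with recovery gaps between puffs)
#' @param nFrames total frames (default 180)
#' @param frameInterval seconds per frame (default 1)
#' @param noiseSd Gaussian noise s.d. (default 0)
#' @param qIn residual intracellular brightness (default 0)
#' @param seed RNG seed
#' @return list with \code{trace} (a \code{\linkS4class{RoiTraceSet}}),
#'   \code{epochs} and \code{truth}
#' @export
simulatePuffTrace <- function(RTrue, epochs = list(base = c(1, 40),
                                                   acid = c(61, 100),
                                                   nh4 = c(141, 180)),
                              nFrames = 180L, frameInterval = 1,
                              noiseSd = 0, qIn = 0, seed = NULL) {
  .assertScalar(RTrue, "RTrue", 0, 1)
  .assertScalar(qIn, "qIn", 0, 1)
  base <- RTrue + (1 - RTrue) * qIn
  f <- rep(base, nFrames)
  f[epochs$acid[1]:epochs$acid[2]] <- qIn * (1 - RTrue)
  f[epochs$nh4[1]:epochs$nh4[2]] <- 1
  if (noiseSd > 0)
    f <- f + .withSeed(seed, stats::rnorm(nFrames, 0, noiseSd))
  trace <- newRoiTraceSet(
    time = frameInterval * (seq_len(nFrames) - 1L),
    bleach = f, background = rep(0, nFrames), reference = rep(1, nFrames),
    bleachEnd = 1L, condition = "synthetic_puff")
  list(trace = trace, epochs = epochs,
       truth = list(RTrue = RTrue, qIn = qIn, noiseSd = noiseSd, seed = seed))
}

#' Surface fraction from a puff trace with marked epochs
#'
#' Convenience wrapper: epoch means of a bleach-ROI trace (background
#' subtracted per frame) fed into \code{\link{estimateSurfaceFraction}}.
#'
#' @param trace a \code{\linkS4class{RoiTraceSet}}
#' @param epochs named list with \code{base}, \code{acid}, \code{nh4}
#'   frame-index ranges
#' @param roi bleach-ROI index (default 1)
#' @param roiKind ROI label passed through
#' @return as \code{\link{estimateSurfaceFraction}}
#' @export
surfaceFractionFromTrace <- function(trace, epochs, roi = 1L,
                                     roiKind = "process") {
  stopifnot(is(trace, "RoiTraceSet"))
  v <- trace@bleach[, roi] - trace@background
  em <- vapply(epochs[c("base", "acid", "nh4")],
               function(e) mean(v[e[1]:e[2]]), numeric(1))
  estimateSurfaceFraction(em[["base"]], em[["acid"]], em[["nh4"]], roiKind)
}

#' Particle-based Brownian-dynamics FRAP simulation
#'
#' Simulates 2D lateral diffusion of membrane molecules in a periodic square
#' domain with an instantaneous hard-edged disk bleach, an immobile fraction,
#' and optional membrane/cytosol exchange; reads out the count of unbleached
#' particles inside the readout disk per frame and pushes it through the same
#' normalization as experimental traces.
#'
#' Mobile particles take Gaussian steps of per-axis s.d. \code{sqrt(2 D dt)};
#' a fraction \code{immobileFraction} never moves. At t = 0 every particle
#' inside the bleach disk is flagged bleached and an immediate post-bleach
#' frame is recorded. When exchange is enabled each particle independently
#' leaves the membrane with probability \code{1 - exp(-kMinus1 dt)} per step
#' and is immediately replaced (mass conserved exactly) by a reservoir
#' particle at a uniform random position. Before the bleach pulse every
#' molecule is fluorescent, so replacements are unbleached; afterwards a
#' replacement is unbleached with probability \code{unbleachedFraction} —
#' the effective fluorescent availability of the intracellular pool.
#' Defaults: \code{kMinus1 = k1} (symmetric steady state, surface fraction
#' R = 0.5) and \code{unbleachedFraction = R * Cin} with
#' \code{Cin = kMinus1/(k1 + kMinus1)}, which makes the simulated
#' whole-field recovery converge to \code{\link{turnoverCurve}} with rate
#' \code{k1} and amplitude \code{(1 - Cin) Cin}. \code{bleachRadius = Inf}
#' requests a whole-field bleach (the domain-size guard is waived).
#'
#' For sub-field bleaches the emitted reference channel is the total
#' unbleached count over the domain, mirroring the experimental whole-cell
#' reference ROI; this cancels the finite-domain depletion of the
#' fluorescent pool exactly as the real normalization does.
#'
#' @param D diffusion coefficient, um^2/s (0 for pure exchange)
#' @param immobileFraction fraction of particles that never move, in [0, 1]
#' @param k1 insertion rate constant for exchange mode, 1/s (0 disables
#'   exchange)
#' @param kMinus1 removal rate constant, 1/s (default \code{k1})
#' @param unbleachedFraction probability that a replacement particle is
#'   unbleached (default derived from \code{k1}, \code{kMinus1}; see above)
#' @param domainSize square domain side, um (periodic boundaries)
#' @param nParticles particle count
#' @param dt simulation step, s (must not exceed \code{frameInterval}; the
#'   step length guard \code{sqrt(4 D dt) <= bleachRadius/5} is enforced)
#' @param duration post-bleach observation time, s
#' @param bleachRadius bleach-disk radius, um (Inf = whole field)
#' @param bleachTime pre-bleach observation time, s
#' @param readoutRadius readout-disk radius, um (default: bleach radius)
#' @param frameInterval seconds between recorded frames (rounded to a
#'   multiple of \code{dt})
#' @param seed RNG seed
#' @return list with \code{trace} (a \code{\linkS4class{NormalizedTrace}})
#'   and \code{truth} (ground-truth record: CmobTrue, tauDTrue, all
#'   parameters and per-frame unbleached counts)
#' @examples
#' \donttest{
#' sim <- simulateBrownianFrap(D = 0.152, immobileFraction = 0.24,
#'                             nParticles = 5000, duration = 30, seed = 1)
#' coef(fitSoumpasis(sim$trace, w = 1.03, nBoot = 0))
#' }
#' @export
simulateBrownianFrap <- function(D, immobileFraction = 0, k1 = 0,
                                 kMinus1 = k1, unbleachedFraction = NULL,
                                 domainSize = 20, nParticles = 20000L,
                                 dt = 0.01, duration = 60,
                                 bleachRadius = 1.03, bleachTime = 6,
                                 readoutRadius = bleachRadius,
                                 frameInterval = 0.14832, seed = 1L) {
  .assertScalar(D, "D", 0, Inf)
  .assertScalar(immobileFraction, "immobileFraction", 0, 1)
  .assertScalar(k1, "k1", 0, Inf)
  .assertScalar(kMinus1, "kMinus1", 0, Inf)
  if (dt > frameInterval)
    mfStop("dt must not exceed frameInterval", "validation")
  wholeField <- is.infinite(bleachRadius)
  if (!wholeField) {
    if (sqrt(4 * D * dt) > bleachRadius / 5)
      mfStop("step resolution guard violated: sqrt(4 D dt) > bleachRadius/5",
             "validation")
    if (domainSize < 10 * bleachRadius)
      mfStop("domain must be at least 10x the bleach radius", "validation")
  }
  exchange <- k1 > 0 || kMinus1 > 0
  if (exchange && is.null(unbleachedFraction)) {
    cin <- kMinus1 / (k1 + kMinus1)
    unbleachedFraction <- (1 - cin) * cin
  }
  if (is.null(unbleachedFraction)) unbleachedFraction <- 1
  .assertScalar(unbleachedFraction, "unbleachedFraction", 0, 1)

  L <- domainSize
  stepsPerFrame <- max(1L, round(frameInterval / dt))
  fi <- stepsPerFrame * dt
  nPre <- max(1L, round(bleachTime / fi))
  nPost <- floor(duration / fi) + 1L  # frame at t = 0 included
  sdStep <- sqrt(2 * D * dt)
  pOff <- if (exchange) 1 - exp(-kMinus1 * dt) else 0
  rr2 <- if (is.infinite(readoutRadius)) Inf else readoutRadius^2
  br2 <- if (wholeField) Inf else bleachRadius^2
  cx <- L / 2

  res <- .withSeed(seed, {
    x <- stats::runif(nParticles, 0, L)
    y <- stats::runif(nParticles, 0, L)
    nImm <- round(nParticles * immobileFraction)
    mobile <- rep(TRUE, nParticles)
    if (nImm > 0) mobile[sample.int(nParticles, nImm)] <- FALSE
    bleached <- rep(FALSE, nParticles)

    inReadout <- function()
      if (is.infinite(rr2)) !bleached
      else !bleached & ((x - cx)^2 + (y - cx)^2 <= rr2)

    postBleach <- FALSE
    stepOnce <- function() {
      if (D > 0) {
        nm <- sum(mobile)
        if (nm > 0) {
          x[mobile] <<- (x[mobile] + stats::rnorm(nm, 0, sdStep)) %% L
          y[mobile] <<- (y[mobile] + stats::rnorm(nm, 0, sdStep)) %% L
        }
      }
      if (pOff > 0) {
        out <- stats::runif(nParticles) < pOff
        nOut <- sum(out)
        if (nOut > 0) {
          x[out] <<- stats::runif(nOut, 0, L)
          y[out] <<- stats::runif(nOut, 0, L)
          ## pre-bleach nothing is bleached; post-bleach the reservoir's
          ## fluorescent availability is unbleachedFraction
          bleached[out] <<- if (postBleach)
            stats::runif(nOut) >= unbleachedFraction else FALSE
          mobile[out] <<- stats::runif(nOut) >= immobileFraction
        }
      }
    }

    counts <- numeric(nPre + nPost)
    refCounts <- numeric(nPre + nPost)
    for (fr in seq_len(nPre)) {
      for (s in seq_len(stepsPerFrame)) stepOnce()
      counts[fr] <- sum(inReadout())
      refCounts[fr] <- sum(!bleached)
    }
    ## instantaneous bleach, then an immediate post-bleach frame at t = 0
    bleached <- bleached |
      (if (wholeField) rep(TRUE, nParticles)
       else (x - cx)^2 + (y - cx)^2 <= br2)
    postBleach <- TRUE
    counts[nPre + 1L] <- sum(inReadout())
    refCounts[nPre + 1L] <- sum(!bleached)
    if (nPost > 1L) for (fr in seq_len(nPost - 1L)) {
      for (s in seq_len(stepsPerFrame)) stepOnce()
      counts[nPre + 1L + fr] <- sum(inReadout())
      refCounts[nPre + 1L + fr] <- sum(!bleached)
    }
    list(counts = counts, refCounts = refCounts)
  })

  ## the reference tracks the global unbleached pool only when the bleach
  ## leaves one (whole-field bleach has no outside reference)
  ref <- if (wholeField || is.infinite(readoutRadius))
    rep(nParticles, length(res$counts)) else res$refCounts
  raw <- newRoiTraceSet(
    time = fi * (seq_along(res$counts) - 1L),
    bleach = res$counts, background = rep(0, length(res$counts)),
    reference = ref,
    bleachEnd = nPre + 1L,
    roiRadius = if (is.infinite(readoutRadius)) NA_real_ else readoutRadius,
    condition = "synthetic_brownian_frap")
  trace <- normalizeTrace(raw, 1L, nPre)
  truth <- list(
    CmobTrue = 1 - immobileFraction,
    tauDTrue = if (D > 0 && !wholeField) bleachRadius^2 / (4 * D) else NA_real_,
    D = D, immobileFraction = immobileFraction,
    k1 = k1, kMinus1 = if (exchange) kMinus1 else 0,
    unbleachedFraction = unbleachedFraction,
    domainSize = domainSize, nParticles = nParticles, dt = dt,
    duration = duration, bleachRadius = bleachRadius,
    bleachTime = bleachTime, readoutRadius = readoutRadius,
    frameInterval = fi, seed = seed, counts = res$counts,
    refCounts = res$refCounts)
  list(trace = trace, truth = truth)
}

#' Simulate a 2D spatial point pattern
#'
#' Generators for the point-pattern geometries used by the cluster and
#' nearest-neighbour machinery, each with recorded ground truth:
#' \describe{
#'   \item{poisson}{\code{N ~ Poisson(lambda * area)} uniform points.}
#'   \item{thomas}{Poisson (or fixed-count) parents with
#'     \code{Poisson(meanOffspring)} offspring displaced by an isotropic
#'     Gaussian of s.d. \code{offspringSd} nm.}
#'   \item{associated}{channel 1 Poisson at \code{lambda}; channel 2 at
#'     \code{lambda2} where a fraction \code{assocFraction} of points is
#'     placed as Gaussian (\code{assocSd} nm) displacements of random
#'     channel-1 points and the rest uniform.}
#'   \item{repulsive}{channel 1 Poisson at \code{lambda}; channel 2 uniform
#'     candidates at \code{lambda2} thinned by a hard exclusion radius
#'     \code{exclusionRadius} nm around channel-1 points.}
#' }
#'
#' @param mode one of \code{"poisson"}, \code{"thomas"},
#'   \code{"associated"}, \code{"repulsive"}
#' @param area field area in um^2 (square field)
#' @param lambda density of the (first) channel, per um^2
#' @param lambda2 density of the second channel (associated/repulsive)
#' @param nParents fixed parent count (thomas; overrides
#'   \code{parentDensity})
#' @param parentDensity parent density per um^2 (thomas)
#' @param meanOffspring mean offspring per parent (thomas)
#' @param offspringSd offspring displacement s.d., nm (thomas)
#' @param assocFraction fraction of channel-2 points tied to channel 1
#' @param assocSd association displacement s.d., nm
#' @param exclusionRadius hard-core exclusion radius, nm (repulsive)
#' @param channelNames labels for the generated channels
#' @param seed RNG seed
#' @return list with \code{map} (a \code{\linkS4class{LocalizationMap}}) and
#'   \code{truth}
#' @export
simulatePointPattern <- function(mode = c("poisson", "thomas", "associated",
                                          "repulsive"),
                                 area = 4, lambda = 67, lambda2 = 50,
                                 nParents = NULL, parentDensity = 5,
                                 meanOffspring = 80, offspringSd = 30,
                                 assocFraction = 0.7, assocSd = 50,
                                 exclusionRadius = 100,
                                 channelNames = c("chan1", "chan2"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  .assertScalar(area, "area", 0, Inf, openLower = TRUE)
  side <- sqrt(area) * 1000  # nm
  res <- .withSeed(seed, {
    runifPts <- function(n) cbind(stats::runif(n, 0, side),
                                  stats::runif(n, 0, side))
    switch(mode,
      poisson = {
        n <- stats::rpois(1, lambda * area)
        list(p1 = runifPts(n), p2 = NULL,
             truth = list(lambda = lambda, n = n))
      },
      thomas = {
        np <- if (is.null(nParents)) stats::rpois(1, parentDensity * area)
              else nParents
        parents <- runifPts(np)
        nOff <- stats::rpois(np, meanOffspring)
        pts <- do.call(rbind, lapply(seq_len(np), function(i)
          cbind(parents[i, 1] + stats::rnorm(nOff[i], 0, offspringSd),
                parents[i, 2] + stats::rnorm(nOff[i], 0, offspringSd))))
        if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
        keep <- pts[, 1] >= 0 & pts[, 1] <= side &
                pts[, 2] >= 0 & pts[, 2] <= side
        list(p1 = pts[keep, , drop = FALSE], p2 = NULL,
             truth = list(nParents = np, parents = parents,
                          meanOffspring = meanOffspring,
                          offspringSd = offspringSd))
      },
      associated = {
        n1 <- stats::rpois(1, lambda * area)
        p1 <- runifPts(n1)
        n2 <- stats::rpois(1, lambda2 * area)
        tied <- stats::runif(n2) < assocFraction
        p2 <- runifPts(n2)
        nT <- sum(tied)
        if (nT > 0 && n1 > 0) {
          anchor <- p1[sample.int(n1, nT, replace = TRUE), , drop = FALSE]
          p2[tied, ] <- anchor + matrix(stats::rnorm(2 * nT, 0, assocSd),
                                        ncol = 2)
          p2 <- pmin(pmax(p2, 0), side)
        }
        list(p1 = p1, p2 = p2,
             truth = list(lambda = lambda, lambda2 = lambda2,
                          assocFraction = assocFraction, assocSd = assocSd))
      },
      repulsive = {
        n1 <- stats::rpois(1, lambda * area)
        p1 <- runifPts(n1)
        n2 <- stats::rpois(1, lambda2 * area)
        p2 <- runifPts(n2)
        if (n1 > 0 && n2 > 0) {
          ## keep candidates with no channel-1 point inside the exclusion radius
          keep <- vapply(seq_len(n2), function(i)
            min((p1[, 1] - p2[i, 1])^2 + (p1[, 2] - p2[i, 2])^2) >
              exclusionRadius^2, logical(1))
          p2 <- p2[keep, , drop = FALSE]
        }
        list(p1 = p1, p2 = p2,
             truth = list(lambda = lambda, lambda2 = lambda2,
                          exclusionRadius = exclusionRadius))
      })
  })
  pts <- rbind(res$p1, res$p2)
  ch <- factor(c(rep(channelNames[1], nrow(res$p1)),
                 rep(channelNames[2],
                     if (is.null(res$p2)) 0 else nrow(res$p2))),
               levels = channelNames[c(1, if (!is.null(res$p2)) 2)])
  map <- new("LocalizationMap",
             x = pts[, 1], y = pts[, 2], channel = ch,
             fieldArea = area)
  list(map = map, truth = c(res$truth, list(mode = mode, area = area,
                                            seed = seed)))
}
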