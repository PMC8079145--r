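#' Closed-form whole-cell FRAP turnover curve
#'
#' Fluorescence recovery of the membrane pool after whole-cell photobleaching
#' under the two-compartment membrane/cytosol exchange model:
#' \deqn{f(t) = (1 - C_{in}) C_{in} (e^{-k_b t} - e^{-k_1 t})}
#' on the normalized scale where the pre-bleach baseline is 1 and the first
#' post-bleach frame is 0. With \eqn{k_b = 0} the curve rises monotonically to
#' the plateau \eqn{(1 - C_{in}) C_{in}}.
#'
#' @param t time since bleach end, seconds (non-negative)
#' @param Cin intracellular fraction of the protein, in [0, 1]
#' @param k1 membrane insertion rate constant (1/s)
#' @param kb residual photobleaching rate constant (1/s, >= 0)
#' @return numeric vector of dimensionless fluorescence values
#' @examples
#' turnoverCurve(c(0, 10, 100), Cin = 0.30, k1 = 0.045)
#' @export
turnoverCurve <- function(t, Cin, k1, kb = 0) {
  .assertScalar(Cin, "Cin", 0, 1)
  .assertScalar(k1, "k1", 0, Inf, openLower = TRUE)
  .assertScalar(kb, "kb", 0, Inf)
  if (any(t < 0)) mfStop("t must be non-negative", "validation")
  if (kb > 0 && kb >= k1)
    warning("kb >= k1: recovery curve is non-monotone under this model")
  (1 - Cin) * Cin * (exp(-kb * t) - exp(-k1 * t))
}

#' Steady-state removal rate constant
#'
#' Under steady-state exchange between the membrane and intracellular pools,
#' the removal (endocytosis) rate constant follows from the insertion rate
#' constant and the surface fraction R:
#' \deqn{k_{-1} = (1/R - 1)\, k_1.}
#'
#' @param k1 insertion rate constant (1/s)
#' @param R surface fraction, strictly inside (0, 1)
#' @return removal rate constant (1/s)
#' @examples
#' steadyStateRemovalRate(0.045, R = 0.72)
#' @export
steadyStateRemovalRate <- function(k1, R) {
  .assertScalar(k1, "k1", 0, Inf, openLower = TRUE)
  .assertScalar(R, "R", 0, 1, openLower = TRUE, openUpper = TRUE)
  (1 / R - 1) * k1
}

#' Characteristic membrane lifetime
#'
#' The characteristic lifetime of the fluorescent membrane pool recovered by
#' the whole-cell FRAP fit, defined as \eqn{1/k_1}. (The reciprocal of the
#' removal constant, \eqn{1/k_{-1}}, is also reported by
#' \code{\link{fitTurnover}}.)
#'
#' @param k1 insertion rate constant (1/s)
#' @return lifetime in seconds
#' @export
membraneLifetime <- function(k1) {
  .assertScalar(k1, "k1", 0, Inf, openLower = TRUE)
  1 / k1
}

#' Surface-fraction estimate from a pH-manipulation trace
#'
#' Transient extracellular acidification quenches the surface pool of a
#' pH-sensitive tag while transient NH4Cl permeation renders the intracellular
#' pool fluorescent, so epoch-averaged intensities at baseline, during the
#' acid puff and during the NH4Cl puff determine the surface fraction
#' \deqn{R = (f_{base} - f_{acid}) / (f_{NH4} - f_{acid}),}
#' clamped to [0, 1] with a flag when noise pushes it outside.
#'
#' @param fBase,fAcid,fNh4 epoch-averaged, background-subtracted intensities
#'   (vectors over ROIs are supported)
#' @param roiKind "process" or "soma" label per ROI (metadata)
#' @return data.frame with columns \code{R}, \code{Rraw}, \code{clamped},
#'   \code{f_base}, \code{f_acid}, \code{f_nh4}, \code{roi_kind}
#' @examples
#' estimateSurfaceFraction(fBase = 1, fAcid = 0, fNh4 = 1.389)
#' @export
estimateSurfaceFraction <- function(fBase, fAcid, fNh4, roiKind = "process") {
  n <- max(length(fBase), length(fAcid), length(fNh4))
  fBase <- rep_len(fBase, n); fAcid <- rep_len(fAcid, n)
  fNh4 <- rep_len(fNh4, n); roiKind <- rep_len(roiKind, n)
  if (any(fNh4 <= fAcid))
    mfStop("f_nh4 must exceed f_acid (no resolvable total pool)", "validation")
  rRaw <- (fBase - fAcid) / (fNh4 - fAcid)
  r <- pmin(1, pmax(0, rRaw))
  data.frame(R = r, Rraw = rRaw, clamped = rRaw < 0 | rRaw > 1,
             f_base = fBase, f_acid = fAcid, f_nh4 = fNh4,
             roi_kind = roiKind)
}

#' Fit the two-compartment turnover model to a whole-cell FRAP trace
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' \code{\link{turnoverCurve}} over the post-bleach frames of a normalized
#' trace. Free parameters: \code{Cin}, \code{k1} and the residual
#' photobleaching rate \code{kb} (lower-bounded at 0 rather than fixed).
#' Derived: \code{R = 1 - Cin}, \code{kMinus1 = (1/R - 1) k1} and the
#' membrane lifetime \code{1/k1}. Confidence intervals come from seeded
#' residual-resampling bootstrap.
#'
#' The model amplitude \eqn{(1-C_{in})C_{in}} is symmetric under
#' \eqn{C_{in} \leftrightarrow 1 - C_{in}}; \code{CinUpper = 0.5} (default)
#' selects the intracellular-minority branch expected for a predominantly
#' surface-resident protein.
#'
#' @param trace a \code{\linkS4class{NormalizedTrace}}
#' @param CinUpper upper bound for Cin (default 0.5; set to 1 to allow the
#'   intracellular-majority branch)
#' @param nBoot residual-bootstrap replicates (default 1000; 0 disables)
#' @param bootSeed RNG seed for the bootstrap
#' @return a \code{\linkS4class{TurnoverFit}}
#' @examples
#' nt <- simulateTurnoverTrace(Cin = 0.3, k1 = 0.045)
#' coef(fitTurnover(nt, nBoot = 0))
#' @export
fitTurnover <- function(trace, CinUpper = 0.5, nBoot = 1000L, bootSeed = 1L) {
  stopifnot(is(trace, "NormalizedTrace"))
  post <- trace@t >= 0
  t <- trace@t[post]
  f <- trace@f[post]
  if (length(t) < 5L)
    mfStop("too few post-bleach frames for a 3-parameter fit", "validation")

  ## deterministic, derivative-free initialization
  plateau <- mean(utils::tail(f, max(3L, length(f) %/% 10L)))
  a <- min(max(plateau, 1e-3), 0.2499)
  cinInit <- min(max((1 - sqrt(1 - 4 * a)) / 2, 0.01), CinUpper - 0.01)
  iHalf <- which(f >= plateau / 2)[1]
  k1Init <- if (!is.na(iHalf) && t[iHalf] > 0) log(2) / t[iHalf] else
    1 / max(t[length(t)] / 3, 1e-6)

  model <- function(p, tt)
    (1 - p[1]) * p[1] * (exp(-p[3] * tt) - exp(-p[2] * tt))
  lower <- c(1e-4, 1e-6, 0)
  upper <- c(CinUpper, 100, 10)
  fitOnce <- function(y, start) {
    res <- minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p) y - model(p, t),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!res$info %in% 1:4)
      mfStop(sprintf("turnover fit did not converge: %s", res$message),
             "computation")
    res
  }
  res <- fitOnce(f, c(cinInit, k1Init, 1e-4))
  p <- res$par
  fitted <- model(p, t)
  rss <- sum((f - fitted)^2)
  se <- tryCatch({
    s <- summary(res)$coefficients[, "Std. Error"]
    stats::setNames(as.numeric(s), c("Cin", "k1", "kb"))
  }, error = function(e)
    stats::setNames(rep(NA_real_, 3), c("Cin", "k1", "kb")))

  flags <- character(0)
  sigma <- sqrt(rss / max(1L, length(t) - 3L))
  ## unrecovered amplitude at the last frame vs. the SEM of the trace end
  gap <- (1 - p[1]) * p[1] * exp(-p[2] * t[length(t)])
  if (gap > 2 * sigma / sqrt(length(t)))
    flags <- c(flags, "plateau_not_reached")

  parNames <- c("Cin", "k1", "kb")
  boot <- matrix(numeric(0), 0, 3, dimnames = list(NULL, parNames))
  ci <- matrix(NA_real_, 3, 2, dimnames = list(parNames, c("2.5%", "97.5%")))
  if (nBoot > 0L) {
    r0 <- f - fitted
    boot <- .withSeed(bootSeed, {
      t(vapply(seq_len(nBoot), function(b) {
        yb <- fitted + sample(r0, length(r0), replace = TRUE)
        tryCatch(fitOnce(yb, p)$par, error = function(e) rep(NA_real_, 3))
      }, numeric(3)))
    })
    colnames(boot) <- parNames
    ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE, names = FALSE))
    dimnames(ci) <- list(parNames, c("2.5%", "97.5%"))
  }

  est <- c(Cin = p[1], k1 = p[2], kb = p[3],
           R = 1 - p[1],
           kMinus1 = (1 / (1 - p[1]) - 1) * p[2],
           lifetime = 1 / p[2])
  new("TurnoverFit",
      estimates = est, se = se, rss = rss, nPoints = length(t),
      ci95 = ci, boot = boot, flags = flags,
      t = t, f = f, fitted = fitted)
}

#' Two-state kinetic oracle for the turnover model
#'
#' Numerically integrates the full two-state exchange system for the
#' fluorescent membrane and intracellular fractions after a whole-cell
#' bleach,
#' \deqn{dC^f_{mem}/dt = k_1 C^f_{in} - (k_{-1} + k_b) C^f_{mem}, \quad
#'       dC^f_{in}/dt = -k_1 C^f_{in} + k_{-1} C^f_{mem},}
#' with initial conditions \eqn{C^f_{in}(0) = C_{in}}, \eqn{C^f_{mem}(0)=0}.
#' Its recovery rate is \eqn{k_1 + k_{-1}} rather than the \eqn{k_1} of the
#' fitted closed form \code{\link{turnoverCurve}}; use
#' \code{\link{turnoverDiscrepancy}} to quantify the difference.
#'
#' @param tGrid output times (seconds, non-negative)
#' @param Cin,k1,kMinus1,kb model parameters (see
#'   \code{\link{turnoverCurve}}; \code{kMinus1} is the removal constant)
#' @param relTol relative tolerance of the adaptive integrator
#' @return data.frame with columns \code{t}, \code{Cinf}, \code{Cmemf}
#' @export
turnoverODE <- function(tGrid, Cin, k1, kMinus1, kb = 0, relTol = 1e-8) {
  .assertScalar(Cin, "Cin", 0, 1)
  .assertScalar(k1, "k1", 0, Inf, openLower = TRUE)
  .assertScalar(kMinus1, "kMinus1", 0, Inf)
  .assertScalar(kb, "kb", 0, Inf)
  if (any(tGrid < 0)) mfStop("tGrid must be non-negative", "validation")
  times <- sort(unique(c(0, tGrid)))
  rhs <- function(t, y, parms) {
    list(c(-k1 * y[1] + kMinus1 * y[2],
           k1 * y[1] - (kMinus1 + kb) * y[2]))
  }
  out <- tryCatch(
    deSolve::ode(c(Cinf = Cin, Cmemf = 0), times, rhs, parms = NULL,
                 rtol = relTol, atol = 1e-12),
    warning = function(w) mfStop(
      sprintf("ODE integration failed: %s", conditionMessage(w)),
      "computation"))
  out <- as.data.frame(out)
  names(out)[1] <- "t"
  out[match(tGrid, out$t), , drop = FALSE]
}

#' Discrepancy between the fitted closed form and the two-state oracle
#'
#' Maximum absolute difference between \code{\link{turnoverCurve}} and the
#' membrane-fraction trajectory of \code{\link{turnoverODE}} over a time
#' window — the model-simplification error incurred by fitting the closed
#' form whose recovery rate is \eqn{k_1} instead of \eqn{k_1 + k_{-1}}.
#'
#' @inheritParams turnoverODE
#' @param tMax window end (seconds)
#' @param n grid points
#' @return list with \code{maxAbs}, \code{tAtMax} and the comparison grid
#' @export
turnoverDiscrepancy <- function(Cin, k1, kMinus1, kb = 0, tMax = 300,
                                n = 601L) {
  tg <- seq(0, tMax, length.out = n)
  ode <- turnoverODE(tg, Cin, k1, kMinus1, kb)
  cf <- turnoverCurve(tg, Cin, k1, kb)
  d <- abs(ode$Cmemf - cf)
  list(maxAbs = max(d), tAtMax = tg[which.max(d)],
       grid = data.frame(t = tg, closedForm = cf, ode = ode$Cmemf))
}
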