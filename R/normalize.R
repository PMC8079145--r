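#' Normalize a raw FRAP trace
#'
#' Converts one bleach-ROI trace of a \code{\linkS4class{RoiTraceSet}} into a
#' normalized FRAP curve. Per frame the background-corrected ratio
#' \deqn{F_{NOR} = (F_{BL} - F_{BKG}) / (F_{REF} - F_{BKG})}
#' is computed; the \eqn{F_{NOR}} value of the first post-bleach frame is then
#' subtracted from all frames, and all frames are divided by the mean of the
#' (already-subtracted) \code{nBaseline} pre-bleach values. The result is 0
#' exactly at the first post-bleach frame and averages 1 over the baseline
#' window; time is re-expressed as seconds since bleach end.
#'
#' @param raw a \code{\linkS4class{RoiTraceSet}}
#' @param roi bleach-ROI index or name (default: first ROI)
#' @param nBaseline number of pre-bleach frames defining the baseline
#'   (default 40)
#' @return a \code{\linkS4class{NormalizedTrace}}
#' @examples
#' tr <- simulateTurnoverTrace(Cin = 0.3, k1 = 0.045, rawChannels = TRUE)
#' nt <- normalizeTrace(tr)
#' @export
normalizeTrace <- function(raw, roi = 1L, nBaseline = 40L) {
  stopifnot(is(raw, "RoiTraceSet"))
  if (is.character(roi)) roi <- match(roi, roiNames(raw))
  if (is.na(roi) || roi < 1L || roi > ncol(raw@bleach))
    mfStop("unknown bleach ROI", "validation")
  be <- raw@bleachEnd
  if (be - 1L < nBaseline)
    mfStop(sprintf(
      "need at least %d pre-bleach frames, found %d", nBaseline, be - 1L),
      "validation")
  denom <- raw@reference - raw@background
  if (any(denom <= 0))
    mfStop("f_reference <= f_background (reference bleached out)",
           "validation")
  fnor <- (raw@bleach[, roi] - raw@background) / denom
  fnor <- fnor - fnor[be]
  base <- mean(fnor[(be - nBaseline):(be - 1L)])
  if (base <= 0)
    mfStop("pre-bleach baseline is non-positive after offset subtraction",
           "computation")
  newNormalizedTrace(
    t = raw@time - raw@time[be],
    f = fnor / base,
    nBaseline = nBaseline,
    source = colnames(raw@bleach)[roi],
    condition = raw@condition)
}

## Linear interpolation of a trace's f onto a target time grid. Grids are
## protocol-fixed, so extrapolation beyond the source range is an error.
.interpTrace <- function(trace, tOut, tol = 1e-9) {
  if (length(trace@t) == length(tOut) &&
      max(abs(trace@t - tOut)) <= tol * max(1, max(abs(tOut))))
    return(trace@f)
  rng <- range(trace@t)
  if (min(tOut) < rng[1] - tol || max(tOut) > rng[2] + tol)
    mfStop("trace grids cannot be aligned: target grid extends beyond source",
           "validation")
  stats::approx(trace@t, trace@f, xout = tOut, rule = 2)$y
}

#' Paired-trial drift correction
#'
#' FRAP protocols that record pairs of trials (a control cycle followed by a
#' treatment cycle) allow correction for non-specific, use-dependent drift.
#' Because acquisition photobleaching and expression drift act
#' multiplicatively on fluorescence, the default correction divides the
#' second treatment trial, pointwise over post-bleach frames, by the drift
#' ratio observed in the control pair (second control / first control); a
#' difference-based correction is available as an alternative. Where the
#' ratio denominator (first control) is below \code{clampThreshold} the
#' correction is withheld and the frame flagged.
#'
#' @param treat1,treat2 first and second treatment trials
#'   (\code{\linkS4class{NormalizedTrace}}); \code{treat1} is carried as the
#'   within-pair reference and is not modified
#' @param ctrl1,ctrl2 first and second control trials
#' @param method \code{"ratio"} (default) or \code{"difference"}
#' @param clampThreshold minimum |first control| for the ratio correction
#' @return corrected second treatment trial as a
#'   \code{\linkS4class{NormalizedTrace}} with per-frame flags
#' @export
pairCorrect <- function(treat1, treat2, ctrl1, ctrl2,
                        method = c("ratio", "difference"),
                        clampThreshold = 0.05) {
  method <- match.arg(method)
  for (tr in list(treat1, treat2, ctrl1, ctrl2))
    stopifnot(is(tr, "NormalizedTrace"))
  tOut <- treat2@t
  c1 <- .interpTrace(ctrl1, tOut)
  c2 <- .interpTrace(ctrl2, tOut)
  f <- treat2@f
  flag <- treat2@flag
  post <- tOut >= 0
  if (method == "ratio") {
    unstable <- post & abs(c1) < clampThreshold
    ok <- post & !unstable
    f[ok] <- f[ok] / (c2[ok] / c1[ok])
    flag <- flag | unstable
  } else {
    f[post] <- f[post] - (c2[post] - c1[post])
  }
  ## re-anchor: the corrected trace must keep its defining offsets
  i0 <- which(tOut == 0)
  f[i0] <- 0
  newNormalizedTrace(tOut, f, flag, treat2@nBaseline,
                     source = treat2@source, condition = treat2@condition)
}

#' Average replicate FRAP traces
#'
#' Pointwise mean of replicate normalized traces sharing a common time grid,
#' with a per-frame dispersion band: the standard error of the mean and a
#' seeded percentile-bootstrap 95\% interval over replicates.
#'
#' @param traces list of \code{\linkS4class{NormalizedTrace}} on a common grid
#' @param nBoot bootstrap resamples (default 1000; 0 disables the interval)
#' @param seed RNG seed for the bootstrap
#' @return a \code{\linkS4class{NormalizedTrace}} carrying \code{sem},
#'   \code{ciLow} and \code{ciHigh}; with a single input trace the dispersion
#'   is NA and the trace is flagged
#' @export
averageTraces <- function(traces, nBoot = 1000L, seed = 1L) {
  if (!length(traces))
    mfStop("no traces to average", "validation")
  for (tr in traces) stopifnot(is(tr, "NormalizedTrace"))
  t0 <- traces[[1]]@t
  fm <- vapply(traces, .interpTrace, numeric(length(t0)), tOut = t0)
  fm <- matrix(fm, nrow = length(t0))
  n <- ncol(fm)
  mu <- rowMeans(fm)
  if (n >= 2L) {
    sem <- apply(fm, 1, stats::sd) / sqrt(n)
    if (nBoot > 0L) {
      ci <- .withSeed(seed, {
        bootMu <- vapply(seq_len(nBoot), function(b)
          rowMeans(fm[, sample.int(n, n, replace = TRUE), drop = FALSE]),
          numeric(length(t0)))
        apply(matrix(bootMu, nrow = length(t0)), 1,
              stats::quantile, probs = c(0.025, 0.975), names = FALSE)
      })
      lo <- ci[1, ]; hi <- ci[2, ]
    } else lo <- hi <- rep(NA_real_, length(t0))
    flag <- rep(FALSE, length(t0))
  } else {
    sem <- lo <- hi <- rep(NA_real_, length(t0))
    flag <- rep(TRUE, length(t0))  # dispersion undefined
  }
  newNormalizedTrace(t0, mu, flag, traces[[1]]@nBaseline,
                     source = sprintf("mean of %d traces", n),
                     condition = traces[[1]]@condition,
                     sem = sem, ciLow = lo, ciHigh = hi)
}
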