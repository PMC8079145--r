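#' @describeIn nFrames frame count of a trace set
#' @export
setMethod("nFrames", "RoiTraceSet", function(x) length(x@time))

#' @describeIn roiNames bleach-ROI column names
#' @export
setMethod("roiNames", "RoiTraceSet", function(x) colnames(x@bleach))

#' @describeIn bleachEnd first post-bleach frame index
#' @export
setMethod("bleachEnd", "RoiTraceSet", function(x) x@bleachEnd)

#' @describeIn lambdaDensity clusters per um^2
#' @export
setMethod("lambdaDensity", "ClusterSet", function(x, area) {
  if (missing(area)) area <- x@area
  if (!is.numeric(area) || length(area) != 1L || area <= 0)
    mfStop("area must be a single positive value (um^2)", "validation")
  nrow(x@centroids) / area
})

#' @describeIn clusterLabels per-point labels
#' @export
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)

#' @describeIn clusterCentroids centroid coordinates (nm)
#' @export
setMethod("clusterCentroids", "ClusterSet", function(x) x@centroids)

#' @describeIn channels channel names
#' @export
setMethod("channels", "LocalizationMap",
          function(x) levels(droplevels(x@channel)))

#' @describeIn qualityFlags flags of a normalized trace
#' @export
setMethod("qualityFlags", "NormalizedTrace", function(x) {
  if (any(x@flag)) "flagged_frames" else character(0)
})

#' @describeIn qualityFlags flags of a fit
#' @export
setMethod("qualityFlags", "FrapFit", function(x) x@flags)

#' @describeIn qualityFlags flags of a distance distribution
#' @export
setMethod("qualityFlags", "NNDistribution", function(x) x@flags)

#' @describeIn bootstrapCI percentile intervals
#' @export
setMethod("bootstrapCI", "FrapFit", function(x) x@ci95)

#' Parameter estimates of a FRAP fit
#' @param object a \code{\linkS4class{FrapFit}}
#' @param ... ignored
#' @return named numeric vector of free and derived parameters
#' @export
setMethod("coef", "FrapFit", function(object, ...) object@estimates)

#' Residuals of a FRAP fit over the fitted frames
#' @param object a \code{\linkS4class{FrapFit}}
#' @param ... ignored
#' @return numeric vector
#' @export
setMethod("residuals", "FrapFit", function(object, ...) object@f - object@fitted)

setMethod("show", "RoiTraceSet", function(object) {
  cat(sprintf(
    "RoiTraceSet: %d frames, %d bleach ROI(s) [%s]\n",
    nFrames(object), ncol(object@bleach),
    paste(roiNames(object), collapse = ", ")))
  dt <- if (nFrames(object) > 1) mean(diff(object@time)) else NA_real_
  cat(sprintf("  frame interval %.4g s; first post-bleach frame %d\n",
              dt, object@bleachEnd))
  if (nzchar(object@condition))
    cat(sprintf("  condition: %s\n", object@condition))
})

setMethod("show", "NormalizedTrace", function(object) {
  cat(sprintf(
    "NormalizedTrace: %d frames (%d pre-bleach baseline), t in [%.4g, %.4g] s\n",
    length(object@t), object@nBaseline, min(object@t), max(object@t)))
  if (any(object@flag))
    cat(sprintf("  %d flagged frame(s)\n", sum(object@flag)))
  if (length(object@sem))
    cat("  carries SEM and bootstrap 95% band (averaged trace)\n")
})

setMethod("show", "TurnoverFit", function(object) {
  e <- object@estimates
  cat("Two-compartment membrane turnover fit\n")
  cat(sprintf("  Cin = %.4g, k1 = %.4g /s, kb = %.4g /s\n",
              e[["Cin"]], e[["k1"]], e[["kb"]]))
  cat(sprintf("  derived: R = %.4g, k-1 = %.4g /s, membrane lifetime = %.4g s\n",
              e[["R"]], e[["kMinus1"]], e[["lifetime"]]))
  cat(sprintf("  rss = %.4g over %d frames\n", object@rss, object@nPoints))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "SoumpasisFit", function(object) {
  e <- object@estimates
  cat("Soumpasis circular-spot diffusion fit\n")
  cat(sprintf("  Cmob = %.4g, tauD = %.4g s (w = %.4g um)\n",
              e[["Cmob"]], e[["tauD"]], e[["w"]]))
  cat(sprintf("  D = %.4g um^2/s, D* = Cmob*D = %.4g um^2/s\n",
              e[["D"]], e[["Dstar"]]))
  cat(sprintf("  rss = %.4g over %d frames\n", object@rss, object@nPoints))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "LocalizationMap", function(object) {
  tab <- table(droplevels(object@channel))
  cat(sprintf("LocalizationMap: %d points over %.4g um^2\n",
              length(object@x), object@fieldArea))
  for (ch in names(tab)) cat(sprintf("  %s: %d\n", ch, tab[[ch]]))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf(
    "ClusterSet (%s): %d clusters, %d/%d points clustered\n",
    object@channel, nrow(object@centroids),
    sum(object@labels > 0L), length(object@labels)))
  cat(sprintf("  eps = %g nm, minPts = %d, lambda = %.4g per um^2\n",
              object@eps, object@minPts, lambdaDensity(object)))
})

setMethod("show", "NNDistribution", function(object) {
  cat(sprintf(
    "NNDistribution: %d distances, %g nm bins up to %g nm\n",
    object@nDistances, object@binWidth, object@cutoff))
  if (length(object@nullCdf))
    cat(sprintf("  Poisson null attached (lambda = %.4g per um^2)\n",
                object@lambda))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Coerce a normalized trace to a data frame
#'
#' @param x a \code{\linkS4class{NormalizedTrace}}
#' @param ... ignored
#' @return data.frame with columns \code{t_s}, \code{f}, \code{flag} and,
#'   for averaged traces, \code{sem}, \code{ci_low}, \code{ci_high}
#' @export
as.data.frame.NormalizedTrace <- function(x, ...) {
  out <- data.frame(t_s = x@t, f = x@f, flag = x@flag)
  if (length(x@sem)) {
    out$sem <- x@sem
    out$ci_low <- x@ciLow
    out$ci_high <- x@ciHigh
  }
  out
}
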