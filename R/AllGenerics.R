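#' Number of frames in a trace set
#' @param x a \code{\linkS4class{RoiTraceSet}}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' ROI identifiers of the bleach traces
#' @param x a \code{\linkS4class{RoiTraceSet}}
#' @return character vector of ROI ids
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' Index of the first post-bleach frame
#' @param x a \code{\linkS4class{RoiTraceSet}}
#' @return integer frame index
#' @export
setGeneric("bleachEnd", function(x) standardGeneric("bleachEnd"))

#' Cluster surface density
#'
#' Number of detected clusters per square micron of analysed membrane area.
#'
#' @param x a \code{\linkS4class{ClusterSet}}
#' @param area analysis area in um^2; defaults to the area stored in \code{x}
#' @return numeric, clusters per um^2
#' @export
setGeneric("lambdaDensity", function(x, area) standardGeneric("lambdaDensity"))

#' Per-point cluster labels (0 = noise)
#' @param x a \code{\linkS4class{ClusterSet}}
#' @return integer vector
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Cluster centroids in nm
#' @param x a \code{\linkS4class{ClusterSet}}
#' @return numeric matrix (clusters x 2)
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))

#' Channels present in a localization map
#' @param x a \code{\linkS4class{LocalizationMap}}
#' @return character vector of channel names
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Quality flags attached to a result
#' @param x a fit, trace or distribution object
#' @return character vector (possibly empty)
#' @export
setGeneric("qualityFlags", function(x) standardGeneric("qualityFlags"))

#' Bootstrap 95\% confidence intervals of a fit
#' @param x a \code{\linkS4class{FrapFit}}
#' @return numeric matrix (parameters x 2); NA when bootstrapping was disabled
#' @export
setGeneric("bootstrapCI", function(x) standardGeneric("bootstrapCI"))
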