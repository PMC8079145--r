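#' @import methods
NULL

## Relative tolerance for the uniform-time-grid check (fraction of the mean
## frame interval). Frame intervals are hardware-fixed, so 1% is generous.
.GRID_TOL <- 0.01

#' Raw ROI fluorescence traces from a FRAP acquisition
#'
#' Per-frame mean intensities for one or more bleach ROIs together with the
#' background and reference ROIs required for normalization, plus acquisition
#' metadata. Time is stored relative to acquisition start; conversion to
#' time-since-bleach happens in \code{\link{normalizeTrace}} so the raw record
#' stays immutable.
#'
#' @slot time numeric, seconds per frame (strictly increasing, uniform grid).
#' @slot bleach numeric matrix, frames x ROIs, arbitrary fluorescence units;
#'   column names are ROI identifiers.
#' @slot background numeric, background ROI intensity per frame (a.u.).
#' @slot reference numeric, reference ROI intensity per frame (a.u.).
#' @slot bleachEnd integer, frame index of the first post-bleach frame.
#' @slot pixelSize numeric, microns per pixel (NA if unknown).
#' @slot roiRadius numeric, bleach-ROI radius in microns, one value per ROI
#'   (NA if unknown).
#' @slot condition character, free-text condition label.
#'
#' @exportClass RoiTraceSet
setClass("RoiTraceSet",
  representation(
    time = "numeric",
    bleach = "matrix",
    background = "numeric",
    reference = "numeric",
    bleachEnd = "integer",
    pixelSize = "numeric",
    roiRadius = "numeric",
    condition = "character"
  )
)

setValidity("RoiTraceSet", function(object) {
  n <- length(object@time)
  msg <- character(0)
  if (nrow(object@bleach) != n)
    msg <- c(msg, "bleach matrix must have one row per frame")
  if (length(object@background) != n || length(object@reference) != n)
    msg <- c(msg, "background and reference must have one value per frame")
  if (n >= 2) {
    dt <- diff(object@time)
    if (any(dt <= 0))
      msg <- c(msg, "time must be strictly increasing")
    else if ((max(dt) - min(dt)) > .GRID_TOL * mean(dt))
      msg <- c(msg, sprintf(
        "time grid is non-uniform beyond %.0f%% tolerance", 100 * .GRID_TOL))
  }
  if (length(object@bleachEnd) != 1L || is.na(object@bleachEnd) ||
      object@bleachEnd < 1L || object@bleachEnd > n)
    msg <- c(msg, "bleachEnd must be a frame index within the record")
  nr <- length(object@roiRadius)
  if (!(nr %in% c(1L, ncol(object@bleach))))
    msg <- c(msg, "roiRadius must have one value, or one per bleach ROI")
  if (any(!is.na(object@roiRadius) & object@roiRadius <= 0))
    msg <- c(msg, "roiRadius must be positive")
  if (length(msg)) msg else TRUE
})

#' Normalized FRAP trace
#'
#' Background-corrected, baseline- and offset-normalized fluorescence versus
#' time since the end of the photobleaching pulse. Pre-bleach frames carry
#' negative time; the first post-bleach frame (t = 0) is 0 exactly and the
#' mean over the \code{nBaseline} pre-bleach frames is 1.
#'
#' @slot t numeric, seconds since bleach end.
#' @slot f numeric, dimensionless fluorescence.
#' @slot flag logical per frame; TRUE marks frames where a correction was
#'   withheld or unreliable (e.g. near-zero drift denominator).
#' @slot nBaseline integer, number of pre-bleach frames used for baseline.
#' @slot source character, provenance (source trace / ROI id).
#' @slot condition character, condition label.
#' @slot sem numeric, per-frame standard error (averaged traces; length 0
#'   otherwise).
#' @slot ciLow,ciHigh numeric, per-frame bootstrap 95% interval (averaged
#'   traces; length 0 otherwise).
#'
#' @exportClass NormalizedTrace
setClass("NormalizedTrace",
  representation(
    t = "numeric",
    f = "numeric",
    flag = "logical",
    nBaseline = "integer",
    source = "character",
    condition = "character",
    sem = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric"
  )
)

setValidity("NormalizedTrace", function(object) {
  msg <- character(0)
  n <- length(object@t)
  if (length(object@f) != n || length(object@flag) != n)
    msg <- c(msg, "t, f and flag must have equal length")
  if (n >= 2 && any(diff(object@t) <= 0))
    msg <- c(msg, "t must be strictly increasing")
  i0 <- which(object@t == 0)
  if (length(i0) != 1L)
    msg <- c(msg, "exactly one frame must sit at t = 0 (bleach end)")
  else if (abs(object@f[i0]) > 1e-9)
    msg <- c(msg, "f at the first post-bleach frame must be 0")
  nb <- object@nBaseline
  if (length(i0) == 1L && nb > 0L) {
    pre <- which(object@t < 0)
    if (length(pre) < nb)
      msg <- c(msg, "fewer pre-bleach frames than nBaseline")
    else {
      base <- utils::tail(pre, nb)
      if (abs(mean(object@f[base]) - 1) > 1e-9)
        msg <- c(msg, "baseline mean must equal 1 within 1e-9")
    }
  }
  for (s in c("sem", "ciLow", "ciHigh"))
    if (!length(slot(object, s)) %in% c(0L, n))
      msg <- c(msg, sprintf("%s must be empty or one value per frame", s))
  if (length(msg)) msg else TRUE
})

#' Virtual parent for FRAP model fits
#'
#' Common diagnostics shared by \code{\linkS4class{TurnoverFit}} and
#' \code{\linkS4class{SoumpasisFit}}: parameter estimates, standard errors,
#' residual sum of squares, bootstrap replicates and percentile intervals.
#'
#' @slot estimates named numeric, free and derived parameter estimates.
#' @slot se named numeric, asymptotic standard errors of the free parameters.
#' @slot rss numeric, residual sum of squares over the fitted frames.
#' @slot nPoints integer, number of fitted frames.
#' @slot ci95 numeric matrix (parameters x 2), percentile bootstrap interval
#'   (all NA when bootstrapping was disabled).
#' @slot boot numeric matrix (replicates x parameters) of bootstrap
#'   re-estimates (0 rows when disabled).
#' @slot flags character, quality flags (e.g. "plateau_not_reached").
#' @slot t,f,fitted numeric, the fitted frames and the model prediction.
#'
#' @exportClass FrapFit
setClass("FrapFit",
  representation(
    estimates = "numeric",
    se = "numeric",
    rss = "numeric",
    nPoints = "integer",
    ci95 = "matrix",
    boot = "matrix",
    flags = "character",
    t = "numeric",
    f = "numeric",
    fitted = "numeric",
    "VIRTUAL"
  )
)

#' Whole-cell membrane turnover fit
#'
#' Result of fitting the two-compartment membrane/cytosol exchange model to a
#' normalized whole-cell FRAP trace. Estimates: \code{Cin} (intracellular
#' fraction), \code{k1} (insertion rate constant, 1/s), \code{kb} (residual
#' photobleaching rate, 1/s), and derived \code{R = 1 - Cin},
#' \code{kMinus1 = (1/R - 1) k1} and \code{lifetime = 1/k1} (s).
#'
#' @exportClass TurnoverFit
setClass("TurnoverFit", contains = "FrapFit")

setValidity("TurnoverFit", function(object) {
  e <- object@estimates
  msg <- character(0)
  need <- c("Cin", "k1", "kb", "R", "kMinus1", "lifetime")
  if (!all(need %in% names(e)))
    return(paste("estimates must contain", paste(need, collapse = ", ")))
  if (abs(e[["lifetime"]] * e[["k1"]] - 1) > 1e-9)
    msg <- c(msg, "lifetime * k1 must equal 1")
  if (abs(e[["R"]] - (1 - e[["Cin"]])) > 1e-9)
    msg <- c(msg, "R must equal 1 - Cin")
  if (abs(e[["kMinus1"]] - (1 / e[["R"]] - 1) * e[["k1"]]) > 1e-9)
    msg <- c(msg, "kMinus1 must equal (1/R - 1) * k1")
  if (object@rss < 0) msg <- c(msg, "rss must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Soumpasis circular-spot diffusion fit
#'
#' Result of fitting the Soumpasis pure-diffusion recovery curve to a
#' normalized spot-FRAP trace. Estimates: \code{Cmob} (mobile fraction),
#' \code{tauD} (characteristic diffusion time, s), plus the derived
#' \code{D = w^2 / (4 tauD)} (um^2/s) and \code{Dstar = Cmob * D} for the
#' bleach-spot radius \code{w} (um) supplied to the fit.
#'
#' @exportClass SoumpasisFit
setClass("SoumpasisFit", contains = "FrapFit")

setValidity("SoumpasisFit", function(object) {
  e <- object@estimates
  msg <- character(0)
  need <- c("Cmob", "tauD", "w", "D", "Dstar")
  if (!all(need %in% names(e)))
    return(paste("estimates must contain", paste(need, collapse = ", ")))
  if (abs(e[["D"]] - e[["w"]]^2 / (4 * e[["tauD"]])) > 1e-9 * max(1, e[["D"]]))
    msg <- c(msg, "D must equal w^2 / (4 tauD)")
  if (abs(e[["Dstar"]] - e[["Cmob"]] * e[["D"]]) > 1e-9)
    msg <- c(msg, "Dstar must equal Cmob * D")
  if (e[["Cmob"]] < 0 || e[["Cmob"]] > 1 + 1e-9)
    msg <- c(msg, "Cmob must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' 2D molecular localization map
#'
#' A single-molecule localization table: planar coordinates in nanometres and
#' a channel label per point, plus the area of the analysed field in square
#' microns.
#'
#' @slot x,y numeric, coordinates in nm (finite, non-negative).
#' @slot channel factor, channel label per point.
#' @slot fieldArea numeric, analysed area in um^2.
#'
#' @exportClass LocalizationMap
setClass("LocalizationMap",
  representation(
    x = "numeric",
    y = "numeric",
    channel = "factor",
    fieldArea = "numeric"
  )
)

setValidity("LocalizationMap", function(object) {
  msg <- character(0)
  n <- length(object@x)
  if (length(object@y) != n || length(object@channel) != n)
    msg <- c(msg, "x, y and channel must have equal length")
  if (n > 0 && (!all(is.finite(object@x)) || !all(is.finite(object@y))))
    msg <- c(msg, "coordinates must be finite")
  if (n > 0 && (any(object@x < 0) || any(object@y < 0)))
    msg <- c(msg, "coordinates must be non-negative (nm)")
  if (length(object@fieldArea) != 1L || is.na(object@fieldArea) ||
      object@fieldArea <= 0)
    msg <- c(msg, "fieldArea must be a single positive value (um^2)")
  if (nlevels(droplevels(object@channel)) < 1L && n > 0)
    msg <- c(msg, "at least one point per referenced channel")
  if (length(msg)) msg else TRUE
})

#' Density-based clusters of a localization channel
#'
#' Output of \code{\link{dbscanClusters}}: per-point cluster labels (0 =
#' noise), cluster centroids and sizes, the clustering parameters, and the
#' cluster surface density lambda (clusters per um^2) over the analysis area.
#'
#' @slot labels integer per point; 0 marks noise.
#' @slot centroids numeric matrix (clusters x 2), nm.
#' @slot sizes integer, points per cluster.
#' @slot eps numeric, neighbourhood radius (nm).
#' @slot minPts integer, minimum neighbours (point itself included).
#' @slot area numeric, analysis area (um^2).
#' @slot channel character, clustered channel.
#'
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(
    labels = "integer",
    centroids = "matrix",
    sizes = "integer",
    eps = "numeric",
    minPts = "integer",
    area = "numeric",
    channel = "character"
  )
)

setValidity("ClusterSet", function(object) {
  msg <- character(0)
  k <- nrow(object@centroids)
  if (length(object@sizes) != k)
    msg <- c(msg, "one size per cluster required")
  if (k > 0 && any(object@sizes < object@minPts))
    msg <- c(msg, "every cluster must contain at least minPts points")
  if (length(object@labels) &&
      (min(object@labels) < 0L || max(object@labels) > k))
    msg <- c(msg, "labels must lie in 0..nClusters")
  if (object@area <= 0) msg <- c(msg, "area must be positive")
  if (length(msg)) msg else TRUE
})

#' Nearest-neighbour distance distribution
#'
#' Binned empirical cumulative distribution of nearest-neighbour distances up
#' to a cutoff, optionally paired with the 2D Poisson-null CDF
#' \code{D(r) = 1 - exp(-lambda pi r^2)} at the same bin edges.
#'
#' @slot breaks numeric, bin edges in nm (from 0 to the cutoff).
#' @slot counts integer, distances per bin.
#' @slot ecdf numeric, empirical CDF at the right bin edges (normalized to
#'   the number of retained distances).
#' @slot nullCdf numeric, Poisson-null CDF at the right bin edges (length 0
#'   when no density was supplied).
#' @slot cutoff,binWidth numeric, nm.
#' @slot nDistances integer, retained distances.
#' @slot lambda numeric, target density used for the null (per um^2; NA if
#'   none).
#' @slot flags character, e.g. "truncated_last_bin".
#'
#' @exportClass NNDistribution
setClass("NNDistribution",
  representation(
    breaks = "numeric",
    counts = "integer",
    ecdf = "numeric",
    nullCdf = "numeric",
    cutoff = "numeric",
    binWidth = "numeric",
    nDistances = "integer",
    lambda = "numeric",
    flags = "character"
  )
)

setValidity("NNDistribution", function(object) {
  msg <- character(0)
  nb <- length(object@breaks) - 1L
  if (length(object@counts) != nb || length(object@ecdf) != nb)
    msg <- c(msg, "counts and ecdf must have one value per bin")
  if (!length(object@nullCdf) %in% c(0L, nb))
    msg <- c(msg, "nullCdf must be empty or one value per bin")
  if (nb > 0) {
    if (any(diff(object@ecdf) < -1e-12) ||
        any(object@ecdf < -1e-12) || any(object@ecdf > 1 + 1e-12))
      msg <- c(msg, "ecdf must be nondecreasing within [0, 1]")
    if (length(object@nullCdf) &&
        (any(diff(object@nullCdf) < -1e-12) ||
         any(object@nullCdf < -1e-12) || any(object@nullCdf > 1 + 1e-12)))
      msg <- c(msg, "nullCdf must be nondecreasing within [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
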