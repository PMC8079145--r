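## Classed errors so callers (and the pipeline driver) can distinguish
## malformed input from numerical failure.
mfStop <- function(msg, type = c("validation", "format", "computation")) {
  type <- match.arg(type)
  cls <- switch(type,
    validation = "mfValidationError",
    format = "mfFormatError",
    computation = "mfComputationError")
  stop(structure(
    class = c(cls, "mfError", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

## Evaluate expr under a fixed RNG seed without disturbing the caller's
## RNG stream. seed = NULL leaves the stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    mfStop("seed must be a single finite number", "validation")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                          openLower = FALSE, openUpper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (openLower) x > lower else x >= lower) &&
    (if (openUpper) x < upper else x <= upper)
  if (!ok)
    mfStop(sprintf("%s must be a single finite value in %s%g, %g%s",
                   name,
                   if (openLower) "(" else "[", lower, upper,
                   if (openUpper) ")" else "]"),
           "validation")
  invisible(x)
}

## Construct a RoiTraceSet with defaulted metadata.
newRoiTraceSet <- function(time, bleach, background, reference, bleachEnd,
                           pixelSize = NA_real_, roiRadius = NA_real_,
                           condition = "") {
  if (is.null(dim(bleach))) bleach <- matrix(bleach, ncol = 1L)
  if (is.null(colnames(bleach)))
    colnames(bleach) <- paste0("roi", seq_len(ncol(bleach)))
  new("RoiTraceSet",
      time = as.numeric(time), bleach = bleach,
      background = as.numeric(background), reference = as.numeric(reference),
      bleachEnd = as.integer(bleachEnd),
      pixelSize = as.numeric(pixelSize), roiRadius = as.numeric(roiRadius),
      condition = as.character(condition))
}

## Construct a NormalizedTrace with defaulted slots.
newNormalizedTrace <- function(t, f, flag = rep(FALSE, length(t)),
                               nBaseline, source = "", condition = "",
                               sem = numeric(0), ciLow = numeric(0),
                               ciHigh = numeric(0)) {
  new("NormalizedTrace",
      t = as.numeric(t), f = as.numeric(f), flag = as.logical(flag),
      nBaseline = as.integer(nBaseline),
      source = as.character(source), condition = as.character(condition),
      sem = as.numeric(sem), ciLow = as.numeric(ciLow),
      ciHigh = as.numeric(ciHigh))
}
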