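## Run configuration is a JSON object (or an equivalent R list). Seeds and a
## config digest are embedded in every output file so reruns are diffable.

.readConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      mfStop(sprintf("config file not found: %s", config), "validation")
    list(cfg = jsonlite::read_json(config, simplifyVector = TRUE),
         digest = unname(tools::md5sum(config)))
  } else if (is.list(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
    list(cfg = config, digest = unname(tools::md5sum(tmp)))
  } else mfStop("config must be a path or a list", "validation")
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

.provenance <- function(digest, seed) {
  list(package = "memFRAP",
       version = as.character(utils::packageVersion("memFRAP")),
       configMd5 = digest, seed = seed)
}

.fitToList <- function(fit) {
  c(as.list(fit@estimates),
    list(se = as.list(fit@se), rss = fit@rss, nPoints = fit@nPoints,
         ci95 = apply(fit@ci95, 1, as.numeric, simplify = FALSE),
         flags = as.list(fit@flags)))
}

#' Run the FRAP analysis pipeline
#'
#' End-to-end run over one or more trace tables: read, normalize, fit (the
#' turnover model for whole-cell traces or the Soumpasis diffusion model for
#' spot traces) and, for diffusion runs with exactly two conditions, compare
#' them. All referenced files are validated before any computation; outputs
#' (per-trace normalized CSV and fit JSON, plus a \code{bundle.json}) carry
#' the config digest and seed, so a rerun with the same config is
#' byte-identical.
#'
#' Config fields: \code{traces} (array of \code{\{path, roi, bleach_end,
#' condition\}}), \code{mode} ("turnover" or "diffusion"),
#' \code{baseline_frames} (default 40), \code{spot_radius_um} (diffusion),
#' \code{n_boot} (default 0), \code{seed}.
#'
#' @param config path to a JSON run configuration, or an equivalent list
#' @param outDir output directory (created if missing)
#' @return the result bundle, invisibly (also written to
#'   \code{outDir/bundle.json})
#' @export
runFrapPipeline <- function(config, outDir) {
  rc <- .readConfig(config)
  cfg <- rc$cfg
  mode <- if (is.null(cfg$mode)) "turnover" else cfg$mode
  if (!mode %in% c("turnover", "diffusion"))
    mfStop("mode must be 'turnover' or 'diffusion'", "validation")
  nBaseline <- if (is.null(cfg$baseline_frames)) 40L
               else as.integer(cfg$baseline_frames)
  nBoot <- if (is.null(cfg$n_boot)) 0L else as.integer(cfg$n_boot)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  traces <- cfg$traces
  if (is.data.frame(traces)) traces <- split(traces, seq_len(nrow(traces)))
  if (!length(traces))
    mfStop("config lists no traces", "validation")
  for (tr in traces)
    if (!file.exists(tr$path))
      mfStop(sprintf("input trace not found: %s", tr$path), "validation")
  if (mode == "diffusion" && is.null(cfg$spot_radius_um))
    mfStop("spot_radius_um required for diffusion mode", "validation")

  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  message(sprintf("[memFRAP] %s pipeline: %d trace(s), seed %d",
                  mode, length(traces), seed))
  results <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    raw <- readTraceTable(
      tr$path,
      bleachEnd = if (is.null(tr$bleach_end)) NULL else tr$bleach_end,
      condition = if (is.null(tr$condition)) "" else tr$condition)
    nt <- normalizeTrace(raw, if (is.null(tr$roi)) 1L else tr$roi, nBaseline)
    fit <- if (mode == "turnover")
      fitTurnover(nt, nBoot = nBoot, bootSeed = seed + i)
    else
      fitSoumpasis(nt, w = cfg$spot_radius_um, nBoot = nBoot,
                   bootSeed = seed + i)
    base <- sprintf("trace%02d", i)
    utils::write.csv(as.data.frame(nt),
                     file.path(outDir, paste0(base, "_norm.csv")),
                     row.names = FALSE)
    .writeJson(c(.fitToList(fit),
                 list(input = tr$path,
                      condition = if (is.null(tr$condition)) "" else
                        tr$condition,
                      provenance = .provenance(rc$digest, seed))),
               file.path(outDir, paste0(base, "_fit.json")))
    results[[base]] <- list(fit = fit, trace = nt,
                            condition = if (is.null(tr$condition)) "" else
                              tr$condition)
  }
  bundle <- list(mode = mode,
                 fits = lapply(results, function(r)
                   c(.fitToList(r$fit), list(condition = r$condition))),
                 provenance = .provenance(rc$digest, seed))
  if (mode == "diffusion" && length(results) == 2L) {
    cmp <- compareConditions(results[[1]]$fit, results[[2]]$fit)
    bundle$comparison <- cmp[c("dCmob", "dDstar", "percentChange")]
  }
  .writeJson(bundle, file.path(outDir, "bundle.json"))
  invisible(bundle)
}

#' Run the SMLM spatial analysis pipeline
#'
#' Clusters the target channel of a localization table, computes the cluster
#' density lambda, collects nearest-neighbour distances from the source
#' channel to the cluster centroids (or a channel self-analysis when source
#' and target coincide), bins them, and compares the empirical distribution
#' with the Poisson null of the same density.
#'
#' Config fields: \code{localizations} (CSV path), \code{target_channel},
#' \code{source_channel}, \code{eps_nm} (default 100), \code{min_pts}
#' (default 50), \code{cutoff_nm} (default 500), \code{bin_nm} (default 5),
#' \code{field_area_um2} (optional), \code{n_sim} (default 999),
#' \code{seed}.
#'
#' @inheritParams runFrapPipeline
#' @return the result bundle, invisibly (also written to
#'   \code{outDir/bundle.json})
#' @export
runSmlmPipeline <- function(config, outDir) {
  rc <- .readConfig(config)
  cfg <- rc$cfg
  if (is.null(cfg$localizations))
    mfStop("config must name a localizations table", "validation")
  if (!file.exists(cfg$localizations))
    mfStop(sprintf("localization table not found: %s", cfg$localizations),
           "validation")
  eps <- if (is.null(cfg$eps_nm)) 100 else cfg$eps_nm
  minPts <- if (is.null(cfg$min_pts)) 50L else as.integer(cfg$min_pts)
  cutoff <- if (is.null(cfg$cutoff_nm)) 500 else cfg$cutoff_nm
  binW <- if (is.null(cfg$bin_nm)) 5 else cfg$bin_nm
  nSim <- if (is.null(cfg$n_sim)) 999L else as.integer(cfg$n_sim)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  map <- readLocalizations(
    cfg$localizations,
    fieldArea = if (is.null(cfg$field_area_um2)) NULL else cfg$field_area_um2)
  target <- if (is.null(cfg$target_channel)) channels(map)[1]
            else cfg$target_channel
  source <- if (is.null(cfg$source_channel)) target else cfg$source_channel
  message(sprintf("[memFRAP] smlm pipeline: %s -> %s clusters, seed %d",
                  source, target, seed))

  ## self analysis compares a channel with itself (no clustering step);
  ## otherwise source molecules are measured against target cluster centroids
  selfMode <- identical(source, target)
  if (selfMode) {
    clusters <- NULL
    d <- nnDistances(map, cutoff = cutoff, channel = source)
    nnLambda <- sum(map@channel == source) / map@fieldArea
  } else {
    clusters <- dbscanClusters(map, target, eps = eps, minPts = minPts)
    if (nrow(clusterCentroids(clusters)) == 0L)
      mfStop("no clusters found in the target channel", "computation")
    d <- nnDistances(map, to = clusters, cutoff = cutoff, channel = source)
    nnLambda <- lambdaDensity(clusters)
  }
  nnd <- nnDistribution(d, binWidth = binW, cutoff = cutoff,
                        lambda = nnLambda)
  cmp <- compareToNull(nnd, nSim = nSim, seed = seed)

  utils::write.csv(
    data.frame(r_nm = nnd@breaks[-1], count = nnd@counts,
               ecdf = nnd@ecdf, null_cdf = nnd@nullCdf),
    file.path(outDir, "nn_distribution.csv"), row.names = FALSE)
  bundle <- list(
    targetChannel = target, sourceChannel = source,
    nClusters = if (selfMode) NA else nrow(clusterCentroids(clusters)),
    lambdaPerUm2 = nnLambda, analysisAreaUm2 = map@fieldArea,
    nDistances = nnd@nDistances,
    comparison = cmp,
    parameters = list(eps_nm = eps, min_pts = minPts, cutoff_nm = cutoff,
                      bin_nm = binW, n_sim = nSim),
    provenance = .provenance(rc$digest, seed))
  .writeJson(bundle, file.path(outDir, "bundle.json"))
  invisible(bundle)
}
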