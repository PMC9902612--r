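utils::globalVariables(c("mean", "name", "lower", "upper"))

.fmtTime <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")
.parseTime <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Read and write the package's table formats
#'
#' Plain-CSV serialization of the fix, burst and transition-record tables
#' (timestamps as ISO-8601 local clock time), JSON serialization of the
#' structural-zero mask (object keyed `"region|from|to"` holding the masked
#' cells), the standardization spec, and [SimTruth-class] objects, and YAML
#' serialization of [SimConfig-class].
#'
#' @param x object to write.
#' @param path file path.
#' @rdname io
#' @export
writeFixes <- function(x, path) {
  x$timestamp <- .fmtTime(x$timestamp)
  utils::write.csv(x, path, row.names = FALSE)
}

#' @rdname io
#' @export
readFixes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- .parseTime(x$timestamp)
  x
}

#' @rdname io
#' @export
writeBursts <- function(x, path) writeFixes(x, path)

#' @rdname io
#' @export
readBursts <- function(path) readFixes(path)

#' @rdname io
#' @export
writeRecords <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' @rdname io
#' @export
readRecords <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname io
#' @export
writeMask <- function(x, path) {
  dn <- dimnames(x)
  masked <- character()
  for (r in dn[[1]]) for (i in dn[[2]]) for (j in dn[[3]])
    if (!x[r, i, j]) masked <- c(masked, paste(r, i, j, sep = "|"))
  jsonlite::write_json(list(dimnames = dn, masked = masked), path,
                       auto_unbox = FALSE, pretty = TRUE)
}

#' @rdname io
#' @export
readMask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- obj$dimnames
  mask <- array(TRUE, vapply(dn, length, 0L), dimnames = dn)
  for (key in obj$masked) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    mask[p[1], p[2], p[3]] <- FALSE
  }
  mask
}

#' @rdname io
#' @export
writeStandardization <- function(x, path)
  jsonlite::write_json(x, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)

#' @rdname io
#' @export
readStandardization <- function(path)
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))

#' @rdname io
#' @export
writeSimTruth <- function(x, path) {
  co <- x@coefficients
  obj <- list(
    habitats = co@habitats, baseline = co@baseline, regions = co@regions,
    intercepts = co@intercepts, hyperMeans = co@hyperMeans,
    diel = co@diel, time = co@time, forage = co@forage, walk = co@walk,
    stationary = co@stationary, temperature = co@temperature,
    covariateMoments = x@covariateMoments,
    realizedTransitionCounts = as.vector(x@realizedTransitionCounts))
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor",
                       dataframe = "columns", na = "null", pretty = TRUE)
}

.matToList <- function(m) lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
.listToMat <- function(l, dn) {
  m <- do.call(rbind, lapply(l, function(r)
    vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)))
  dimnames(m) <- dn
  m
}

#' @rdname io
#' @export
writeSimConfigYaml <- function(x, path) {
  co <- x@trueCoefficients
  obj <- list(
    habitats = x@habitats, regions = x@regions,
    regionHabitats = x@regionHabitats, baselineHabitat = x@baselineHabitat,
    nIndividuals = x@nIndividuals, nSteps = x@nSteps, pMissing = x@pMissing,
    burstPeriodMin = x@burstPeriodMin, fixPeriodMin = x@fixPeriodMin,
    behaviorAlpha = lapply(x@behaviorAlpha, as.list),
    tempParams = as.list(x@tempParams),
    startTime = .fmtTime(x@startTime), seed = x@seed,
    trueCoefficients = list(
      intercepts = .matToList(co@intercepts),
      hyperMeans = as.list(co@hyperMeans), diel = as.list(co@diel),
      time = as.list(co@time), forage = .matToList(co@forage),
      walk = .matToList(co@walk), stationary = .matToList(co@stationary),
      temperature = .matToList(co@temperature)))
  yaml::write_yaml(obj, path, precision = 15L)
}

#' @rdname io
#' @export
readSimConfigYaml <- function(path) {
  obj <- yaml::read_yaml(path)
  habitats <- unlist(obj$habitats); regions <- unlist(obj$regions)
  rh <- lapply(obj$regionHabitats, unlist)
  tc <- obj$trueCoefficients
  co <- transitionCoefficients(
    habitats, obj$baselineHabitat, regions, rh,
    intercepts = .listToMat(tc$intercepts, list(habitats, regions)),
    hyperMeans = unlist(tc$hyperMeans), diel = unlist(tc$diel),
    time = unlist(tc$time),
    forage = .listToMat(tc$forage, list(habitats, habitats)),
    walk = .listToMat(tc$walk, list(habitats, habitats)),
    stationary = .listToMat(tc$stationary, list(habitats, habitats)),
    temperature = .listToMat(tc$temperature, list(habitats, habitats)))
  simConfig(
    habitats = habitats, regions = regions, regionHabitats = rh,
    baselineHabitat = obj$baselineHabitat, trueCoefficients = co,
    nIndividuals = obj$nIndividuals, nSteps = obj$nSteps,
    pMissing = obj$pMissing, burstPeriodMin = obj$burstPeriodMin,
    fixPeriodMin = obj$fixPeriodMin,
    behaviorAlpha = lapply(obj$behaviorAlpha, function(a) unlist(a)),
    tempParams = unlist(obj$tempParams),
    startTime = .parseTime(obj$startTime), seed = obj$seed)
}

#' Write posterior draws and a run manifest
#'
#' Saves the draw matrix as CSV (one named column per coefficient plus the
#' log-likelihood trace) and a JSON manifest with seed, iteration counts,
#' record count and runtime.
#'
#' @param post a [TransitionPosterior-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writePosterior <- function(post, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  drawsPath <- file.path(dir, "draws.csv")
  manifestPath <- file.path(dir, "manifest.json")
  df <- as.data.frame(draws(post), check.names = FALSE)
  df$logLik <- post@logLik
  utils::write.csv(df, drawsPath, row.names = FALSE)
  jsonlite::write_json(post@meta, manifestPath, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(drawsPath, manifestPath))
}
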