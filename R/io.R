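## Readers and writers for the package's on-disk formats: radial profiles
## as 2-column CSV, parameter sets and recovery results as JSON, scalar
## maps as 32-bit TIFF + JSON sidecar. All outputs round-trip through the
## package's own readers.

#' Write / read a radial profile as CSV
#'
#' Two-column CSV `r,value` preceded by a one-line `# units:` header.
#'
#' @param profile a [RadialProfile-class].
#' @param path output / input file path.
#' @return `readRadialProfile` returns a [RadialProfile-class];
#'   `writeRadialProfile` returns `path` invisibly.
#' @export
writeRadialProfile <- function(profile, path) {
    stopifnot(is(profile, "RadialProfile"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# units: %s", profile@units), con)
    writeLines("r,value,count", con)
    writeLines(sprintf("%.17g,%.17g,%g", profile@r, profile@values,
                       profile@counts), con)
    invisible(path)
}

#' @rdname writeRadialProfile
#' @export
readRadialProfile <- function(path) {
    hdr <- readLines(path, n = 1L)
    units <- sub("^# units:\\s*", "", hdr)
    if (identical(units, hdr))
        stop("missing '# units:' header line in ", path)
    df <- utils::read.csv(path, skip = 1L)
    RadialProfile(df$r, df$value, units = units,
                  counts = if ("count" %in% names(df)) df$count
                           else rep(1, nrow(df)))
}

.paramsToList <- function(x) {
    sl <- methods::slotNames(class(x))
    out <- lapply(sl, function(s) methods::slot(x, s))
    names(out) <- sl
    out
}

#' Write / read parameter sets as JSON
#'
#' Serializes the parameter S4 classes ([PressureProfileParams-class],
#' [GrowthStressParams-class], [BoundaryStress-class],
#' [ElasticProperties-class], [TransportProperties-class],
#' [CohortSpec-class]) as a JSON object keyed by slot names, with a
#' `class` discriminator.
#'
#' @param x a parameter object.
#' @param path file path.
#' @return `readParams` returns the reconstructed object.
#' @export
writeParams <- function(x, path) {
    cls <- class(x)[1]
    ok <- c("PressureProfileParams", "GrowthStressParams", "BoundaryStress",
            "ElasticProperties", "TransportProperties", "CohortSpec")
    if (!cls %in% ok)
        stop("unsupported parameter class: ", cls)
    obj <- c(list(class = cls), .paramsToList(x))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cls <- obj$class
    obj$class <- NULL
    obj <- lapply(obj, function(v)
        if (is.null(v) || identical(v, "NA")) NA_real_ else v)
    ints <- c("nPerArm", "weeks", "seed")
    for (f in intersect(names(obj), ints)) obj[[f]] <- as.integer(obj[[f]])
    do.call(methods::new, c(list(Class = cls), obj))
}

#' Write / read a recovery result as JSON
#'
#' @param x a [RecoveryResult-class].
#' @param path file path.
#' @export
writeRecoveryResult <- function(x, path) {
    stopifnot(is(x, "RecoveryResult"))
    obj <- .paramsToList(x)
    obj$flags <- as.list(obj$flags)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeRecoveryResult
#' @export
readRecoveryResult <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("RecoveryResult", alphaHat = obj$alphaHat,
        amplitudeHat = obj$amplitudeHat, boundaryHat = obj$boundaryHat,
        ssnPeakHat = obj$ssnPeakHat, rss = obj$rss,
        nBins = as.integer(obj$nBins), converged = obj$converged,
        flags = as.character(unlist(obj$flags)), mode = obj$mode)
}

#' Write / read a scalar map as TIFF + JSON sidecar
#'
#' The value grid is stored as a single-channel 32-bit TIFF after affine
#' normalization to [0, 1]; the offset/scale, pixel spacing, units, mask
#' and metadata are stored in a JSON sidecar (TIFF resolution tags are
#' ignored), and the mask as an 8-bit TIFF. `pathPrefix` yields
#' `<prefix>.tif`, `<prefix>.mask.tif` and `<prefix>.json`. `NaN` pixels
#' (e.g. out-of-mask SSn) are recorded in the sidecar and restored on read.
#'
#' @param map a [ScalarMap-class].
#' @param pathPrefix path prefix for the three files.
#' @return `readScalarMap` returns a [ScalarMap-class];
#'   `writeScalarMap` returns the main TIFF path invisibly.
#' @export
writeScalarMap <- function(map, pathPrefix) {
    stopifnot(is(map, "ScalarMap"))
    v <- map@values
    nanMask <- !is.finite(v)
    v[nanMask] <- 0
    lo <- min(v); hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((v - lo) / scale, paste0(pathPrefix, ".tif"),
                    bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    side <- list(pixel_mm = map@pixelMm, units = map@units,
                 offset = lo, scale = scale,
                 shape = dim(map@values),
                 has_mask = length(map@mask) > 0,
                 nan_pixels = which(nanMask) - 1L,
                 metadata = map@metadata)
    jsonlite::write_json(side, paste0(pathPrefix, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (length(map@mask))
        tiff::writeTIFF(map@mask * 1, paste0(pathPrefix, ".mask.tif"),
                        bits.per.sample = 8L, compression = "none",
                        reduce = FALSE)
    invisible(paste0(pathPrefix, ".tif"))
}

#' @rdname writeScalarMap
#' @export
readScalarMap <- function(pathPrefix) {
    side <- jsonlite::read_json(paste0(pathPrefix, ".json"),
                                simplifyVector = TRUE)
    if (is.null(side$units))
        stop("sidecar of ", pathPrefix, " carries no units")
    v01 <- tiff::readTIFF(paste0(pathPrefix, ".tif"))
    v <- v01 * side$scale + side$offset
    if (length(side$nan_pixels))
        v[side$nan_pixels + 1L] <- NaN
    mask <- NULL
    if (isTRUE(side$has_mask))
        mask <- tiff::readTIFF(paste0(pathPrefix, ".mask.tif")) > 0.5
    meta <- side$metadata
    if (is.null(meta)) meta <- list()
    ScalarMap(v, pixelMm = side$pixel_mm, units = side$units, mask = mask,
              metadata = as.list(meta))
}

#' Write a cohort table as CSV
#'
#' @param cohort data.frame from [generateCohort()].
#' @param path file path.
#' @export
writeCohort <- function(cohort, path) {
    utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path)
    utils::read.csv(path, stringsAsFactors = FALSE)
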