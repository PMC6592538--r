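#' Render a perfusion map as a blue-to-red color overlay
#'
#' The dynamic-color convention of clinical fluorescence software: red for
#' the best-perfused region, blue for the least perfused. Pixels outside the
#' flap mask are black.
#'
#' @param map a \linkS4class{PerfusionMap}.
#' @param file optional PNG output path.
#' @param what \code{"ingress"} (default) or \code{"timeToPeak"} (rendered
#'   inverted: short time-to-peak = red).
#' @return Invisibly, an H x W x 3 RGB array in [0, 1].
#' @export
renderPerfusionMap <- function(map, file = NULL,
                               what = c("ingress", "timeToPeak")) {
    what <- match.arg(what)
    stopifnot(is(map, "PerfusionMap"))
    img <- if (what == "ingress") ingressMap(map) else -timeToPeakMap(map)
    mask <- mapMask(map)
    v <- img[mask]
    rng <- range(v)
    scaled <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else rep(0.5, length(v))
    ramp <- grDevices::colorRamp(c("#0000B0", "#00C0C0", "#00B000",
                                   "#E0E000", "#D00000"))
    rgbv <- ramp(scaled) / 255
    out <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
    for (ch in 1:3) {
        plane <- matrix(0, nrow(mask), ncol(mask))
        plane[mask] <- rgbv[, ch]
        out[, , ch] <- plane
    }
    if (!is.null(file))
        png::writePNG(out, file)
    invisible(out)
}

#' Write flap geometry as JSON plus mask TIFF
#'
#' @param geometry a \linkS4class{FlapGeometry}.
#' @param jsonPath output JSON path; the mask is written next to it.
#' @param maskPath optional explicit mask TIFF path.
#' @return Invisibly, \code{jsonPath}.
#' @export
writeFlapGeometry <- function(geometry, jsonPath,
                              maskPath = paste0(
                                  tools::file_path_sans_ext(jsonPath),
                                  "_mask.tif")) {
    stopifnot(is(geometry, "FlapGeometry"))
    tiff::writeTIFF(flapMask(geometry) * 1, maskPath, bits.per.sample = 8L)
    meta <- list(mask_path = basename(maskPath),
                 midline_col = midlineCol(geometry),
                 perforator = perforator(geometry),
                 pixel_size_mm = pixelSizeMm(geometry))
    jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(jsonPath)
}

#' Read flap geometry written by [writeFlapGeometry()]
#'
#' @param jsonPath JSON path; \code{mask_path} inside it is resolved relative
#'   to the JSON's directory.
#' @return A \linkS4class{FlapGeometry}.
#' @export
readFlapGeometry <- function(jsonPath) {
    if (!file.exists(jsonPath))
        stop("geometry file not found: ", jsonPath)
    meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    maskPath <- meta$mask_path
    if (!file.exists(maskPath))
        maskPath <- file.path(dirname(jsonPath), meta$mask_path)
    mask <- tiff::readTIFF(maskPath) > 0.5
    FlapGeometry(mask, midlineCol = meta$midline_col,
                 perforator = meta$perforator,
                 pixelSizeMm = if (is.null(meta$pixel_size_mm)) 1
                               else meta$pixel_size_mm)
}

#' Export a zone partition as a labelled TIFF
#'
#' Labels 0 (outside flap) to 4 (ROI 4), stored as an 8-bit image with
#' levels scaled by 1/255 so they survive the TIFF [0, 1] convention.
#'
#' @param zones a \linkS4class{ZoneSet}.
#' @param path output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
writeZoneSet <- function(zones, path) {
    stopifnot(is(zones, "ZoneSet"))
    tiff::writeTIFF(zoneLabels(zones) / 255, path, bits.per.sample = 8L)
    invisible(path)
}

#' Read a zone partition written by [writeZoneSet()]
#'
#' @param path labelled TIFF path.
#' @return A \linkS4class{ZoneSet}.
#' @export
readZoneSet <- function(path) {
    labels <- round(tiff::readTIFF(path) * 255)
    storage.mode(labels) <- "integer"
    new("ZoneSet", labels = labels)
}
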