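## Frame-stack I/O: multi-page TIFF plus a JSON sidecar carrying the frame
## rate and APU scale, and the 20-second standardization applied to every
## video before quantification.

.sidecarPath <- function(tiffPath) {
    paste0(tools::file_path_sans_ext(tiffPath), ".json")
}

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Pixel values are stored as 32-bit samples scaled to \code{[0, 1]} by
#' \code{apuMax}; the sidecar records \code{frame_rate_hz},
#' \code{start_time_s}, \code{apu_max} and \code{n_frames} so the stack can
#' be reconstructed exactly (up to the 32-bit quantization, about 1e-7 APU).
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param tiffPath output TIFF path.
#' @param jsonPath sidecar path; defaults to the TIFF path with a
#'   \code{.json} extension.
#' @return Invisibly, \code{tiffPath}.
#' @export
writeFrameStack <- function(stack, tiffPath,
                            jsonPath = .sidecarPath(tiffPath)) {
    stopifnot(is(stack, "FrameStack"))
    arr <- frames(stack) / apuMax(stack)
    pages <- lapply(seq_len(dim(arr)[3L]), function(i) arr[, , i])
    tiff::writeTIFF(pages, tiffPath, bits.per.sample = 32L, reduce = FALSE)
    meta <- list(frame_rate_hz = frameRate(stack),
                 start_time_s = frameTimes(stack)[1L],
                 apu_max = apuMax(stack),
                 n_frames = nFrames(stack))
    jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(tiffPath)
}

#' Read a frame stack written by [writeFrameStack()]
#'
#' @param tiffPath multi-page TIFF path.
#' @param jsonPath sidecar JSON path; defaults to the TIFF path with a
#'   \code{.json} extension.
#' @return A \linkS4class{FrameStack}.
#' @export
readFrameStack <- function(tiffPath, jsonPath = .sidecarPath(tiffPath)) {
    if (!file.exists(tiffPath))
        stop("TIFF file not found: ", tiffPath)
    if (!file.exists(jsonPath))
        stop("metadata sidecar not found: ", jsonPath)
    meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    req <- c("frame_rate_hz", "apu_max", "n_frames")
    missing <- setdiff(req, names(meta))
    if (length(missing))
        stop("sidecar is missing fields: ", paste(missing, collapse = ", "))
    pages <- tiff::readTIFF(tiffPath, all = TRUE)
    if (length(pages) != meta$n_frames)
        stop(sprintf("TIFF has %d pages but metadata declares %d frames",
                     length(pages), meta$n_frames))
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1L)
        stop("TIFF pages have non-uniform shapes")
    d <- dims[[1L]]
    arr <- array(unlist(pages, use.names = FALSE),
                 dim = c(d[1L], d[2L], length(pages)))
    FrameStack(arr * meta$apu_max, frameRate = meta$frame_rate_hz,
               apuMax = meta$apu_max)
}

#' Standardize a video to the common analysis window
#'
#' Clinical videos are compared over a fixed 20-second window from the start
#' of recording; frames at or beyond \code{duration} seconds are dropped
#' (half-open window \code{[0, duration)}). Retained pixel values and frame
#' times are untouched, so the operation is idempotent. A recording shorter
#' than \code{duration} fails the quality criteria and raises an error, which
#' mirrors the exclusion of too-short clinical recordings from analysis.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param duration window length (s); default 20.
#' @return The trimmed \linkS4class{FrameStack}.
#' @examples
#' geom <- defaultFlapGeometry(16, 32, perforator = c(8, 12))
#' sim <- simulateFlapVideo(geom, preset = 1, noiseSd = 0, seed = 1)
#' nFrames(trimToDuration(sim$stack))  # 80 frames = 20 s x 4 Hz
#' @export
trimToDuration <- function(stack, duration = 20) {
    stopifnot(is(stack, "FrameStack"))
    if (stackDuration(stack) < duration - 1e-9)
        stop(sprintf(paste0("recording lasts %.4g s, shorter than the %.4g-s ",
                            "analysis window: video fails quality criteria"),
                     stackDuration(stack), duration))
    keep <- frameTimes(stack) < duration - 1e-9
    if (all(keep))
        return(stack)
    FrameStack(frames(stack)[, , keep, drop = FALSE],
               frameRate = frameRate(stack), apuMax = apuMax(stack),
               frameTimes = frameTimes(stack)[keep])
}
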