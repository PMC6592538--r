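#' @import methods
NULL

## Central S4 containers. Fluorescence intensities are kept in "absolute
## perfusion units" (APU), the relative scale reported by clinical
## fluorescence-angiography systems; values are clipped to [0, apuMax].

#' FrameStack: a grayscale fluorescence video
#'
#' An H x W x T array of fluorescence intensities in absolute perfusion units
#' (APU) together with its frame times. Frame times start at 0 (recording is
#' synchronized with the dye injection) and are uniformly spaced.
#'
#' @slot frames numeric array, dim = c(H, W, T), values in [0, apuMax].
#' @slot frameTimes numeric vector of length T, seconds, starting at 0,
#'   strictly increasing and uniformly spaced.
#' @slot frameRate frames per second (Hz).
#' @slot apuMax upper bound of the APU scale (default 255).
#'
#' @aliases FrameStack-class
#' @exportClass FrameStack
setClass("FrameStack",
    representation(frames = "array", frameTimes = "numeric",
                   frameRate = "numeric", apuMax = "numeric"))

setValidity("FrameStack", function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L)
        return("'frames' must be a 3-dimensional (H x W x T) array")
    if (d[3L] < 2L)
        return("a frame stack needs at least 2 frames")
    if (length(object@frameTimes) != d[3L])
        return("length(frameTimes) must equal the number of frames")
    dt <- diff(object@frameTimes)
    if (any(dt <= 0))
        return("frame times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * mean(dt))
        return("frame times must be uniformly spaced")
    if (abs(object@frameTimes[1L]) > 1e-9)
        return("frame times must start at 0 (recording starts at injection)")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
        return("'frameRate' must be a single positive number")
    if (abs(object@frameRate * mean(dt) - 1) > 1e-6)
        return("'frameRate' is inconsistent with the frame time spacing")
    if (length(object@apuMax) != 1L || object@apuMax <= 0)
        return("'apuMax' must be a single positive number")
    rng <- range(object@frames)
    if (rng[1L] < -1e-9 || rng[2L] > object@apuMax + 1e-9)
        return("pixel values must lie in [0, apuMax]")
    TRUE
})

#' Construct a FrameStack
#'
#' @param frames H x W x T numeric array of APU values.
#' @param frameRate frames per second (Hz).
#' @param apuMax upper bound of the APU scale.
#' @param frameTimes optional frame times (seconds); defaults to
#'   \code{(0:(T-1)) / frameRate}.
#' @return A \linkS4class{FrameStack}.
#' @examples
#' arr <- array(runif(4 * 4 * 10, 0, 100), dim = c(4, 4, 10))
#' FrameStack(arr, frameRate = 4)
#' @export
FrameStack <- function(frames, frameRate, apuMax = 255,
                       frameTimes = NULL) {
    if (is.null(frameTimes))
        frameTimes <- (seq_len(dim(frames)[3L]) - 1L) / frameRate
    new("FrameStack", frames = frames, frameTimes = as.numeric(frameTimes),
        frameRate = as.numeric(frameRate), apuMax = as.numeric(apuMax))
}

#' FlapGeometry: flap mask, midline and perforator location
#'
#' Describes the geometry on which perfusion is analyzed: the flap mask, the
#' abdominal midline (a column coordinate; pixels with column index
#' \code{<= midlineCol} lie on one side, \code{> midlineCol} on the other)
#' and the emergence point of the main perforator.
#'
#' @slot mask logical H x W matrix, TRUE inside the flap.
#' @slot midlineCol numeric column coordinate of the midline (may be
#'   half-integer so that no pixel sits exactly on it).
#' @slot perforator integer c(row, col) of the perforator emergence point.
#' @slot pixelSizeMm physical pixel size in millimetres.
#'
#' @aliases FlapGeometry-class
#' @exportClass FlapGeometry
setClass("FlapGeometry",
    representation(mask = "matrix", midlineCol = "numeric",
                   perforator = "integer", pixelSizeMm = "numeric"))

setValidity("FlapGeometry", function(object) {
    if (!is.logical(object@mask))
        return("'mask' must be a logical matrix")
    if (!any(object@mask))
        return("flap mask is empty")
    if (length(object@midlineCol) != 1L ||
        object@midlineCol < 1 || object@midlineCol > ncol(object@mask))
        return("'midlineCol' must lie within the image width")
    p <- object@perforator
    if (length(p) != 2L || any(p < 1L) ||
        p[1L] > nrow(object@mask) || p[2L] > ncol(object@mask))
        return("'perforator' must be c(row, col) inside the image")
    if (!object@mask[p[1L], p[2L]])
        return("perforator point must lie inside the flap mask")
    if (length(object@pixelSizeMm) != 1L || object@pixelSizeMm <= 0)
        return("'pixelSizeMm' must be a single positive number")
    TRUE
})

#' Construct a FlapGeometry
#'
#' @param mask logical H x W matrix (TRUE inside the flap).
#' @param midlineCol column coordinate of the midline.
#' @param perforator c(row, col) of the perforator emergence point.
#' @param pixelSizeMm physical pixel size (mm); default 1.
#' @return A \linkS4class{FlapGeometry}.
#' @seealso [defaultFlapGeometry()] for the standard elliptical test geometry.
#' @export
FlapGeometry <- function(mask, midlineCol, perforator, pixelSizeMm = 1) {
    new("FlapGeometry", mask = mask, midlineCol = as.numeric(midlineCol),
        perforator = as.integer(perforator),
        pixelSizeMm = as.numeric(pixelSizeMm))
}

#' ZoneSet: the four Hartrampf-zone regions of interest
#'
#' A labelled image partitioning the flap mask into four regions of interest:
#' ROI 1 = peripheral flap end ipsilateral to the perforator (Hartrampf zone
#' III), ROI 2 = perforator emergence area (zone I), ROI 3 = area adjacent to
#' the perforator across the midline (zone II), ROI 4 = contralateral
#' peripheral end (zone IV).
#'
#' @slot labels integer H x W matrix with values 0 (outside flap) to 4.
#'
#' @aliases ZoneSet-class
#' @exportClass ZoneSet
setClass("ZoneSet", representation(labels = "matrix"))

setValidity("ZoneSet", function(object) {
    l <- object@labels
    if (!all(l %in% 0:4))
        return("zone labels must be integers in 0..4")
    TRUE
})

#' PerfusionCurve: a regional time-intensity curve
#'
#' Mean fluorescence over a region of interest at each frame time.
#'
#' @slot times frame times (seconds).
#' @slot values mean fluorescence (APU) at each time.
#'
#' @aliases PerfusionCurve-class
#' @exportClass PerfusionCurve
setClass("PerfusionCurve",
    representation(times = "numeric", values = "numeric"))

setValidity("PerfusionCurve", function(object) {
    if (length(object@times) != length(object@values))
        return("'times' and 'values' must have the same length")
    if (length(object@times) < 1L)
        return("empty curve")
    if (any(diff(object@times) <= 0))
        return("curve times must be strictly increasing")
    TRUE
})

#' Construct a PerfusionCurve
#'
#' @param times frame times (seconds).
#' @param values mean fluorescence values (APU).
#' @return A \linkS4class{PerfusionCurve}.
#' @export
PerfusionCurve <- function(times, values) {
    new("PerfusionCurve", times = as.numeric(times),
        values = as.numeric(values))
}

#' PerfusionMap: per-pixel ingress and time-to-peak images
#'
#' The per-pixel analogue of the regional perfusion parameters, used for
#' dynamic color analysis and perfusion-pattern classification. Pixels
#' outside the flap mask are NA.
#'
#' @slot ingress H x W matrix of per-pixel ingress (APU), NA outside the mask.
#' @slot timeToPeak H x W matrix of per-pixel time of peak fluorescence (s).
#' @slot mask logical H x W flap mask the map was computed on.
#'
#' @aliases PerfusionMap-class
#' @exportClass PerfusionMap
setClass("PerfusionMap",
    representation(ingress = "matrix", timeToPeak = "matrix",
                   mask = "matrix"))

setValidity("PerfusionMap", function(object) {
    if (!identical(dim(object@ingress), dim(object@mask)) ||
        !identical(dim(object@timeToPeak), dim(object@mask)))
        return("'ingress', 'timeToPeak' and 'mask' must share dimensions")
    v <- object@ingress[object@mask]
    if (any(!is.na(v) & v < -1e-9))
        return("ingress values must be non-negative")
    if (any(!is.na(object@ingress[!object@mask])))
        return("ingress must be NA outside the flap mask")
    TRUE
})

#' GroundTruth: the known kinetics behind a simulated video
#'
#' Returned alongside every simulated \linkS4class{FrameStack}: the true
#' per-pixel amplitude and bolus-arrival fields, the perfusion-pattern label
#' the simulation was generated from, and the true per-zone ingress values
#' (maximum of the noiseless zone-mean curve over the 20-s analysis window
#' minus the true baseline).
#'
#' @slot amplitude H x W matrix of true amplitudes A(x, y) (APU), 0 outside
#'   the flap mask.
#' @slot arrival H x W matrix of bolus arrival times (s), NA outside the mask.
#' @slot pattern integer pattern label in 1..3.
#' @slot zoneIngress named numeric vector of true ingress for roi1..roi4.
#'
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(amplitude = "matrix", arrival = "matrix",
                   pattern = "integer", zoneIngress = "numeric"))

setValidity("GroundTruth", function(object) {
    if (!object@pattern %in% 1:3)
        return("'pattern' must be 1, 2 or 3")
    if (any(object@amplitude < 0))
        return("amplitudes must be non-negative")
    TRUE
})

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf("FrameStack: %d x %d pixels, %d frames @ %.3g Hz (%.4g s)\n",
                d[1L], d[2L], d[3L], object@frameRate,
                d[3L] / object@frameRate))
    cat(sprintf("  APU range observed [%.4g, %.4g], scale max %.4g\n",
                min(object@frames), max(object@frames), object@apuMax))
})

setMethod("show", "FlapGeometry", function(object) {
    cat(sprintf(
        "FlapGeometry: %d x %d image, %d mask pixels (%.3g mm/px)\n",
        nrow(object@mask), ncol(object@mask), sum(object@mask),
        object@pixelSizeMm))
    cat(sprintf("  midline at column %.1f, perforator at (%d, %d)\n",
                object@midlineCol, object@perforator[1L],
                object@perforator[2L]))
})

setMethod("show", "ZoneSet", function(object) {
    n <- tabulate(object@labels[object@labels > 0L], nbins = 4L)
    cat("ZoneSet (Hartrampf zones):\n")
    cat(sprintf("  ROI %d (zone %s): %d px\n", 1:4,
                c("III", "I", "II", "IV"), n), sep = "")
})

setMethod("show", "PerfusionCurve", function(object) {
    cat(sprintf("PerfusionCurve: %d samples over [%.3g, %.3g] s, %s [%.4g, %.4g] APU\n",
                length(object@times), min(object@times), max(object@times),
                "range", min(object@values), max(object@values)))
})

setMethod("show", "PerfusionMap", function(object) {
    v <- object@ingress[object@mask]
    cat(sprintf("PerfusionMap: %d x %d, %d flap pixels\n",
                nrow(object@mask), ncol(object@mask), sum(object@mask)))
    cat(sprintf("  ingress [%.4g, %.4g] APU; time-to-peak [%.3g, %.3g] s\n",
                min(v), max(v), min(object@timeToPeak[object@mask]),
                max(object@timeToPeak[object@mask])))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: pattern %d\n", object@pattern))
    cat("  true zone ingress (APU):",
        paste(sprintf("%s=%.3g", names(object@zoneIngress),
                      object@zoneIngress), collapse = ", "), "\n")
})
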