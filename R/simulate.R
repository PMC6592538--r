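## Synthetic flap-video generator. Every simulated video carries closed-form
## ground truth (per-pixel amplitude and arrival fields, per-zone ingress,
## pattern label) so the downstream quantification and classification stages
## can be validated without clinical recordings.

withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(seed)
        return(expr)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Kinetic parameters of the simulated bolus passage
#'
#' Bundles the per-pixel gamma-variate kinetics and the spatial structure of
#' the simulated amplitude field: exponential decay with distance from the
#' perforator emergence point, a multiplicative attenuation for pixels across
#' the midline, and a multiplicative attenuation for the peripheral flap
#' ends.
#'
#' @param baseline tissue baseline fluorescence B (APU).
#' @param amplitude amplitude A0 at the perforator point (APU).
#' @param tArrival bolus arrival time t0 at the perforator (s).
#' @param timeToPeak rise time tp from arrival to peak (s).
#' @param shape gamma-variate shape alpha.
#' @param speed bolus propagation speed v through the flap (mm/s); arrival
#'   at distance d is t0 + d / v.
#' @param decayLength amplitude decay length lambda (mm): amplitude falls as
#'   exp(-d / lambda).
#' @param midlineFactor multiplicative attenuation m in (0, 1] applied to
#'   pixels on the opposite side of the midline from the perforator.
#' @param peripheralFactor multiplicative attenuation p in (0, 1] applied to
#'   pixels in the peripheral end bands of the flap.
#' @return A list of class \code{KineticsParams}.
#' @seealso [presetKinetics()] for the three pattern presets.
#' @export
kineticsParams <- function(baseline = 5, amplitude = 150, tArrival = 2,
                           timeToPeak = 5, shape = 2, speed = 20,
                           decayLength = 150, midlineFactor = 0.3,
                           peripheralFactor = 1) {
    stopifnot(baseline >= 0, amplitude > 0, timeToPeak > 0, shape > 0,
              speed > 0, decayLength > 0,
              midlineFactor > 0, midlineFactor <= 1,
              peripheralFactor > 0, peripheralFactor <= 1)
    structure(list(baseline = baseline, amplitude = amplitude,
                   tArrival = tArrival, timeToPeak = timeToPeak,
                   shape = shape, speed = speed, decayLength = decayLength,
                   midlineFactor = midlineFactor,
                   peripheralFactor = peripheralFactor),
              class = "KineticsParams")
}

#' @export
print.KineticsParams <- function(x, ...) {
    cat("KineticsParams:\n")
    cat(sprintf("  B = %.3g APU, A0 = %.3g APU, t0 = %.3g s, tp = %.3g s, alpha = %.3g\n",
                x$baseline, x$amplitude, x$tArrival, x$timeToPeak, x$shape))
    cat(sprintf("  v = %.3g mm/s, lambda = %.3g mm, midline m = %.3g, peripheral p = %.3g\n",
                x$speed, x$decayLength, x$midlineFactor, x$peripheralFactor))
    invisible(x)
}

#' Kinetics presets for the three perfusion patterns
#'
#' Returns kinetic parameters that emulate the three perfusion phenotypes
#' seen on dynamic color analysis of DIEP flaps:
#' \describe{
#'   \item{1}{homogeneous perfusion of the hemi-flap ipsilateral to the
#'     perforator, not crossing the midline: long decay length, strong
#'     midline attenuation, no peripheral attenuation.}
#'   \item{2}{perfusion confined to the perforator emergence area: short
#'     decay length.}
#'   \item{3}{homogeneous perfusion on both sides of the midline with poor
#'     perfusion of the peripheral flap ends: long decay length, no midline
#'     attenuation, strong peripheral attenuation.}
#' }
#'
#' @param preset pattern id, 1, 2 or 3.
#' @param ... overrides passed on to [kineticsParams()].
#' @return A \code{KineticsParams} list.
#' @export
presetKinetics <- function(preset, ...) {
    if (length(preset) != 1L || !preset %in% 1:3)
        stop("'preset' must be 1, 2 or 3")
    base <- switch(as.integer(preset),
        list(decayLength = 150, midlineFactor = 0.3, peripheralFactor = 1),
        list(decayLength = 30,  midlineFactor = 0.3, peripheralFactor = 1),
        list(decayLength = 200, midlineFactor = 1,   peripheralFactor = 0.1))
    do.call(kineticsParams, utils::modifyList(base, list(...)))
}

#' Standard simulated flap geometry
#'
#' An elliptical flap mask on a 128 x 256 image at 1 mm/pixel, midline at the
#' central column and the main perforator emerging in the middle of the
#' ipsilateral (left) hemi-flap — a desk-scale stand-in for the abdominal
#' field of view of a fluorescence-angiography camera.
#'
#' @param height,width image size in pixels.
#' @param perforator c(row, col) of the perforator point; default centred in
#'   the left hemi-flap.
#' @param pixelSizeMm pixel size (mm).
#' @return A \linkS4class{FlapGeometry}.
#' @export
defaultFlapGeometry <- function(height = 128, width = 256,
                                perforator = c(round(height / 2),
                                               round(3 * width / 8)),
                                pixelSizeMm = 1) {
    rc <- (height + 1) / 2
    cc <- (width + 1) / 2
    row <- matrix(seq_len(height), height, width)
    col <- matrix(seq_len(width), height, width, byrow = TRUE)
    mask <- ((row - rc) / (height / 2 - 0.5))^2 +
            ((col - cc) / (width / 2 - 0.5))^2 <= 1
    FlapGeometry(mask, midlineCol = cc, perforator = perforator,
                 pixelSizeMm = pixelSizeMm)
}

## Distance (mm) of every pixel from the perforator point.
.distanceField <- function(geometry) {
    mask <- flapMask(geometry)
    p <- perforator(geometry)
    row <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
    col <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
    sqrt((row - p[1L])^2 + (col - p[2L])^2) * pixelSizeMm(geometry)
}

## TRUE for pixels on the opposite side of the midline from the perforator.
.contralateralField <- function(geometry) {
    mask <- flapMask(geometry)
    col <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
    m <- midlineCol(geometry)
    perfLow <- perforator(geometry)[2L] <= m
    if (perfLow) col > m else col <= m
}

## TRUE for pixels in the outermost `fraction` of the flap length (columns)
## at each end.
.peripheralBand <- function(geometry, fraction = 0.15) {
    mask <- flapMask(geometry)
    cols <- range(which(colSums(mask) > 0L))
    len <- cols[2L] - cols[1L] + 1L
    bw <- floor(fraction * len)
    col <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
    col < cols[1L] + bw | col > cols[2L] - bw
}

#' Simulate a fluorescence angiography video of a DIEP flap
#'
#' Generates a frame stack with known per-pixel gamma-variate kinetics. The
#' true amplitude field is
#' \deqn{A(x, y) = A_0 \, e^{-d/\lambda} \, m^{[\mathrm{contralateral}]}
#'   \, p^{[\mathrm{peripheral\ band}]}}
#' with \code{d} the Euclidean distance from the perforator emergence point,
#' and the bolus arrives at \code{t0 + d / v}, quantized to the frame grid so
#' that every pixel's sampled time course attains its analytic peak
#' \code{B + A(x, y)} exactly on a recorded frame. Zero-mean Gaussian noise
#' of standard deviation \code{noiseSd} is added to every pixel of every
#' frame and values are clipped to \code{[0, apuMax]}. Pixels outside the
#' flap mask carry no signal.
#'
#' @param geometry a \linkS4class{FlapGeometry}.
#' @param preset perfusion-pattern preset (1, 2 or 3), used when
#'   \code{kinetics} is not supplied; also recorded as the ground-truth label.
#' @param kinetics a \code{KineticsParams}; defaults to
#'   \code{presetKinetics(preset)}.
#' @param noiseSd additive Gaussian noise standard deviation (APU).
#' @param frameRate frames per second (Hz).
#' @param duration recorded duration (s); must be >= 20 so the standard
#'   20-second trim is applicable.
#' @param seed integer seed for reproducibility; identical seeds give
#'   bit-identical output. The caller's RNG state is left untouched.
#' @param peripheralFraction width of each peripheral end band as a fraction
#'   of flap length.
#' @param apuMax APU scale maximum for clipping and storage.
#' @param baselineWindow number of initial frames used when computing the
#'   ground-truth per-zone ingress (they precede every bolus arrival at the
#'   defaults, so the true baseline is exact).
#' @return A list with elements \code{stack} (\linkS4class{FrameStack}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' geom <- defaultFlapGeometry(32, 64, perforator = c(16, 24))
#' sim <- simulateFlapVideo(geom, preset = 2, noiseSd = 0, seed = 1)
#' sim$stack
#' sim$truth
#' @export
simulateFlapVideo <- function(geometry = defaultFlapGeometry(),
                              preset = 1L,
                              kinetics = presetKinetics(preset),
                              noiseSd = 2, frameRate = 4, duration = 25,
                              seed = NULL, peripheralFraction = 0.15,
                              apuMax = 255, baselineWindow = 4L) {
    stopifnot(is(geometry, "FlapGeometry"))
    if (length(preset) != 1L || !preset %in% 1:3)
        stop("'preset' must be 1, 2 or 3")
    if (duration < 20)
        stop("'duration' must be at least 20 s (the standard analysis window)")
    if (noiseSd < 0)
        stop("'noiseSd' must be non-negative")
    k <- kinetics
    if (k$baseline + k$amplitude > apuMax)
        stop("baseline + amplitude exceeds the APU range")

    mask <- flapMask(geometry)
    H <- nrow(mask); W <- ncol(mask)
    nT <- round(duration * frameRate)
    times <- (seq_len(nT) - 1L) / frameRate

    d <- .distanceField(geometry)
    A <- k$amplitude * exp(-d / k$decayLength)
    contra <- .contralateralField(geometry)
    A[contra] <- A[contra] * k$midlineFactor
    band <- .peripheralBand(geometry, peripheralFraction)
    A[band] <- A[band] * k$peripheralFactor
    A[!mask] <- 0

    ## arrival quantized to the frame grid: the sampled maximum of each
    ## pixel's course is then exactly B + A(x,y)
    tArr <- round((k$tArrival + d / k$speed) * frameRate) / frameRate
    tArr[!mask] <- NA_real_

    idx <- which(mask)
    n <- length(idx)
    tm <- matrix(times, n, nT, byrow = TRUE)
    clean <- gammaVariate(tm, baseline = k$baseline, amplitude = A[idx],
                          tArrival = tArr[idx], timeToPeak = k$timeToPeak,
                          shape = k$shape)

    arr <- withSeed(seed, {
        a <- matrix(0, H * W, nT)
        a[idx, ] <- clean
        if (noiseSd > 0)
            a <- a + matrix(stats::rnorm(length(a), 0, noiseSd),
                            nrow(a), ncol(a))
        a
    })
    arr[arr < 0] <- 0
    arr[arr > apuMax] <- apuMax
    stack <- FrameStack(array(arr, dim = c(H, W, nT)), frameRate = frameRate,
                        apuMax = apuMax)

    ## ground-truth per-zone ingress from the noiseless signal restricted to
    ## the 20-s analysis window
    zones <- partitionZones(geometry)
    inWin <- times < 20 - 1e-9
    zi <- vapply(1:4, function(z) {
        zidx <- which(zoneMask(zones, z))
        rows <- match(zidx, idx)
        rows <- rows[!is.na(rows)]
        if (!length(rows))
            return(0)
        mcurve <- colMeans(clean[rows, inWin, drop = FALSE])
        max(mcurve) - k$baseline
    }, numeric(1))
    names(zi) <- paste0("roi", 1:4)

    truth <- new("GroundTruth", amplitude = A, arrival = tArr,
                 pattern = as.integer(preset), zoneIngress = zi)
    list(stack = stack, truth = truth)
}
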