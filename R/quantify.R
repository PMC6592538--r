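## Perfusion quantification: regional time-intensity curves and the two
## perfusion parameters reported by clinical fluorescence-angiography
## software — ingress (APU) and ingress rate (APU/s) — plus their per-pixel
## analogues for dynamic color analysis.

## Centered moving average of width 3 with shrinking windows at the ends.
## Applied before peak/onset detection only; the ingress difference itself
## uses raw values so that it agrees with a brute-force scan of the frames.
.smooth3 <- function(y) {
    n <- length(y)
    if (n < 3L)
        return(y)
    s <- (y + c(y[-1L], y[n]) + c(y[1L], y[-n])) / 3
    s[1L] <- (y[1L] + y[2L]) / 2
    s[n] <- (y[n - 1L] + y[n]) / 2
    s
}

## Matrix row-wise version of .smooth3 (rows = pixels, cols = frames).
.smooth3Rows <- function(X) {
    nT <- ncol(X)
    if (nT < 3L)
        return(X)
    S <- (X[, c(1L, seq_len(nT - 1L)), drop = FALSE] + X +
          X[, c(seq_len(nT - 1L) + 1L, nT), drop = FALSE]) / 3
    S[, 1L] <- (X[, 1L] + X[, 2L]) / 2
    S[, nT] <- (X[, nT - 1L] + X[, nT]) / 2
    S
}

#' Mean time-intensity curve over a region of interest
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param mask logical H x W region mask (non-empty).
#' @return A \linkS4class{PerfusionCurve}: the arithmetic mean of in-mask
#'   pixel values at each frame.
#' @export
roiMeanCurve <- function(stack, mask) {
    stopifnot(is(stack, "FrameStack"), is.logical(mask))
    d <- dim(frames(stack))
    if (!identical(dim(mask), d[1:2]))
        stop("mask dimensions do not match the frame stack")
    if (!any(mask))
        stop("empty region mask")
    flat <- matrix(frames(stack), d[1L] * d[2L], d[3L])
    PerfusionCurve(frameTimes(stack),
                   colMeans(flat[which(mask), , drop = FALSE]))
}

#' Baseline fluorescence of a curve
#'
#' The mean of the first \code{window} samples. Recording starts at dye
#' injection, so the earliest frames precede any bolus arrival; the default
#' window of 4 frames corresponds to 1 s at 4 Hz.
#'
#' @param curve a \linkS4class{PerfusionCurve}.
#' @param window number of initial frames to average (>= 1).
#' @return Baseline fluorescence (APU).
#' @export
estimateBaseline <- function(curve, window = 4L) {
    stopifnot(is(curve, "PerfusionCurve"))
    n <- length(curveValues(curve))
    if (window < 1L || window > n)
        stop("'window' must be between 1 and the curve length")
    mean(curveValues(curve)[seq_len(window)])
}

#' Ingress of a regional perfusion curve
#'
#' Ingress is the absolute difference between the initial mean fluorescence
#' of a region and its maximal value: \code{max(curve) - baseline}, floored
#' at 0 so that a noisy all-baseline region cannot return a negative value.
#' The peak time is the time of the first maximum of the lightly smoothed
#' curve (moving average, width 3); the ingress difference itself uses the
#' raw frame values.
#'
#' @param curve a \linkS4class{PerfusionCurve}.
#' @param window baseline window in frames (see [estimateBaseline()]).
#' @return A list of class \code{PerfusionParams} with elements
#'   \code{baseline} (APU), \code{ingress} (APU), \code{tPeak} (s) and
#'   \code{tOnset} (NA here; filled by [computeIngressRate()]).
#' @examples
#' cv <- PerfusionCurve(0:4, c(10, 10, 10, 50, 90))
#' computeIngress(cv, window = 3)$ingress  # 80
#' @export
computeIngress <- function(curve, window = 4L) {
    stopifnot(is(curve, "PerfusionCurve"))
    y <- curveValues(curve)
    if (length(y) < window + 1L)
        stop("curve must be longer than the baseline window")
    baseline <- estimateBaseline(curve, window)
    ingress <- max(max(y) - baseline, 0)
    peakIdx <- which.max(.smooth3(y))
    structure(list(baseline = baseline, ingress = ingress,
                   tPeak = curveTimes(curve)[peakIdx], tOnset = NA_real_),
              class = "PerfusionParams")
}

#' @export
print.PerfusionParams <- function(x, ...) {
    cat(sprintf("PerfusionParams: baseline %.4g APU, ingress %.4g APU,",
                x$baseline, x$ingress),
        sprintf("onset %.3g s, peak %.3g s\n", x$tOnset, x$tPeak))
    invisible(x)
}

#' Ingress rate (blush rate) of a regional perfusion curve
#'
#' The speed of the fluorescence rise. With \code{rateMethod = "rise"} (the
#' default) it is defined as ingress divided by the rise time from bolus
#' onset to peak, where onset is the first time the smoothed curve exceeds
#' \code{baseline + onsetK * sd(baseline window)} (falling back to the first
#' frame when the curve never sits below that threshold). With
#' \code{rateMethod = "deriv"} it is the maximum slope of the smoothed curve.
#' A curve with zero ingress has rate 0 by convention.
#'
#' @param curve a \linkS4class{PerfusionCurve}.
#' @param window baseline window in frames.
#' @param onsetK multiplier of the baseline standard deviation used for
#'   onset detection; default 3.
#' @param rateMethod \code{"rise"} (ingress / rise time) or \code{"deriv"}
#'   (maximum smoothed derivative).
#' @return Ingress rate (APU/s) with attributes \code{tOnset} and
#'   \code{tPeak} (s).
#' @examples
#' ramp <- PerfusionCurve(seq(0, 20, by = 0.5), seq(0, 40, by = 1))
#' computeIngressRate(ramp, window = 1)  # 2 APU/s
#' @export
computeIngressRate <- function(curve, window = 4L, onsetK = 3,
                               rateMethod = c("rise", "deriv")) {
    rateMethod <- match.arg(rateMethod)
    p <- computeIngress(curve, window)
    y <- curveValues(curve)
    t <- curveTimes(curve)
    if (p$ingress <= 0)
        return(structure(0, tOnset = NA_real_, tPeak = p$tPeak))
    s <- .smooth3(y)
    if (rateMethod == "deriv") {
        slope <- max(diff(s) / diff(t))
        return(structure(max(slope, 0), tOnset = NA_real_, tPeak = p$tPeak))
    }
    sdB <- if (window > 1L) stats::sd(y[seq_len(window)]) else 0
    thr <- p$baseline + onsetK * sdB
    peakIdx <- which.max(s)
    if (peakIdx == 1L)
        stop("degenerate rise: curve peaks at the first frame")
    onsetIdx <- which(s[seq_len(peakIdx)] > thr)[1L]
    if (is.na(onsetIdx))
        onsetIdx <- 1L
    if (onsetIdx == peakIdx)
        stop("degenerate rise: onset and peak coincide")
    rate <- p$ingress / (t[peakIdx] - t[onsetIdx])
    structure(rate, tOnset = t[onsetIdx], tPeak = t[peakIdx])
}

#' Quantify perfusion over the whole flap and the four Hartrampf zones
#'
#' Applies curve extraction, ingress and ingress rate to the whole-flap
#' bright zone and to ROI 1..4. The stack should first be standardized with
#' [trimToDuration()]; a warning is emitted otherwise.
#'
#' @param stack a \linkS4class{FrameStack}, trimmed to the 20-s window.
#' @param geometry a \linkS4class{FlapGeometry}.
#' @param zones a \linkS4class{ZoneSet}; defaults to
#'   \code{partitionZones(geometry)}.
#' @param fraction bright-zone fraction (see [brightZone()]).
#' @param window baseline window in frames.
#' @param onsetK onset threshold multiplier (see [computeIngressRate()]).
#' @return A data frame of class \code{ZonePerfusion} with one row per
#'   region (\code{whole_flap}, \code{roi1}..\code{roi4}) and columns
#'   \code{region}, \code{baseline_apu}, \code{ingress_apu},
#'   \code{ingress_rate_apu_s}, \code{t_onset_s}, \code{t_peak_s}.
#' @export
quantifyZones <- function(stack, geometry, zones = partitionZones(geometry),
                          fraction = 0.2, window = 4L, onsetK = 3) {
    stopifnot(is(stack, "FrameStack"), is(geometry, "FlapGeometry"),
              is(zones, "ZoneSet"))
    if (stackDuration(stack) > 20 + 1e-6)
        warning("stack is longer than the 20-s analysis window; ",
                "apply trimToDuration() before quantification")
    masks <- c(list(whole_flap = brightZone(stack, flapMask(geometry),
                                            fraction)),
               stats::setNames(lapply(1:4, function(i) zoneMask(zones, i)),
                               paste0("roi", 1:4)))
    rows <- lapply(names(masks), function(nm) {
        curve <- roiMeanCurve(stack, masks[[nm]])
        p <- computeIngress(curve, window)
        if (p$ingress > 0) {
            r <- computeIngressRate(curve, window, onsetK)
            tOnset <- attr(r, "tOnset")
            rate <- as.numeric(r)
        } else {
            rate <- 0
            tOnset <- NA_real_
        }
        data.frame(region = nm, baseline_apu = p$baseline,
                   ingress_apu = p$ingress, ingress_rate_apu_s = rate,
                   t_onset_s = tOnset, t_peak_s = p$tPeak,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("ZonePerfusion", "data.frame")
    out
}

#' Per-pixel perfusion map for dynamic color analysis
#'
#' Applies the ingress and time-of-peak definitions pixel by pixel: per-pixel
#' baseline is the mean of the first \code{window} frames, per-pixel ingress
#' is the raw maximum minus that baseline (floored at 0), and the peak time
#' is taken from the width-3 smoothed course. The resulting ingress image is
#' what a blue-to-red dynamic color overlay renders (red = best perfused)
#' and what the perfusion-pattern classifier reads.
#'
#' @param stack a \linkS4class{FrameStack}, trimmed to the 20-s window.
#' @param mask logical flap mask.
#' @param window baseline window in frames.
#' @return A \linkS4class{PerfusionMap}.
#' @seealso [renderPerfusionMap()] for the color rendering.
#' @export
perfusionMap <- function(stack, mask, window = 4L) {
    stopifnot(is(stack, "FrameStack"), is.logical(mask))
    if (!any(mask))
        stop("empty flap mask")
    d <- dim(frames(stack))
    if (!identical(dim(mask), d[1:2]))
        stop("mask dimensions do not match the frame stack")
    if (d[3L] < window + 1L)
        stop("stack must be longer than the baseline window")
    flat <- matrix(frames(stack), d[1L] * d[2L], d[3L])
    idx <- which(mask)
    X <- flat[idx, , drop = FALSE]
    baseline <- rowMeans(X[, seq_len(window), drop = FALSE])
    rawPeak <- X[cbind(seq_along(idx), max.col(X, ties.method = "first"))]
    ingress <- pmax(rawPeak - baseline, 0)
    S <- .smooth3Rows(X)
    tPeak <- frameTimes(stack)[max.col(S, ties.method = "first")]
    ingressImg <- matrix(NA_real_, d[1L], d[2L])
    tPeakImg <- matrix(NA_real_, d[1L], d[2L])
    ingressImg[idx] <- ingress
    tPeakImg[idx] <- tPeak
    new("PerfusionMap", ingress = ingressImg, timeToPeak = tPeakImg,
        mask = mask)
}
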