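## Flap zoning: the four regions of interest mapped onto the Hartrampf
## perfusion zones, and the "bright zone" on which whole-flap parameters are
## estimated.

#' Partition a flap into the four Hartrampf-zone regions of interest
#'
#' Each hemi-flap (split by the midline) is divided at the midpoint of its
#' column extent into a central and a peripheral region:
#' \itemize{
#'   \item ROI 1: peripheral end ipsilateral to the perforator (zone III),
#'   \item ROI 2: perforator emergence area, adjacent to the midline (zone I),
#'   \item ROI 3: contralateral area adjacent to the midline (zone II),
#'   \item ROI 4: contralateral peripheral end (zone IV).
#' }
#' The four masks are pairwise disjoint and their union is exactly the flap
#' mask. Equal-width column splits are used because clinical ROI placement is
#' done freehand and no reproducible sizing rule exists; the label image can
#' be edited for irregular flaps.
#'
#' @param geometry a \linkS4class{FlapGeometry}. The perforator must not sit
#'   exactly on the midline (its side would be undefined).
#' @return A \linkS4class{ZoneSet}.
#' @examples
#' geom <- defaultFlapGeometry(32, 64, perforator = c(16, 24))
#' zones <- partitionZones(geom)
#' sum(zoneLabels(zones) > 0) == sum(flapMask(geom))
#' @export
partitionZones <- function(geometry) {
    stopifnot(is(geometry, "FlapGeometry"))
    mask <- flapMask(geometry)
    m <- midlineCol(geometry)
    pc <- perforator(geometry)[2L]
    if (abs(pc - m) < .Machine$double.eps^0.5)
        stop("perforator lies exactly on the midline: side is ambiguous")
    H <- nrow(mask); W <- ncol(mask)
    col <- matrix(seq_len(W), H, W, byrow = TRUE)
    low <- col <= m
    perfLow <- pc <= m

    labels <- matrix(0L, H, W)
    assignSide <- function(sideMask, outerAtLow, roiOuter, roiCentral) {
        inSide <- mask & sideMask
        if (!any(inSide))
            return(invisible(NULL))
        cr <- range(which(colSums(inSide) > 0L))
        w <- cr[2L] - cr[1L] + 1L
        nOuter <- floor(w / 2)
        outer <- if (outerAtLow) col < cr[1L] + nOuter else col > cr[2L] - nOuter
        labels[inSide & outer] <<- roiOuter
        labels[inSide & !outer] <<- roiCentral
        invisible(NULL)
    }
    ## ipsilateral half: outer = ROI1, central (midline-adjacent) = ROI2
    assignSide(if (perfLow) low else !low, outerAtLow = perfLow, 1L, 2L)
    ## contralateral half: central = ROI3, outer = ROI4
    assignSide(if (perfLow) !low else low, outerAtLow = !perfLow, 4L, 3L)

    zones <- new("ZoneSet", labels = labels)
    if (!zoneMask(zones, 2L)[perforator(geometry)[1L], pc])
        stop("ROI 2 does not contain the perforator point; ",
             "the perforator lies in the peripheral half of its side")
    zones
}

#' Bright zone: the highest-fluorescence flap subregion
#'
#' Selects the flap pixels whose peak fluorescence over the video lies in the
#' top \code{fraction} of the flap's peak-fluorescence distribution. This
#' emulates the automatic whole-flap analysis region of clinical software, in
#' which perfusion parameters are estimated on the brightest part of the
#' flap. The threshold is an order statistic (inclusive), so the selection is
#' invariant under any strictly increasing rescaling of intensities, and a
#' perfectly uniform video yields the entire flap mask.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param mask logical flap mask.
#' @param fraction fraction of flap pixels to retain, in (0, 1); default 0.2.
#' @return Logical H x W mask of the bright zone.
#' @export
brightZone <- function(stack, mask, fraction = 0.2) {
    stopifnot(is(stack, "FrameStack"), is.logical(mask))
    if (!any(mask))
        stop("empty flap mask")
    if (fraction <= 0 || fraction >= 1)
        stop("'fraction' must be in (0, 1)")
    d <- dim(frames(stack))
    if (!identical(dim(mask), d[1:2]))
        stop("mask dimensions do not match the frame stack")
    flat <- matrix(frames(stack), d[1L] * d[2L], d[3L])
    idx <- which(mask)
    peaks <- flat[idx, , drop = FALSE]
    peak <- peaks[cbind(seq_along(idx), max.col(peaks, ties.method = "first"))]
    thr <- stats::quantile(peak, probs = 1 - fraction, type = 1, names = FALSE)
    out <- matrix(FALSE, d[1L], d[2L])
    out[idx[peak >= thr]] <- TRUE
    out
}
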