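## Perfusion-pattern classification. Clinically the three patterns are read
## by eye from the dynamic color overlay; here the reading is made
## reproducible by summarizing the per-pixel ingress map into zone ratios and
## a midline-crossing index and applying fixed thresholds.

#' Extract pattern features from a perfusion map
#'
#' Computes, from the per-pixel ingress image:
#' \itemize{
#'   \item zone ratios \code{r1 = ROI1/ROI2}, \code{r3 = ROI3/ROI2},
#'     \code{r4 = ROI4/ROI2} of mean per-pixel ingress;
#'   \item the midline-crossing index: mean ingress over a contralateral band
#'     adjacent to the midline divided by the mirror ipsilateral band.
#' }
#' All features are ratios, hence invariant to rescaling of the map.
#'
#' @param map a \linkS4class{PerfusionMap}.
#' @param zones a \linkS4class{ZoneSet}.
#' @param geometry the \linkS4class{FlapGeometry} the map was computed on.
#' @param bandFraction width of each midline band as a fraction of the flap
#'   column extent; default 0.1.
#' @return A list of class \code{PatternFeatures} with elements \code{r1},
#'   \code{r3}, \code{r4}, \code{crossingIndex} and \code{zoneMeans}.
#' @export
extractPatternFeatures <- function(map, zones, geometry,
                                   bandFraction = 0.1) {
    stopifnot(is(map, "PerfusionMap"), is(zones, "ZoneSet"),
              is(geometry, "FlapGeometry"))
    img <- ingressMap(map)
    zoneMeans <- vapply(1:4, function(i) {
        v <- img[zoneMask(zones, i) & mapMask(map)]
        if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
    names(zoneMeans) <- paste0("roi", 1:4)
    if (is.na(zoneMeans[2L]) || zoneMeans[2L] <= 0)
        stop("undefined features: ROI 2 mean per-pixel ingress is not positive")

    mask <- mapMask(map)
    m <- midlineCol(geometry)
    cols <- range(which(colSums(mask) > 0L))
    w <- max(1L, round(bandFraction * (cols[2L] - cols[1L] + 1L)))
    col <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
    lowBand <- col <= m & col > m - w
    highBand <- col > m & col <= m + w
    perfLow <- perforator(geometry)[2L] <= m
    ipsiBand <- if (perfLow) lowBand else highBand
    contraBand <- if (perfLow) highBand else lowBand
    bandMean <- function(b) {
        v <- img[b & mask]
        if (!length(v)) NA_real_ else mean(v)
    }
    ipsi <- bandMean(ipsiBand)
    contra <- bandMean(contraBand)
    if (is.na(ipsi) || ipsi <= 0)
        stop("undefined features: ipsilateral midline band has no positive ingress")
    structure(list(r1 = unname(zoneMeans[1L] / zoneMeans[2L]),
                   r3 = unname(zoneMeans[3L] / zoneMeans[2L]),
                   r4 = unname(zoneMeans[4L] / zoneMeans[2L]),
                   crossingIndex = contra / ipsi,
                   zoneMeans = zoneMeans),
              class = "PatternFeatures")
}

#' @export
print.PatternFeatures <- function(x, ...) {
    cat(sprintf("PatternFeatures: r1 = %.3g, r3 = %.3g, r4 = %.3g, crossing index = %.3g\n",
                x$r1, x$r3, x$r4, x$crossingIndex))
    invisible(x)
}

#' Classify a flap into one of the three perfusion patterns
#'
#' Deterministic decision rule on the pattern features:
#' \itemize{
#'   \item crossing index >= \code{tauCross} and \code{min(r1, r4)} <
#'     \code{tauPeriph}: type 3 (homogeneous perfusion on either side of the
#'     midline, poor perfusion of the peripheral flap ends);
#'   \item crossing index < \code{tauCross} and \code{r1} >= \code{tauPeriph}:
#'     type 1 (homogeneous ipsilateral perfusion not crossing the midline);
#'   \item otherwise: type 2 (perfusion confined to the perforator emergence
#'     area).
#' }
#' Every feature vector receives exactly one label.
#'
#' @param features a \code{PatternFeatures} list.
#' @param tauCross midline-crossing threshold; default 0.5.
#' @param tauPeriph peripheral-ratio threshold; default 0.5.
#' @return A list of class \code{PatternLabel} with elements \code{label}
#'   (integer 1..3), \code{features} and \code{thresholds}.
#' @export
classifyPattern <- function(features, tauCross = 0.5, tauPeriph = 0.5) {
    stopifnot(inherits(features, "PatternFeatures"))
    ci <- features$crossingIndex
    label <- if (ci >= tauCross && min(features$r1, features$r4) < tauPeriph)
        3L
    else if (ci < tauCross && features$r1 >= tauPeriph)
        1L
    else
        2L
    structure(list(label = label, features = features,
                   thresholds = c(tauCross = tauCross,
                                  tauPeriph = tauPeriph)),
              class = "PatternLabel")
}

#' @export
print.PatternLabel <- function(x, ...) {
    cat(sprintf("PatternLabel: type %d (tauCross = %.3g, tauPeriph = %.3g)\n",
                x$label, x$thresholds["tauCross"], x$thresholds["tauPeriph"]))
    print(x$features)
    invisible(x)
}

#' End-to-end pattern classification of a video
#'
#' Convenience wrapper: trims the stack to the 20-s window, computes the
#' per-pixel perfusion map, partitions the zones and applies
#' [extractPatternFeatures()] and [classifyPattern()].
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param geometry a \linkS4class{FlapGeometry}.
#' @param window baseline window in frames.
#' @param bandFraction midline band width fraction.
#' @param tauCross,tauPeriph classification thresholds.
#' @return A \code{PatternLabel}.
#' @export
classifyFlap <- function(stack, geometry, window = 4L, bandFraction = 0.1,
                         tauCross = 0.5, tauPeriph = 0.5) {
    stack <- trimToDuration(stack)
    map <- perfusionMap(stack, flapMask(geometry), window)
    zones <- partitionZones(geometry)
    features <- extractPatternFeatures(map, zones, geometry, bandFraction)
    classifyPattern(features, tauCross, tauPeriph)
}
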