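## Accessor generics for the S4 containers. Slots are never reached into
## directly by user code.

#' @rdname FrameStack-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname FrameStack-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname FrameStack-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname FrameStack-accessors
#' @export
setGeneric("apuMax", function(x) standardGeneric("apuMax"))
#' @rdname FrameStack-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname FrameStack-accessors
#' @export
setGeneric("stackDuration", function(x) standardGeneric("stackDuration"))

#' Accessors for FrameStack
#'
#' @param x a \linkS4class{FrameStack}.
#' @return \code{frames} the H x W x T array; \code{frameTimes} the frame
#'   times (s); \code{frameRate} the frame rate (Hz); \code{apuMax} the APU
#'   scale maximum; \code{nFrames} the frame count; \code{stackDuration} the
#'   total recorded duration \code{nFrames / frameRate} (s).
#' @name FrameStack-accessors
#' @aliases frames frameTimes frameRate apuMax nFrames stackDuration
NULL

#' @rdname FrameStack-accessors
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)
#' @rdname FrameStack-accessors
#' @export
setMethod("frameTimes", "FrameStack", function(x) x@frameTimes)
#' @rdname FrameStack-accessors
#' @export
setMethod("frameRate", "FrameStack", function(x) x@frameRate)
#' @rdname FrameStack-accessors
#' @export
setMethod("apuMax", "FrameStack", function(x) x@apuMax)
#' @rdname FrameStack-accessors
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3L])
#' @rdname FrameStack-accessors
#' @export
setMethod("stackDuration", "FrameStack",
          function(x) dim(x@frames)[3L] / x@frameRate)

#' @rdname FlapGeometry-accessors
#' @export
setGeneric("flapMask", function(x) standardGeneric("flapMask"))
#' @rdname FlapGeometry-accessors
#' @export
setGeneric("midlineCol", function(x) standardGeneric("midlineCol"))
#' @rdname FlapGeometry-accessors
#' @export
setGeneric("perforator", function(x) standardGeneric("perforator"))
#' @rdname FlapGeometry-accessors
#' @export
setGeneric("pixelSizeMm", function(x) standardGeneric("pixelSizeMm"))

#' Accessors for FlapGeometry
#'
#' @param x a \linkS4class{FlapGeometry}.
#' @return \code{flapMask} the logical flap mask; \code{midlineCol} the
#'   midline column coordinate; \code{perforator} c(row, col) of the
#'   perforator point; \code{pixelSizeMm} the pixel size (mm).
#' @name FlapGeometry-accessors
#' @aliases flapMask midlineCol perforator pixelSizeMm
NULL

#' @rdname FlapGeometry-accessors
#' @export
setMethod("flapMask", "FlapGeometry", function(x) x@mask)
#' @rdname FlapGeometry-accessors
#' @export
setMethod("midlineCol", "FlapGeometry", function(x) x@midlineCol)
#' @rdname FlapGeometry-accessors
#' @export
setMethod("perforator", "FlapGeometry", function(x) x@perforator)
#' @rdname FlapGeometry-accessors
#' @export
setMethod("pixelSizeMm", "FlapGeometry", function(x) x@pixelSizeMm)

#' @rdname ZoneSet-accessors
#' @export
setGeneric("zoneLabels", function(x) standardGeneric("zoneLabels"))
#' @rdname ZoneSet-accessors
#' @export
setGeneric("zoneMask", function(x, i) standardGeneric("zoneMask"))

#' Accessors for ZoneSet
#'
#' @param x a \linkS4class{ZoneSet}.
#' @param i zone index in 1..4 (ROI number).
#' @return \code{zoneLabels} the integer label image (0 outside the flap,
#'   1..4 for ROI 1..4); \code{zoneMask} the logical mask of one ROI.
#' @name ZoneSet-accessors
#' @aliases zoneLabels zoneMask
NULL

#' @rdname ZoneSet-accessors
#' @export
setMethod("zoneLabels", "ZoneSet", function(x) x@labels)
#' @rdname ZoneSet-accessors
#' @export
setMethod("zoneMask", "ZoneSet", function(x, i) {
    stopifnot(length(i) == 1L, i %in% 1:4)
    x@labels == as.integer(i)
})

#' @rdname PerfusionCurve-accessors
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))
#' @rdname PerfusionCurve-accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' Accessors for PerfusionCurve
#'
#' @param x a \linkS4class{PerfusionCurve}.
#' @return \code{curveTimes} the sample times (s); \code{curveValues} the
#'   mean fluorescence values (APU).
#' @name PerfusionCurve-accessors
#' @aliases curveTimes curveValues
NULL

#' @rdname PerfusionCurve-accessors
#' @export
setMethod("curveTimes", "PerfusionCurve", function(x) x@times)
#' @rdname PerfusionCurve-accessors
#' @export
setMethod("curveValues", "PerfusionCurve", function(x) x@values)

#' @rdname PerfusionMap-accessors
#' @export
setGeneric("ingressMap", function(x) standardGeneric("ingressMap"))
#' @rdname PerfusionMap-accessors
#' @export
setGeneric("timeToPeakMap", function(x) standardGeneric("timeToPeakMap"))
#' @rdname PerfusionMap-accessors
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))

#' Accessors for PerfusionMap
#'
#' @param x a \linkS4class{PerfusionMap}.
#' @return \code{ingressMap} the per-pixel ingress image (APU, NA outside
#'   the flap); \code{timeToPeakMap} the per-pixel time-to-peak image (s);
#'   \code{mapMask} the flap mask the map was computed on.
#' @name PerfusionMap-accessors
#' @aliases ingressMap timeToPeakMap mapMask
NULL

#' @rdname PerfusionMap-accessors
#' @export
setMethod("ingressMap", "PerfusionMap", function(x) x@ingress)
#' @rdname PerfusionMap-accessors
#' @export
setMethod("timeToPeakMap", "PerfusionMap", function(x) x@timeToPeak)
#' @rdname PerfusionMap-accessors
#' @export
setMethod("mapMask", "PerfusionMap", function(x) x@mask)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("amplitudeField", function(x) standardGeneric("amplitudeField"))
#' @rdname GroundTruth-accessors
#' @export
setGeneric("arrivalField", function(x) standardGeneric("arrivalField"))
#' @rdname GroundTruth-accessors
#' @export
setGeneric("patternId", function(x) standardGeneric("patternId"))
#' @rdname GroundTruth-accessors
#' @export
setGeneric("zoneIngress", function(x) standardGeneric("zoneIngress"))

#' Accessors for GroundTruth
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return \code{amplitudeField} the true per-pixel amplitude image (APU);
#'   \code{arrivalField} the true bolus-arrival-time image (s, NA outside the
#'   flap); \code{patternId} the pattern label (1, 2 or 3);
#'   \code{zoneIngress} the named vector of true per-zone ingress (APU).
#' @name GroundTruth-accessors
#' @aliases amplitudeField arrivalField patternId zoneIngress
NULL

#' @rdname GroundTruth-accessors
#' @export
setMethod("amplitudeField", "GroundTruth", function(x) x@amplitude)
#' @rdname GroundTruth-accessors
#' @export
setMethod("arrivalField", "GroundTruth", function(x) x@arrival)
#' @rdname GroundTruth-accessors
#' @export
setMethod("patternId", "GroundTruth", function(x) x@pattern)
#' @rdname GroundTruth-accessors
#' @export
setMethod("zoneIngress", "GroundTruth", function(x) x@zoneIngress)
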