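#' Normalized gamma-variate bolus kinetics
#'
#' Evaluates the indicator-dilution time-intensity model used by the
#' simulator. The curve stays at the baseline \code{B} before the bolus
#' arrival \code{t0}, then rises as a gamma-variate normalized so that its
#' peak value is exactly \code{B + A}, attained at \code{t0 + tp}:
#' \deqn{f(t) = B + A \left(\frac{t - t_0}{t_p}\right)^{\alpha}
#'   \exp\left\{\alpha \left(1 - \frac{t - t_0}{t_p}\right)\right\},
#'   \quad t \ge t_0.}
#' The normalization makes the true regional ingress analytically known
#' (it equals \code{A}), which is what makes simulated videos usable as
#' ground truth. No washout term is modelled: clinical recordings are
#' standardized to a 20-second window during which fluorescence is still
#' rising or plateauing.
#'
#' @param t time (s); vectorized.
#' @param baseline baseline fluorescence B (APU).
#' @param amplitude rise amplitude A above baseline (APU), >= 0.
#' @param tArrival bolus arrival time t0 (s).
#' @param timeToPeak time from arrival to peak tp (s), > 0.
#' @param shape gamma-variate shape alpha (dimensionless), > 0.
#' @return Fluorescence (APU) at each \code{t}.
#' @examples
#' gammaVariate(7, baseline = 10, amplitude = 100, tArrival = 2,
#'              timeToPeak = 5, shape = 2)  # peak: 110
#' @export
gammaVariate <- function(t, baseline, amplitude, tArrival, timeToPeak,
                         shape) {
    if (any(timeToPeak <= 0))
        stop("'timeToPeak' must be positive")
    if (any(shape <= 0))
        stop("'shape' must be positive")
    if (any(amplitude < 0))
        stop("'amplitude' must be non-negative")
    u <- pmax((t - tArrival) / timeToPeak, 0)
    baseline + amplitude * u^shape * exp(shape * (1 - u))
}
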