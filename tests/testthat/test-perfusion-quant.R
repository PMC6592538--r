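test_that("regional mean curve reduces to single-pixel course and constants", {
    geom <- smallGeometry()
    sim <- simulateFlapVideo(geom, preset = 2, noiseSd = 1, seed = 41)
    mask1 <- matrix(FALSE, 32, 64)
    p <- perforator(geom)
    mask1[p[1], p[2]] <- TRUE
    cv <- roiMeanCurve(sim$stack, mask1)
    expect_equal(curveValues(cv), frames(sim$stack)[p[1], p[2], ])

    const <- FrameStack(array(7, dim = c(4, 4, 6)), frameRate = 2)
    expect_equal(curveValues(roiMeanCurve(const, matrix(TRUE, 4, 4))),
                 rep(7, 6))
    expect_error(roiMeanCurve(const, matrix(FALSE, 4, 4)), "empty")
})

test_that("regional mean curve equals a brute-force summation over in-mask pixels", {
    geom <- smallGeometry()
    sim <- simulateFlapVideo(geom, preset = 1, noiseSd = 0, seed = 42)
    zones <- partitionZones(geom)
    roi2 <- zoneMask(zones, 2)
    cv <- roiMeanCurve(sim$stack, roi2)
    arr <- frames(sim$stack)
    oracle <- vapply(seq_len(dim(arr)[3]), function(t) {
        s <- 0; n <- 0
        for (i in seq_len(nrow(roi2))) for (j in seq_len(ncol(roi2)))
            if (roi2[i, j]) { s <- s + arr[i, j, t]; n <- n + 1 }
        s / n
    }, numeric(1))
    expect_equal(curveValues(cv), oracle, tolerance = 1e-12)
})

test_that("baseline is the mean of the first window frames", {
    cv <- PerfusionCurve(0:4, c(10, 10, 10, 50, 90))
    expect_equal(estimateBaseline(cv, 3), 10)
    expect_equal(estimateBaseline(cv, 1), 10)
    expect_equal(estimateBaseline(PerfusionCurve(0:4, c(2, 4, 6, 8, 10)), 2), 3)
    expect_error(estimateBaseline(cv, 6), "window")
    expect_error(estimateBaseline(cv, 0), "window")
})

test_that("ingress equals max minus baseline, floored at zero", {
    expect_equal(computeIngress(PerfusionCurve(0:4, rep(3, 5)), 2)$ingress, 0)
    ramp <- PerfusionCurve(seq(0, 20, length.out = 41),
                           seq(10, 50, length.out = 41))
    expect_equal(computeIngress(ramp, 1)$ingress, 40)
    # noisy all-baseline region never returns a negative ingress
    declining <- PerfusionCurve(0:9, c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
    expect_equal(computeIngress(declining, 1)$ingress, 0)
})

test_that("ingress matches a brute-force scan over all frames for random curves", {
    set.seed(405)
    for (i in 1:1000) {
        n <- sample(10:60, 1)
        y <- runif(n, 0, 255)
        w <- sample(1:5, 1)
        cv <- PerfusionCurve(seq_len(n) / 4, y)
        oracle <- max(max(y) - mean(y[seq_len(w)]), 0)
        expect_equal(computeIngress(cv, w)$ingress, oracle)
    }
})

test_that("ingress rate recovers ingress / rise-time on simple shapes", {
    # linear ramp 0 -> 40 over 20 s, onset at the first frame
    ramp <- PerfusionCurve(seq(0, 20, by = 0.5), seq(0, 40, by = 1))
    expect_equal(as.numeric(computeIngressRate(ramp, window = 1)), 2,
                 tolerance = 0.06)  # smoothing shifts onset by <= 1 frame
    expect_equal(as.numeric(computeIngressRate(
        PerfusionCurve(0:9, rep(4, 10)), 2)), 0)
})

test_that("ingress rate on a dense noiseless gamma-variate matches the analytic rise", {
    # B = 10, A = 100, t0 = 2, tp = 5: onset -> t0, peak at t0 + tp,
    # so rate -> A / tp = 20 APU/s in the dense-sampling limit
    tt <- seq(0, 20, by = 1e-3)
    cv <- PerfusionCurve(tt, gammaVariate(tt, 10, 100, 2, 5, 2))
    r <- computeIngressRate(cv, window = 4)
    expect_equal(attr(r, "tPeak"), 7, tolerance = 1e-2)
    expect_equal(attr(r, "tOnset"), 2, tolerance = 1e-2)
    expect_equal(as.numeric(r), 100 / 5, tolerance = 0.005)
})

test_that("degenerate rises are rejected", {
    spike <- PerfusionCurve(0:9, c(50, rep(10, 9)))
    # baseline window 2 -> baseline 30, ingress 20, but the peak sits on the
    # very first frame: no rise time exists
    expect_error(computeIngressRate(spike, window = 2), "degenerate rise")
})

test_that("ingress and rate are affine equivariant; onset and peak times are not moved", {
    set.seed(406)
    tt <- seq(0, 19.75, by = 0.25)
    for (i in 1:20) {
        y <- gammaVariate(tt, 8, runif(1, 40, 150), runif(1, 1, 4),
                          runif(1, 2, 6), 2) + rnorm(length(tt), 0, 1)
        a <- runif(1, 0.5, 3); b <- runif(1, -5, 20)
        cv <- PerfusionCurve(tt, y)
        cv2 <- PerfusionCurve(tt, a * y + b)
        p1 <- computeIngress(cv); p2 <- computeIngress(cv2)
        expect_equal(p2$ingress, a * p1$ingress, tolerance = 1e-9)
        expect_equal(p2$tPeak, p1$tPeak)
        r1 <- computeIngressRate(cv); r2 <- computeIngressRate(cv2)
        expect_equal(as.numeric(r2), a * as.numeric(r1), tolerance = 1e-9)
        expect_equal(attr(r2, "tOnset"), attr(r1, "tOnset"))
        expect_equal(attr(r2, "tPeak"), attr(r1, "tPeak"))
    }
})

test_that("per-pixel map equals ground truth for noiseless video and zero for constants", {
    geom <- smallGeometry()
    sim <- simulateFlapVideo(geom, preset = 2, noiseSd = 0, seed = 43)
    st <- trimToDuration(sim$stack)
    map <- perfusionMap(st, flapMask(geom))
    mask <- flapMask(geom)
    expect_equal(ingressMap(map)[mask], amplitudeField(sim$truth)[mask],
                 tolerance = 1e-9)
    expect_true(all(is.na(ingressMap(map)[!mask])))

    const <- FrameStack(array(7, dim = c(8, 8, 10)), frameRate = 4)
    m0 <- perfusionMap(const, matrix(TRUE, 8, 8), window = 2)
    expect_true(all(ingressMap(m0) == 0))
})

test_that("zone-averaged per-pixel ingress matches curve-then-ingress when arrivals align, and bounds it otherwise", {
    geom <- smallGeometry()
    # effectively infinite propagation speed: all pixels rise together
    k <- presetKinetics(2, speed = 1e9)
    sim <- simulateFlapVideo(geom, preset = 2, kinetics = k, noiseSd = 0,
                             seed = 44)
    st <- trimToDuration(sim$stack)
    zones <- partitionZones(geom)
    roi2 <- zoneMask(zones, 2)
    map <- perfusionMap(st, flapMask(geom))
    meanOfMax <- mean(ingressMap(map)[roi2])
    maxOfMean <- computeIngress(roiMeanCurve(st, roi2))$ingress
    expect_equal(meanOfMax, maxOfMean, tolerance = 1e-9)

    # heterogeneous arrivals: max of the mean curve <= mean of pixel maxima
    sim2 <- simulateFlapVideo(geom, preset = 2, noiseSd = 0, seed = 45)
    st2 <- trimToDuration(sim2$stack)
    map2 <- perfusionMap(st2, flapMask(geom))
    expect_lte(computeIngress(roiMeanCurve(st2, roi2))$ingress,
               mean(ingressMap(map2)[roi2]) + 1e-9)
})

test_that("zone quantification ranks the perforator zone first for preset 2", {
    geom <- smallGeometry()
    sim <- simulateFlapVideo(geom, preset = 2, noiseSd = 0, seed = 46)
    st <- trimToDuration(sim$stack)
    q <- quantifyZones(st, geom)
    expect_setequal(q$region, c("whole_flap", paste0("roi", 1:4)))
    ing <- setNames(q$ingress_apu, q$region)
    expect_true(all(ing["roi2"] > ing[c("roi1", "roi3", "roi4")]))
    # warning when the stack was not standardized first
    expect_warning(quantifyZones(sim$stack, geom), "20-s")
    # uniform video: all five ingress values are 0
    const <- FrameStack(array(7, dim = c(32, 64, 10)), frameRate = 0.5)
    q0 <- quantifyZones(const, geom)
    expect_true(all(q0$ingress_apu == 0))
    expect_true(all(q0$ingress_rate_apu_s == 0))
})
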