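test_that("noiseless pixel at the perforator follows the full-amplitude kinetics", {
    geom <- smallGeometry()
    k <- presetKinetics(2)
    sim <- simulateFlapVideo(geom, preset = 2, kinetics = k, noiseSd = 0,
                             seed = 7)
    p <- perforator(geom)
    course <- frames(sim$stack)[p[1], p[2], ]
    expected <- gammaVariate(frameTimes(sim$stack), k$baseline, k$amplitude,
                             k$tArrival, k$timeToPeak, k$shape)
    expect_equal(course, expected, tolerance = 1e-12)
    expect_equal(amplitudeField(sim$truth)[p[1], p[2]], k$amplitude)
})

test_that("sampled per-pixel maxima equal B + A(x,y) for noiseless video", {
    geom <- smallGeometry()
    k <- presetKinetics(1)
    sim <- simulateFlapVideo(geom, preset = 1, noiseSd = 0, seed = 1)
    arr <- frames(sim$stack)
    mask <- flapMask(geom)
    peaks <- apply(arr, c(1, 2), max)
    expect_equal(peaks[mask],
                 k$baseline + amplitudeField(sim$truth)[mask],
                 tolerance = 1e-12)
})

test_that("midline factor attenuates the contralateral amplitude field", {
    geom <- smallGeometry()
    k <- presetKinetics(1)  # m = 0.3
    sim <- simulateFlapVideo(geom, preset = 1, noiseSd = 0, seed = 1)
    A <- amplitudeField(sim$truth)
    mask <- flapMask(geom)
    m <- midlineCol(geom)
    col <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
    ipsi <- mask & col <= m
    contra <- mask & col > m
    # compare at matched distances: the mirror pixel of each contralateral
    # pixel has amplitude A/m exactly (p = 1 for preset 1)
    d <- sqrt((row(mask) - perforator(geom)[1])^2 +
              (col - perforator(geom)[2])^2)
    expect_lte(mean(A[contra]) , k$midlineFactor * mean(A[ipsi]))
    # spatial decay is monotone in distance within each half (p = 1)
    for (half in list(ipsi, contra)) {
        o <- order(d[half])
        expect_true(all(diff(A[half][o]) <= 1e-12))
    }
})

test_that("simulator is bit-identical under the same seed and leaves the RNG alone", {
    geom <- smallGeometry()
    set.seed(123)
    before <- .Random.seed
    s1 <- simulateFlapVideo(geom, preset = 2, noiseSd = 2, seed = 11)
    expect_identical(.Random.seed, before)
    s2 <- simulateFlapVideo(geom, preset = 2, noiseSd = 2, seed = 11)
    expect_identical(frames(s1$stack), frames(s2$stack))
    expect_identical(zoneIngress(s1$truth), zoneIngress(s2$truth))
    s3 <- simulateFlapVideo(geom, preset = 2, noiseSd = 2, seed = 12)
    expect_false(identical(frames(s1$stack), frames(s3$stack)))
})

test_that("simulator validates preset, duration and APU headroom", {
    geom <- smallGeometry()
    expect_error(simulateFlapVideo(geom, preset = 4), "preset")
    expect_error(simulateFlapVideo(geom, preset = 1, duration = 15),
                 "20")
    expect_error(simulateFlapVideo(geom, preset = 1,
                                   kinetics = kineticsParams(baseline = 200,
                                                             amplitude = 150)),
                 "APU range")
})

test_that("simulated cohort recovers configured multiplicative effects at large n", {
    cfgNull <- cohortEffectConfig(n = 10000, effects = list(), seed = 31)
    tab <- simulateCohort(cfgNull)
    expect_equal(nrow(tab), 10000)
    for (cov in c("overweight", "radiotherapy")) {
        r <- mean(tab$ingress_whole_apu[tab[[cov]]]) /
             mean(tab$ingress_whole_apu[!tab[[cov]]])
        expect_lt(abs(r - 1), 0.03)
    }
    cfg <- cohortEffectConfig(n = 10000,
        effects = list(diabetes = c(ingress_whole_apu = 0.35)), seed = 32)
    tab2 <- simulateCohort(cfg)
    r <- mean(tab2$ingress_whole_apu[tab2$diabetes]) /
         mean(tab2$ingress_whole_apu[!tab2$diabetes])
    expect_lt(abs(r - 0.35), 0.02)
})

test_that("cohort simulation is deterministic under a fixed config seed", {
    cfg <- cohortEffectConfig(n = 40, seed = 5)
    expect_identical(simulateCohort(cfg), simulateCohort(cfg))
    expect_false(identical(simulateCohort(cfg),
                           simulateCohort(cohortEffectConfig(n = 40, seed = 6))))
})

test_that("cohort config rejects invalid prevalences and effects", {
    expect_error(cohortEffectConfig(n = 1), "at least 2")
    expect_error(cohortEffectConfig(
        prevalences = list(overweight = 1.2, hypertension = 0.1,
                           dyslipidemia = 0.1, diabetes = 0.1,
                           former_smoker = 0.1, radiotherapy = 0.5,
                           chemotherapy = 0.5,
                           hormone_therapy = c(none = 0.5, tamoxifen = 0.4,
                                               aromatase_inhibitor = 0.1))),
        "prevalences")
    expect_error(cohortEffectConfig(
        effects = list(diabetes = c(ingress_whole_apu = -2))), "positive")
})
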