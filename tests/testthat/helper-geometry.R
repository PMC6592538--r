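# Small desk-scale geometry for fast unit tests (the full-scale default
# geometry is exercised in test-acceptance.R).
smallGeometry <- function(height = 32, width = 64)
    defaultFlapGeometry(height, width)

# Random valid geometry: rectangular or elliptical mask, random midline and a
# perforator placed in the central half of its side (so ROI 2 contains it).
randomGeometry <- function() {
    H <- sample(20:40, 1)
    W <- sample(40:80, 1)
    elliptical <- runif(1) < 0.5
    if (elliptical) {
        g <- defaultFlapGeometry(H, W)
        mask <- flapMask(g)
    } else {
        mask <- matrix(FALSE, H, W)
        mask[sample(2:5, 1):(H - sample(0:4, 1)),
             sample(2:5, 1):(W - sample(0:4, 1))] <- TRUE
    }
    cols <- range(which(colSums(mask) > 0))
    midline <- sample(seq(cols[1] + 5, cols[2] - 6), 1) + 0.5
    side <- sample(c("low", "high"), 1)
    sideCols <- if (side == "low") {
        r <- range(which(colSums(mask[, seq_len(floor(midline)), drop = FALSE]) > 0))
        r
    } else {
        offs <- floor(midline)
        r <- range(which(colSums(mask[, (offs + 1):ncol(mask), drop = FALSE]) > 0)) + offs
        r
    }
    w <- sideCols[2] - sideCols[1] + 1
    nOuter <- floor(w / 2)
    centralCols <- if (side == "low")
        seq(sideCols[1] + nOuter, sideCols[2])
    else
        seq(sideCols[1], sideCols[2] - nOuter)
    pc <- sample(rep(centralCols, 2), 1)
    rows <- which(mask[, pc])
    pr <- sample(rep(rows, 2), 1)
    FlapGeometry(mask, midlineCol = midline, perforator = c(pr, pc))
}

# Mirror a geometry across the vertical image axis.
mirrorGeometry <- function(geometry) {
    mask <- flapMask(geometry)
    W <- ncol(mask)
    FlapGeometry(mask[, W:1, drop = FALSE],
                 midlineCol = W + 1 - midlineCol(geometry),
                 perforator = c(perforator(geometry)[1],
                                W + 1 - perforator(geometry)[2]),
                 pixelSizeMm = pixelSizeMm(geometry))
}

# Exhaustive two-sided Fisher p value for a 2x2 table by hypergeometric
# enumeration: sum the probabilities of all tables with the same margins
# that are no more probable than the observed one.
fisherEnumP <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    ks <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(ks, c1, n - c1, r1)
    pObs <- dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Cohort data frame with a given 2x2 contingency table (rows = a, cols = b).
cohortFromCounts <- function(a, b, c, d) {
    data.frame(x = rep(c(TRUE, TRUE, FALSE, FALSE), times = c(a, b, c, d)),
               y = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d)))
}
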