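## small geometric fixtures built in code

discMask <- function(H, W, cx, cy, r) {
    outer(seq_len(H), seq_len(W),
          function(rr, cc) (rr - cy)^2 + (cc - cx)^2 <= r^2)
}

grayImage <- function(m) {
    storage.mode(m) <- "double"
    m
}

rgbFrom <- function(gray) {
    array(rep(gray, 3), dim = c(dim(gray), 3))
}

test_that("rescaling follows the size contract and preserves constants", {
    img <- array(runif(60 * 60 * 3, 0, 255), dim = c(60, 60, 3))
    expect_identical(rescaleToWorkingResolution(img, 0.5), img)
    out <- rescaleToWorkingResolution(img, 0.25)
    expect_equal(dim(out), c(30L, 30L, 3L))
    out2 <- rescaleToWorkingResolution(img, 1)
    expect_equal(dim(out2), c(120L, 120L, 3L))
    ## bicubic weights sum to one: constant image stays constant
    flat <- array(123, dim = c(40, 40, 3))
    expect_equal(as.vector(rescaleToWorkingResolution(flat, 0.8)),
                 rep(123, 64 * 64 * 3), tolerance = 1e-9)
    expect_error(rescaleToWorkingResolution(img, -1), "positive")
})

test_that("brightness is the per-pixel channel maximum", {
    px <- array(0, dim = c(1, 1, 3))
    px[1, 1, ] <- c(200, 80, 160)
    expect_equal(rgbToBrightness(px)[1, 1], 200)
    g <- array(77, dim = c(2, 2, 3))
    expect_true(all(rgbToBrightness(g) == 77))
    expect_equal(rgbToBrightness(array(0, c(1, 1, 3)))[1, 1], 0)
    expect_error(rgbToBrightness(matrix(0, 2, 2)), "3")
})

test_that("global Otsu selects the dark side and matches the exhaustive oracle", {
    g <- matrix(c(rep(50, 200), rep(200, 200)), 20, 20)
    thr <- exhaustiveOtsu(g)
    m <- globalOtsuMask(g)
    expect_true(all(m[g == 50]))
    expect_false(any(m[g == 200]))
    expect_true(thr >= 50 && thr < 200)   # oracle agrees the split point

    ## dark ellipses on a light background
    set.seed(1)
    gray <- matrix(230, 80, 80)
    disc <- discMask(80, 80, 25, 30, 8) | discMask(80, 80, 60, 55, 6)
    gray[disc] <- 60
    m2 <- globalOtsuMask(gray)
    expect_true(all(m2[disc]))
    expect_true(mean(m2[!disc]) < 0.01)

    ## inverted polarity: light objects on dark ground select the ground
    m3 <- globalOtsuMask(255 - gray)
    expect_true(all(m3[!disc][1:10] | TRUE))  # foreground is the background
    expect_true(all(!m3[disc]))
    expect_true(all(m3[!disc]))

    expect_error(globalOtsuMask(matrix(5, 4, 4)), "degenerate")
})

test_that("polarity flag mirrors the threshold comparison", {
    set.seed(2)
    g <- matrix(sample(0:255, 400, TRUE), 20, 20)
    expect_identical(globalOtsuMask(g, darkForeground = TRUE),
                     globalOtsuMask(255 - g, darkForeground = FALSE))
    expect_identical(localAdaptiveMask(g, radius = 3, darkForeground = TRUE),
                     localAdaptiveMask(255 - g, radius = 3,
                                       darkForeground = FALSE))
})

test_that("local adaptive mask separates and rejects flat regions", {
    flat <- matrix(128, 50, 50)
    expect_false(any(localAdaptiveMask(flat)))
    expect_false(any(localAdaptiveMask(flat, C = 5)))

    ## isolated dark disc on a flat background is recovered
    g <- matrix(200, 60, 60)
    disc <- discMask(60, 60, 30, 30, 5)
    g[disc] <- 60
    m <- localAdaptiveMask(g, radius = 20)
    expect_true(all(m[disc]))

    ## a 2-px bright ridge between two dark discs stays background
    g2 <- matrix(200, 40, 60)
    d1 <- discMask(40, 60, 25, 20, 6)
    d2 <- discMask(40, 60, 36, 20, 6)
    ridge <- !d1 & !d2 &
        outer(seq_len(40), seq_len(60), function(r, c) c >= 30 & c <= 32)
    g2[d1 | d2] <- 60
    m2 <- localAdaptiveMask(g2, radius = 10)
    expect_true(all(!m2[ridge & abs(row(g2) - 20) < 5]))
    expect_error(localAdaptiveMask(g2, radius = 0), "radius")
})

test_that("watershed keeps single objects and splits touching ones", {
    ## single disc: one label, area preserved up to boundary pixels
    m <- discMask(60, 60, 30, 30, 10)
    lab <- watershedSplit(m)
    expect_equal(max(lab@mask), 1L)
    expect_gte(sum(lab@mask == 1L), sum(m) - 40)

    ## two overlapping discs, centres 1.5 radii apart -> two labels
    r <- 10
    m2 <- discMask(60, 80, 30, 30, r) | discMask(60, 80, 45, 30, r)
    lab2 <- watershedSplit(m2)
    expect_equal(max(lab2@mask), 2L)
    cen <- lapply(1:2, function(k) {
        idx <- which(lab2@mask == k, arr.ind = TRUE)
        colMeans(idx)
    })
    cx <- sort(vapply(cen, `[`, 0, 2L))
    expect_lt(abs(cx[1] - 30), 2.5)
    expect_lt(abs(cx[2] - 45), 2.5)

    ## k disjoint discs -> k labels
    m3 <- matrix(FALSE, 60, 100)
    for (cx0 in c(15, 45, 80)) m3 <- m3 | discMask(60, 100, cx0, 30, 6)
    expect_equal(max(watershedSplit(m3)@mask), 3L)

    ## empty mask -> empty labeling, not an error
    expect_equal(max(watershedSplit(matrix(FALSE, 10, 10))@mask), 0L)
})

test_that("morphometry recovers known shapes", {
    ## 10x10 px square at 0.5 um/px: area 25 um^2
    lab <- matrix(0L, 40, 40)
    lab[10:19, 15:24] <- 1L
    df <- measureNuclei(lab, resolution = 0.5, minArea = 8)
    expect_equal(nrow(df), 1L)
    expect_equal(df$area, 25)
    expect_equal(df$x, (19.5 - 0.5) * 0.5, tolerance = 1e-9)  # centre col 19.5
    expect_equal(df$y, (14.5 - 0.5) * 0.5, tolerance = 1e-9)

    ## rasterised ellipse, full axes 20 x 10 px, rotated 40 degrees
    H <- 60; W <- 60
    th <- 40 * pi / 180
    xs <- (col(matrix(0, H, W)) - 30.5)
    ys <- (row(matrix(0, H, W)) - 30.5)
    u <- (xs * cos(th) + ys * sin(th)) / 10
    v <- (-xs * sin(th) + ys * cos(th)) / 5
    ell <- (u^2 + v^2 <= 1) * 1L
    dfe <- measureNuclei(ell, resolution = 0.5, minArea = 0)
    expect_equal(dfe$major / 0.5, 20, tolerance = 0.1)
    expect_equal(dfe$minor / 0.5, 10, tolerance = 0.1)
    expect_lt(abs(dfe$theta - 40), 5)

    ## disc: circularity within [0.9, 1]
    disc <- discMask(50, 50, 25, 25, 12) * 1L
    dfd <- measureNuclei(disc, resolution = 0.5)
    expect_gte(dfd$circularity, 0.9)
    expect_lte(dfd$circularity, 1)

    ## border and min-area filters
    border <- matrix(0L, 20, 20); border[1:5, 5:9] <- 1L
    expect_equal(nrow(measureNuclei(border, 0.5)), 0L)
    tiny <- matrix(0L, 20, 20); tiny[10:11, 10:11] <- 1L  # 1 um^2
    expect_equal(nrow(measureNuclei(tiny, 0.5)), 0L)
    expect_equal(nrow(measureNuclei(matrix(0L, 5, 5), 0.5)), 0L)
})

test_that("morphometry is equivariant under 90-degree rotation", {
    set.seed(31)
    H <- 80; W <- 60
    lab <- matrix(0L, H, W)
    k <- 0L
    for (i in 1:4) {
        th <- runif(1, 10, 170) * pi / 180
        cx <- runif(1, 15, W - 15); cy <- runif(1, 15, H - 15)
        xs <- col(lab) - cx; ys <- row(lab) - cy
        u <- (xs * cos(th) + ys * sin(th)) / 9
        v <- (-xs * sin(th) + ys * cos(th)) / 5
        sel <- u^2 + v^2 <= 1 & lab == 0L
        if (sum(sel) > 40) { k <- k + 1L; lab[sel] <- k }
    }
    lab <- matrix(as.integer(factor(lab, levels = c(0, sort(unique(lab[lab > 0]))))) - 1L, H, W)
    df <- measureNuclei(lab, 0.5, minArea = 0, dropBorder = FALSE)
    rot <- nucleomorph:::.d4Matrix(lab, "rot90")
    dfr <- measureNuclei(rot, 0.5, minArea = 0, dropBorder = FALSE)
    expect_equal(nrow(df), nrow(dfr))
    ## match by area, compare centroids and angles
    ord <- order(df$area); ordr <- order(dfr$area)
    df <- df[ord, ]; dfr <- dfr[ordr, ]
    keep <- df$ratio >= 1.3
    expTheta <- df$theta + 90
    expTheta[expTheta > 180] <- expTheta[expTheta > 180] - 180
    expect_true(all(abs(dfr$theta[keep] - expTheta[keep]) < 2 |
                    abs(abs(dfr$theta[keep] - expTheta[keep]) - 180) < 2))
    ## centroid map: (x, y) -> (H_um - y, x)
    Hum <- H * 0.5
    expect_equal(dfr$x, Hum - df$y, tolerance = 1e-6)
    expect_equal(dfr$y, df$x, tolerance = 1e-6)
})

test_that("the full recipe recovers rendered, well-separated nuclei", {
    ## effectively unclustered (one offspring per parent) so the
    ## hard-core thinning keeps nuclei well separated
    cfg <- generatorConfig(widthUm = 200, heightUm = 200, density = 1200,
                           parentDensity = 1200, areaMedian = c(35, 55),
                           minSpacing = 16, edgeMargin = 10)
    truth <- generateSnapshot(cfg, 0, seed = 76)
    expect_gte(nNuclei(truth), 25)
    rgb <- renderHE(truth, seed = 78)
    pred <- segmentImage(rgb, nativeRes = 0.5, verbose = FALSE)
    cc <- concordanceQC(pred, truth, tolUm = 2)
    expect_gt(cc, 0.9)
    expect_true(attr(cc, "passesQC"))

    ## blank image: no nuclei
    blank <- renderHE(TissueSnapshot("b", width = 100, height = 100),
                      seed = 5)
    expect_equal(nNuclei(segmentImage(blank, 0.5, verbose = FALSE)), 0L)
})

test_that("concordance handles identity, misses and the strict QC cut", {
    t10 <- makeRandomSnapshot(10, widthUm = 100, heightUm = 100, seed = 55)
    expect_equal(as.numeric(concordanceQC(t10, t10)), 1)
    empty <- TissueSnapshot("e", width = 100, height = 100)
    expect_equal(as.numeric(concordanceQC(empty, t10)), 0)
    ## 7 of 10 within tolerance: exactly 0.7 fails the strict > 0.70 cut
    pred <- nuclei(t10)[1:7, ]
    p7 <- TissueSnapshot("p", pred, width = 100, height = 100)
    cc <- concordanceQC(p7, t10, tolUm = 2)
    expect_equal(as.numeric(cc), 0.7)
    expect_false(attr(cc, "passesQC"))
    bad <- TissueSnapshot("b", width = 50, height = 100)
    expect_error(concordanceQC(bad, t10), "extent")
})
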