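mkPatchWithNuclei <- function(areas, size = 64, seed = 1) {
    ## build a FeaturePatch whose nuclei have the given areas
    set.seed(seed)
    arr <- array(0, dim = c(size, size, 12))
    pos <- cbind(sample(size, length(areas)), sample(size, length(areas)))
    while (anyDuplicated(pos))
        pos <- cbind(sample(size, length(areas)), sample(size, length(areas)))
    for (k in seq_along(areas)) {
        arr[pos[k, 1], pos[k, 2], 1:6] <- c(8, 4, 2, areas[k], 19, 0.9)
        arr[pos[k, 1], pos[k, 2], 6 + sample.int(6, 1)] <- 1
    }
    new("FeaturePatch", data = arr, specimenId = "t", label = NA_integer_,
        x0 = 1L, y0 = 1L, resolution = 2)
}

test_that("ranking into equal groups drops the top remainder", {
    set.seed(8)
    sc <- runif(11161)
    g <- rankAndGroup(sc, 15)
    expect_equal(attr(g, "groupSize"), 744L)
    expect_equal(as.vector(table(g)), rep(744L, 15))
    expect_equal(sum(is.na(g)), 1L)
    ## the dropped score is the maximum (highest-score tail)
    expect_equal(which(is.na(g)), which.max(sc))
    ## concatenating members in group order reproduces the sorted list
    expect_equal(sc[order(g, sc, na.last = NA)],
                 sort(sc)[seq_len(744 * 15)])
    ## group means increase with index
    gm <- tapply(sc, g, mean)
    expect_true(all(diff(gm) > 0))

    ## singleton groups in sorted order
    g15 <- rankAndGroup(c(5, 3, 9, 1, 7, 2, 8, 4, 6, 10, 11, 15, 13, 12, 14),
                        15)
    expect_equal(order(g15), order(c(5, 3, 9, 1, 7, 2, 8, 4, 6, 10, 11, 15,
                                     13, 12, 14)))
    expect_error(rankAndGroup(1:10, 15), "fewer")
})

test_that("tied scores break stably by insertion order", {
    sc <- c(0.5, 0.2, 0.5, 0.2, 0.5, 0.2)
    g <- rankAndGroup(sc, 3)
    ## sorted: the three 0.2s (input order 2,4,6), then the 0.5s (1,3,5)
    expect_equal(g, c(2L, 1L, 3L, 1L, 3L, 2L), ignore_attr = TRUE)
})

test_that("intra-patch statistics use the population variance", {
    p1 <- mkPatchWithNuclei(40)
    st <- patchStats(p1)
    expect_equal(st$n, 1L)
    expect_equal(st$mean_area, 40)
    expect_equal(st$var_area, 0)

    p3 <- mkPatchWithNuclei(c(10, 20, 30))
    st3 <- patchStats(p3)
    expect_equal(st3$mean_area, 20)
    expect_equal(st3$var_area, 200 / 3)

    pe <- new("FeaturePatch", data = array(0, c(16, 16, 12)),
              specimenId = "e", label = NA_integer_, x0 = 1L, y0 = 1L,
              resolution = 2)
    ste <- patchStats(pe)
    expect_true(ste$empty)
    expect_true(is.na(ste$mean_area))
})

test_that("group summaries reproduce constructed means with zero SE for ties", {
    ps <- c(lapply(1:4, function(i) mkPatchWithNuclei(c(9, 11), seed = i)),
            lapply(1:4, function(i) mkPatchWithNuclei(c(19, 21), seed = i)))
    tab <- patchStatsTable(ps, group = rep(1:2, each = 4))
    gs <- groupSummary(tab)
    a1 <- gs[gs$group == 1 & gs$feature == "area", ]
    a2 <- gs[gs$group == 2 & gs$feature == "area", ]
    expect_equal(a1$meanOfMeans, 10)
    expect_equal(a2$meanOfMeans, 20)
    expect_equal(a1$meanOfVars, 1)    # population var of {9, 11}
    expect_equal(a1$seOfMeans, 0)     # identical patches
    expect_equal(a2$seOfVars, 0)
    expect_error(groupSummary(tab[0, ]), "group|empty")
})

test_that("AUC equals the pair-counting oracle on random instances", {
    expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
    expect_equal(rocAuc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
    expect_equal(rocAuc(rep(0.5, 10), rep(0:1, 5)), 0.5)
    expect_error(rocAuc(1:4, rep(1, 4)), "both classes")

    set.seed(13)
    for (k in 1:200) {
        n <- sample(4:60, 1)
        labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
        scores <- if (k %% 3 == 0) sample(1:5, n, TRUE)  # heavy ties
                  else rnorm(n)
        expect_equal(rocAuc(scores, labels), bruteAuc(scores, labels),
                     info = paste("instance", k))
    }
    ## complement symmetry for tie-free scores
    set.seed(14)
    sc <- rnorm(40); lb <- rep(0:1, 20)
    expect_equal(rocAuc(sc, lb) + rocAuc(-sc, lb), 1)
})

test_that("bootstrap CI behaves at the degenerate ends and covers the point", {
    set.seed(15)
    sep <- c(rnorm(20, 0), rnorm(20, 10))
    lb <- rep(0:1, each = 20)
    ci <- aucCI(sep, lb, nBoot = 200, seed = 1)
    expect_equal(unname(ci), c(1, 1))

    one <- aucCI(rnorm(30), rep(0:1, 15), nBoot = 1, seed = 3)
    expect_equal(one[1], one[2])

    ## percentile interval contains the point AUC on null data
    cover <- 0
    for (k in 1:40) {
        set.seed(400 + k)
        sc <- rnorm(30); lb2 <- rep(0:1, 15)
        a <- rocAuc(sc, lb2)
        ci2 <- aucCI(sc, lb2, nBoot = 200, seed = k)
        cover <- cover + (a >= ci2[1] && a <= ci2[2])
    }
    expect_gte(cover / 40, 0.95)
    expect_error(aucCI(1:3, c(0, 1, 1)), "at least 2")
})

test_that("digital stain blends only strictly above threshold", {
    rgb <- array(100, dim = c(32, 32, 3))
    mk <- function(p) new("ERHeatmap", logits = matrix(0, 1, 1),
                          prob = matrix(p, 1, 1), score = p,
                          specimenId = "t")
    expect_identical(digitalStain(rgb, mk(0.4)), rgb)
    expect_identical(digitalStain(rgb, mk(0.5)), rgb)   # strict >
    st <- digitalStain(rgb, mk(0.9), alpha = 0.35)
    expect_equal(st[1, 1, 1], 0.65 * 100 + 0.35 * 255)
    expect_equal(st[1, 1, 2], 65)
    expect_true(all(st[, , 1] > 100))
})

test_that("baseline learns separable features and is null-calibrated", {
    ## linearly separable toy: training AUC 1
    ps <- c(lapply(1:30, function(i) mkPatchWithNuclei(runif(3, 10, 20),
                                                       seed = i)),
            lapply(1:30, function(i) mkPatchWithNuclei(runif(3, 40, 60),
                                                       seed = 100 + i)))
    labs <- rep(0:1, each = 30)
    bl <- logisticBaselineTrain(ps, labs)
    trainScores <- vapply(ps, function(p) {
        tab <- patchStats(p)
        X <- as.matrix(tab[, bl$features])
        Xs <- sweep(sweep(X, 2, bl$center), 2, bl$scale, "/")
        suppressWarnings(stats::predict(bl$fit,
                                        newdata = as.data.frame(Xs),
                                        type = "response"))
    }, numeric(1))
    expect_equal(rocAuc(trainScores, labs), 1)
    ## the planted area effect gets positive coefficients
    expect_gt(coef(bl$fit)[["mean_area"]], 0)

    ## labels independent of features: AUC near 0.5
    set.seed(77)
    X <- matrix(rnorm(2000 * 12), 2000, 12)
    colnames(X) <- bl$features
    y <- rbinom(2000, 1, 0.5)
    df <- as.data.frame(X); df$y <- y
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    expect_lt(abs(rocAuc(stats::predict(fit, type = "response"), y) - 0.5),
              0.07)

    expect_error(logisticBaselineTrain(ps, rep(1, 60)), "single class")
})

test_that("baseline image score averages patch probabilities", {
    ## image with nuclei everywhere: score = mean of per-patch p
    s <- makeRandomSnapshot(200, widthUm = 256, heightUm = 256, seed = 2,
                            label = 1L)
    img <- encodeSnapshot(s)
    ps <- c(lapply(1:20, function(i) mkPatchWithNuclei(runif(3, 10, 20),
                                                       seed = i)),
            lapply(1:20, function(i) mkPatchWithNuclei(runif(3, 40, 60),
                                                       seed = 50 + i)))
    bl <- logisticBaselineTrain(ps, rep(0:1, each = 20))
    ## toy fit is perfectly separable; glm prediction warns about it
    sc <- suppressWarnings(logisticBaselineScore(bl, img, patchSize = 64))
    expect_true(is.finite(sc) && sc >= 0 && sc <= 1)
    ## empty image: undefined score with a flag
    e <- encodeSnapshot(TissueSnapshot("e", width = 256, height = 256))
    expect_warning(se <- logisticBaselineScore(bl, e, patchSize = 64),
                   "undefined")
    expect_true(is.na(se))
    expect_true(attr(se, "undefined"))
})
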