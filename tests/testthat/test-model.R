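featFromSnapshot <- function(n, seed, widthUm = 200, heightUm = 200,
                             label = NA) {
    encodeSnapshot(makeRandomSnapshot(n, widthUm = widthUm,
                                      heightUm = heightUm, seed = seed,
                                      label = label))
}

test_that("default architecture meets the parameter and layer contract", {
    cfg <- networkConfig()
    m <- buildNetwork(cfg, seed = 1)
    convParams <- sum(vapply(m@weights, length, integer(1)))
    ## 3*3*12*32+32 + 3*3*32*64+64 + 3*3*64*96+96 + 3*3*96*128+128 +
    ## 3*3*128*224+224 + 1*1*224*1+1
    expect_equal(convParams, 446593L)
    expect_equal(parameterCount(m), 446595L)   # + batch-norm gamma/beta
    expect_lt(abs(parameterCount(m) - 4.6e5) / 4.6e5, 0.10)
    expect_equal(cfg$nConvLayers, 6L)
    expect_equal(cfg$nPoolLayers, 5L)
    expect_equal(cfg$nGlobalMeanLayers, 1L)
    expect_equal(cfg$nBatchNormLayers, 1L)
})

test_that("builds are deterministic given the seed", {
    a <- buildNetwork(networkConfig(), seed = 7)
    b <- buildNetwork(networkConfig(), seed = 7)
    c <- buildNetwork(networkConfig(), seed = 8)
    expect_identical(a@weights, b@weights)
    expect_false(identical(a@weights$W1, c@weights$W1))
})

test_that("heatmap geometry follows the five pooling stages", {
    m <- buildNetwork(networkConfig(), seed = 1)
    f <- featFromSnapshot(40, seed = 2)          # 100 x 100 px grid
    expect_warning(hm <- predictHeatmap(m, f), "not been trained")
    expect_equal(dim(hm@logits), c(3L, 3L))      # 100->50->25->12->6->3
    expect_true(hm@score >= 0 && hm@score <= 1)
    tiny <- encodeSnapshot(makeRandomSnapshot(3, widthUm = 40,
                                              heightUm = 40, seed = 3))
    expect_error(suppressWarnings(predictHeatmap(m, tiny)), "32")
})

test_that("inference is deterministic and blind to empty-input position", {
    m <- buildNetwork(networkConfig(), seed = 4)
    f <- featFromSnapshot(30, seed = 5)
    h1 <- suppressWarnings(predictHeatmap(m, f))
    h2 <- suppressWarnings(predictHeatmap(m, f))
    expect_identical(h1@logits, h2@logits)
    ## two all-zero images share the constant-input baseline score
    e1 <- encodeSnapshot(TissueSnapshot("e1", width = 200, height = 200))
    e2 <- encodeSnapshot(TissueSnapshot("e2", width = 200, height = 200))
    expect_equal(suppressWarnings(predictHeatmap(m, e1))@score,
                 suppressWarnings(predictHeatmap(m, e2))@score)
})

test_that("patch sampling is seeded and honours degenerate inputs", {
    imgs <- lapply(1:3, function(i) featFromSnapshot(25, seed = 10 + i,
                                                     label = 0L))
    expect_length(sampleTrainingPatches(imgs, 0, 64, seed = 1), 0L)
    a <- sampleTrainingPatches(imgs, 10, 64, seed = 3)
    b <- sampleTrainingPatches(imgs, 10, 64, seed = 3)
    expect_identical(lapply(a, featureArray), lapply(b, featureArray))
    ## a single source image exactly the patch size: identical windows
    one <- featFromSnapshot(20, seed = 30)       # 100 x 100
    p5 <- sampleTrainingPatches(list(one), 5, 100, seed = 2,
                                augment = FALSE)
    for (p in p5) expect_identical(featureArray(p), featureArray(one))
    ## too-small images are skipped with a warning
    small <- featFromSnapshot(5, seed = 31, widthUm = 80, heightUm = 80)
    expect_warning(sampleTrainingPatches(list(one, small), 3, 100,
                                         seed = 1), "skipped")
    expect_error(suppressWarnings(
        sampleTrainingPatches(list(small), 3, 100, seed = 1)),
        "no image")
})

test_that("zero-epoch training changes nothing; single-class input errors", {
    m <- buildNetwork(networkConfig(), seed = 6)
    imgs <- lapply(1:4, function(i) featFromSnapshot(25, seed = 40 + i,
                                                     label = (i > 2) * 1L))
    m0 <- trainNetwork(m, imgs, config = trainConfig(
        patchSize = 64, epochs = 0, epochsPhase2 = 0, valFraction = 0,
        seed = 1))
    expect_identical(m0@weights, m@weights)
    expect_false(m0@trained)
    expect_error(trainNetwork(m, imgs, labels = rep(1, 4),
                              config = trainConfig(patchSize = 64)),
                 "single class")
})

test_that("the network can overfit a tiny fixed patch set", {
    ## capacity sanity run: 8 fixed patches, no dropout, aggressive
    ## step size (the output batch-norm gain has to grow for the
    ## sigmoid to saturate, which is slow at the default rate)
    imgs <- lapply(1:8, function(i)
        encodeSnapshot(generateSnapshot(
            generatorConfig(widthUm = 128, heightUm = 128),
            classLabel = (i > 4) * 1, seed = 50 + i)))
    m <- buildNetwork(networkConfig(dropout = 0), seed = 2)
    mt <- trainNetwork(m, imgs, config = trainConfig(
        patchSize = 64, patchesPerEpoch = 8, batchSize = 8, epochs = 200,
        epochsPhase2 = 0, valFraction = 0, augment = FALSE, lr = 0.02,
        seed = 3))
    expect_lt(median(tail(mt@history$trainLoss, 10)), 0.1)
    expect_true(mt@trained)
    expect_equal(nrow(mt@history), 200L)
})

test_that("training is reproducible run-to-run with fixed seeds", {
    imgs <- lapply(1:4, function(i) featFromSnapshot(30, seed = 60 + i,
                                                     label = (i %% 2)))
    tc <- trainConfig(patchSize = 64, patchesPerEpoch = 10, batchSize = 5,
                      epochs = 2, epochsPhase2 = 1, valFraction = 0,
                      seed = 11)
    m <- buildNetwork(networkConfig(), seed = 1)
    r1 <- trainNetwork(m, imgs, config = tc)
    r2 <- trainNetwork(m, imgs, config = tc)
    expect_identical(r1@weights, r2@weights)
    expect_identical(r1@history, r2@history)
})

test_that("specimen scoring keeps order, labels and the sigmoid range", {
    m <- buildNetwork(networkConfig(), seed = 3)
    imgs <- lapply(1:3, function(i) featFromSnapshot(20, seed = 70 + i,
                                                     label = (i %% 2)))
    tab <- suppressWarnings(scoreSpecimens(m, imgs))
    expect_equal(tab$specimen_id,
                 vapply(imgs, specimenId, character(1)))
    expect_equal(tab$label, vapply(imgs, erLabel, integer(1)))
    expect_true(all(tab$score >= 0 & tab$score <= 1))
    empty <- scoreSpecimens(m, list())
    expect_equal(nrow(empty), 0L)
    expect_named(empty, c("specimen_id", "score", "label"))
})
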