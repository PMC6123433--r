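## Weakly supervised fully convolutional classifier: configuration,
## initialisation, patch sampling, two-phase training and inference.

.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(seed)
    on.exit({
        if (had) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    force(code)
}

## spatial size after the five 2x2 floor poolings
.poolOut <- function(s) {
    for (i in 1:5) s <- s %/% 2L
    as.integer(s)
}

#' Network configuration
#'
#' The architecture is fixed in topology -- five 3x3 feature
#' convolutions each followed by leaky ReLU and 2x2 max pooling
#' (floor on odd sizes), dropout, a 1x1 single-logit classifier
#' convolution, a global mean over the logit map and one
#' batch-normalisation layer applied to the scalar mean logit before
#' the sigmoid -- i.e. six convolutional layers, five pooling layers,
#' one global mean layer and one batch-normalisation layer. The
#' default widths give 446,593 convolutional parameters (446,595 with
#' the batch-norm affine pair), within 10 percent of 4.6e5.
#'
#' @param widths integer vector of the five feature-conv channel
#'   widths.
#' @param kernel kernel size of the feature convolutions (fixed at 3).
#' @param leakySlope negative slope of the leaky ReLU.
#' @param dropout dropout rate applied immediately before the
#'   classifier convolution.
#' @param standardizeInput standardise the six shape channels at the
#'   input layer using train-set mean/sd at nucleus pixels.
#' @return a list of class `NetworkConfig`.
#' @export
networkConfig <- function(widths = c(32L, 64L, 96L, 128L, 224L),
                          kernel = 3L, leakySlope = 0.01, dropout = 0.5,
                          standardizeInput = TRUE) {
    stopifnot(length(widths) == 5L, all(widths >= 1), kernel == 3L,
              dropout >= 0, dropout < 1)
    structure(list(widths = as.integer(widths), kernel = 3L,
                   leakySlope = leakySlope, dropout = dropout,
                   standardizeInput = isTRUE(standardizeInput),
                   nConvLayers = 6L, nPoolLayers = 5L,
                   nGlobalMeanLayers = 1L, nBatchNormLayers = 1L),
              class = "NetworkConfig")
}

#' Training configuration
#'
#' Two-phase weak-label training: phase 1 holds out `valFraction` of
#' the specimens (stratified by class) and monitors their loss; phase
#' 2 adds the held-out specimens back and keeps training. Patches are
#' sampled uniformly (image, then window) each epoch and each receives
#' a uniformly random dihedral transform when `augment` is TRUE.
#'
#' @param patchSize training window side in pixels (100 px = 200 um).
#' @param patchesPerEpoch patches sampled per epoch.
#' @param batchSize minibatch size (also the batch-norm batch).
#' @param epochs phase-1 epochs.
#' @param epochsPhase2 phase-2 epochs (on all training specimens).
#' @param lr Adam learning rate.
#' @param valFraction specimen-level holdout fraction in `[0, 1)`.
#' @param valEvery compute the holdout loss every this many epochs.
#' @param seed RNG seed recorded in the trained model.
#' @param augment random dihedral augmentation.
#' @param bnMomentum running-statistics momentum of the batch norm.
#' @param bnEps batch-norm variance floor.
#' @return a list of class `TrainConfig`.
#' @export
trainConfig <- function(patchSize = 100L, patchesPerEpoch = 100L,
                        batchSize = 25L, epochs = 45L, epochsPhase2 = 5L,
                        lr = 1e-3, valFraction = 0.2, valEvery = 5L,
                        seed = 1L, augment = TRUE, bnMomentum = 0.9,
                        bnEps = 1e-5) {
    stopifnot(valFraction >= 0, valFraction < 1, patchSize >= 32,
              batchSize >= 2, epochs >= 0, epochsPhase2 >= 0)
    structure(list(patchSize = as.integer(patchSize),
                   patchesPerEpoch = as.integer(patchesPerEpoch),
                   batchSize = as.integer(batchSize),
                   epochs = as.integer(epochs),
                   epochsPhase2 = as.integer(epochsPhase2),
                   lr = lr, valFraction = valFraction,
                   valEvery = as.integer(valEvery), seed = as.integer(seed),
                   augment = isTRUE(augment), bnMomentum = bnMomentum,
                   bnEps = bnEps),
              class = "TrainConfig")
}

#' Build (initialise) the network
#'
#' He-normal initialisation of all convolution weights, zero biases,
#' batch-norm gamma 1 / beta 0 with running statistics (0, 1). Two
#' builds with the same seed have identical weights. The network is
#' fully convolutional: any input with both sides at least 32 px is
#' accepted at inference.
#'
#' @param config a [networkConfig()].
#' @param seed integer seed for the weight initialisation.
#' @return an untrained [NucleoNet-class].
#' @export
buildNetwork <- function(config = networkConfig(), seed = 1L) {
    stopifnot(inherits(config, "NetworkConfig"))
    wdt <- config$widths
    cin <- c(12L, wdt[-5L])
    weights <- list()
    .withSeed(seed, {
        for (l in 1:5) {
            fanIn <- 9L * cin[l]
            weights[[paste0("W", l)]] <-
                array(rnorm(9L * cin[l] * wdt[l], sd = sqrt(2 / fanIn)),
                      dim = c(3L, 3L, cin[l], wdt[l]))
            weights[[paste0("b", l)]] <- numeric(wdt[l])
        }
        weights[["W6"]] <- rnorm(wdt[5L], sd = sqrt(2 / wdt[5L]))
        weights[["b6"]] <- 0
    })
    new("NucleoNet", config = unclass(config), weights = weights,
        bn = list(gamma = 1, beta = 0, rmean = 0, rvar = 1),
        inputScale = NULL, trained = FALSE, seed = as.integer(seed),
        history = data.frame(epoch = integer(), phase = integer(),
                             trainLoss = numeric(), valLoss = numeric()))
}

## per-channel standardisation statistics over nucleus pixels
.computeInputScale <- function(arrays) {
    vals <- vector("list", 6L)
    for (arr in arrays) {
        occ <- .occupiedMask(arr)
        for (ch in 1:6)
            vals[[ch]] <- c(vals[[ch]], arr[, , ch][occ])
    }
    mu <- vapply(vals, function(v) if (length(v)) mean(v) else 0, 0)
    sdv <- vapply(vals, function(v) if (length(v) > 1) sd(v) else 1, 0)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    list(mean = mu, sd = sdv)
}

.occupiedMask <- function(arr) {
    (arr[, , 7L] + arr[, , 8L] + arr[, , 9L] +
     arr[, , 10L] + arr[, , 11L] + arr[, , 12L]) != 0
}

.applyInputScale <- function(arr, scale) {
    if (is.null(scale)) return(arr)
    occ <- .occupiedMask(arr)
    for (ch in 1:6) {
        m <- arr[, , ch]
        m[occ] <- (m[occ] - scale$mean[ch]) / scale$sd[ch]
        arr[, , ch] <- m
    }
    arr
}

#' Sample random training patches
#'
#' Uniform random image choice, then uniform window position, then
#' (optionally) a uniformly random dihedral transform applied through
#' [transformFeatureImage()] so the orientation bins stay consistent.
#' Images smaller than the patch size are skipped with a warning.
#'
#' @param images list of [SparseFeatureImage-class].
#' @param n number of patches.
#' @param patchSize window side in pixels.
#' @param seed RNG seed.
#' @param augment apply random dihedral transforms.
#' @return list of [FeaturePatch-class].
#' @export
sampleTrainingPatches <- function(images, n, patchSize = 100L, seed = 1L,
                                  augment = TRUE) {
    usable <- vapply(images, function(im) {
        d <- dim(im@data)
        d[1L] >= patchSize && d[2L] >= patchSize
    }, logical(1))
    if (any(!usable))
        warning(sum(!usable), " image(s) smaller than the patch size; skipped")
    images <- images[usable]
    if (!length(images)) stop("no image large enough for the patch size",
                              call. = FALSE)
    if (n == 0) return(list())
    .withSeed(seed, {
        out <- vector("list", n)
        for (k in seq_len(n)) {
            i <- sample.int(length(images), 1L)
            d <- dim(images[[i]]@data)
            x0 <- sample.int(d[2L] - patchSize + 1L, 1L)
            y0 <- sample.int(d[1L] - patchSize + 1L, 1L)
            p <- extractPatch(images[[i]], x0, y0, patchSize)
            if (augment) p <- transformFeatureImage(p, sample(d4Ops, 1L))
            out[[k]] <- p
        }
        out
    })
}

## sample one raw patch array, optionally standardised and augmented
.samplePatchArray <- function(arrays, patchSize, augment, scale = NULL) {
    i <- sample.int(length(arrays), 1L)
    d <- dim(arrays[[i]])
    x0 <- sample.int(d[2L] - patchSize + 1L, 1L)
    y0 <- sample.int(d[1L] - patchSize + 1L, 1L)
    a <- arrays[[i]][y0:(y0 + patchSize - 1L), x0:(x0 + patchSize - 1L), ,
                     drop = FALSE]
    if (!is.null(scale)) a <- .applyInputScale(a, scale)
    if (augment) a <- .transformFeatureArray(a, sample(d4Ops, 1L))
    list(arr = a, img = i)
}

.stackPatches <- function(arrs) {
    d <- dim(arrs[[1L]])
    out <- array(0, dim = c(d, length(arrs)))
    for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
    out
}

.bceFromLogits <- function(m, y, bn, bnEps) {
    z <- bn$gamma * (m - bn$rmean) / sqrt(bn$rvar + bnEps) + bn$beta
    p <- pmin(pmax(1 / (1 + exp(-z)), 1e-12), 1 - 1e-12)
    mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Train the network on weakly labeled patches
#'
#' Patches inherit the label of their source image. Phase 1 trains on
#' a stratified subset of specimens and monitors the binary
#' cross-entropy of patches from the held-out specimens; phase 2 adds
#' the held-out specimens back. The loss is binary cross-entropy on
#' `sigmoid(batchnorm(mean logit))`; optimisation is Adam. Fully
#' seeded: the same configuration and seed reproduce the run.
#'
#' @param model an untrained (or partially trained) [NucleoNet-class].
#' @param images list of [SparseFeatureImage-class] with labels.
#' @param labels optional numeric/integer 0/1 vector overriding the
#'   image labels.
#' @param config a [trainConfig()].
#' @return the trained [NucleoNet-class] with `history` filled in.
#' @export
trainNetwork <- function(model, images, labels = NULL,
                         config = trainConfig()) {
    stopifnot(is(model, "NucleoNet"), inherits(config, "TrainConfig"))
    if (is.null(labels))
        labels <- vapply(images, function(im) as.numeric(im@label), 0)
    labels <- as.numeric(labels)
    if (anyNA(labels)) stop("all training images need a 0/1 label",
                            call. = FALSE)
    if (length(unique(labels)) < 2L)
        stop("training set contains a single class", call. = FALSE)
    arrays <- lapply(images, function(im) im@data)
    inputScale <- NULL
    if (isTRUE(model@config$standardizeInput)) {
        inputScale <- .computeInputScale(arrays)
        model@inputScale <- inputScale
        ## scaling is applied per sampled patch (not to whole-image
        ## copies) to keep the training memory footprint low
    }
    usable <- vapply(arrays, function(a)
        dim(a)[1L] >= config$patchSize && dim(a)[2L] >= config$patchSize,
        logical(1))
    if (any(!usable)) {
        warning(sum(!usable), " image(s) smaller than the patch size; skipped")
        arrays <- arrays[usable]; labels <- labels[usable]
    }
    slope <- model@config$leakySlope
    pDrop <- model@config$dropout
    h5 <- .poolOut(config$patchSize)
    C5 <- model@config$widths[5L]
    ## Adam state
    adam <- list(m = lapply(model@weights, function(w) w * 0),
                 v = lapply(model@weights, function(w) w * 0),
                 mg = c(gamma = 0, beta = 0), vg = c(gamma = 0, beta = 0),
                 t = 0L)
    bn <- model@bn
    history <- list()
    .withSeed(config$seed, {
        ## stratified specimen holdout
        valIdx <- integer(0)
        if (config$valFraction > 0) {
            for (cls in unique(labels)) {
                idx <- which(labels == cls)
                nv <- max(1L, round(config$valFraction * length(idx)))
                if (nv < length(idx))
                    valIdx <- c(valIdx, sample(idx, nv))
            }
        }
        trainIdx <- setdiff(seq_along(arrays), valIdx)
        ## fixed holdout patch set for monitoring
        valBatch <- NULL; valY <- NULL
        if (length(valIdx)) {
            nVal <- min(50L, 10L * length(valIdx))
            va <- vector("list", nVal); valY <- numeric(nVal)
            for (k in seq_len(nVal)) {
                s <- .samplePatchArray(arrays[valIdx], config$patchSize,
                                       FALSE, inputScale)
                va[[k]] <- s$arr
                valY[k] <- labels[valIdx][s$img]
            }
            valBatch <- .stackPatches(va)
        }
        runPhase <- function(idxSet, nEpochs, phase, epoch0) {
            for (e in seq_len(nEpochs)) {
                nP <- config$patchesPerEpoch
                pa <- vector("list", nP); py <- numeric(nP)
                for (k in seq_len(nP)) {
                    s <- .samplePatchArray(arrays[idxSet], config$patchSize,
                                           config$augment, inputScale)
                    pa[[k]] <- s$arr
                    py[k] <- labels[idxSet][s$img]
                }
                epLoss <- 0; nB <- 0L
                for (b0 in seq.int(1L, nP, by = config$batchSize)) {
                    b1 <- min(b0 + config$batchSize - 1L, nP)
                    if (b1 - b0 + 1L < 2L) next   # batch norm needs >= 2
                    xb <- .stackPatches(pa[b0:b1])
                    yb <- py[b0:b1]
                    nb <- b1 - b0 + 1L
                    dropmask <- if (pDrop > 0)
                        array(rbinom(h5 * h5 * C5 * nb, 1L, 1 - pDrop) /
                              (1 - pDrop), dim = c(h5, h5, C5, nb))
                        else numeric(0)
                    st <- cnn_train_step(model@weights, xb, yb,
                                         bn$gamma, bn$beta, config$bnEps,
                                         slope, dropmask)
                    ## Adam
                    adam$t <<- adam$t + 1L
                    corr1 <- 1 - 0.9^adam$t
                    corr2 <- 1 - 0.999^adam$t
                    for (nm in names(model@weights)) {
                        g <- st$grads[[nm]]
                        adam$m[[nm]] <<- 0.9 * adam$m[[nm]] + 0.1 * g
                        adam$v[[nm]] <<- 0.999 * adam$v[[nm]] + 0.001 * g^2
                        model@weights[[nm]] <<- model@weights[[nm]] -
                            config$lr * (adam$m[[nm]] / corr1) /
                            (sqrt(adam$v[[nm]] / corr2) + 1e-8)
                    }
                    for (nm in c("gamma", "beta")) {
                        g <- st$grads[[nm]]
                        adam$mg[nm] <<- 0.9 * adam$mg[nm] + 0.1 * g
                        adam$vg[nm] <<- 0.999 * adam$vg[nm] + 0.001 * g^2
                        bn[[nm]] <<- unname(bn[[nm]] - config$lr *
                            (adam$mg[nm] / corr1) /
                            (sqrt(adam$vg[nm] / corr2) + 1e-8))
                    }
                    bn$rmean <<- config$bnMomentum * bn$rmean +
                        (1 - config$bnMomentum) * st$batch_mean
                    bn$rvar <<- config$bnMomentum * bn$rvar +
                        (1 - config$bnMomentum) * st$batch_var
                    epLoss <- epLoss + st$loss; nB <- nB + 1L
                }
                valLoss <- NA_real_
                if (!is.null(valBatch) && phase == 1L &&
                    (e %% config$valEvery == 0L || e == nEpochs)) {
                    mlog <- cnn_forward_batch(model@weights, valBatch, slope)
                    valLoss <- .bceFromLogits(mlog, valY, bn, config$bnEps)
                }
                history[[length(history) + 1L]] <<-
                    data.frame(epoch = epoch0 + e, phase = phase,
                               trainLoss = if (nB) epLoss / nB else NA_real_,
                               valLoss = valLoss)
            }
        }
        if (config$epochs > 0L)
            runPhase(trainIdx, config$epochs, 1L, 0L)
        if (config$epochsPhase2 > 0L)
            runPhase(seq_along(arrays), config$epochsPhase2, 2L,
                     config$epochs)
    })
    model@bn <- bn
    model@history <- if (length(history)) do.call(rbind, history)
                     else model@history
    model@trained <- (config$epochs + config$epochsPhase2) > 0L
    model@seed <- config$seed
    validObject(model)
    model
}

#' Predict the spatial heatmap and specimen score
#'
#' Deterministic inference: dropout disabled, batch normalisation in
#' inference mode (running statistics). The heatmap has one logit per
#' output location (input size reduced by the five pooling stages);
#' the specimen score is `sigmoid(BN(mean logit))`, higher = more
#' ER-negative evidence.
#'
#' @param model a trained [NucleoNet-class].
#' @param img a [SparseFeatureImage-class] (both sides >= 32 px).
#' @param bnEps batch-norm variance floor.
#' @return an [ERHeatmap-class].
#' @export
predictHeatmap <- function(model, img, bnEps = 1e-5) {
    stopifnot(is(model, "NucleoNet"), is(img, "SparseFeatureImage"))
    if (!model@trained)
        warning("model has not been trained; scores are from random weights")
    d <- dim(img@data)
    if (d[1L] < 32L || d[2L] < 32L)
        stop("input smaller than the 32 px receptive-field minimum",
             call. = FALSE)
    arr <- .applyInputScale(img@data, model@inputScale)
    logits <- cnn_logit_map(model@weights, arr, model@config$leakySlope)
    bn <- model@bn
    norm <- function(v) bn$gamma * (v - bn$rmean) / sqrt(bn$rvar + bnEps) +
        bn$beta
    prob <- 1 / (1 + exp(-norm(logits)))
    score <- 1 / (1 + exp(-norm(mean(logits))))
    new("ERHeatmap", logits = logits, prob = prob, score = score,
        specimenId = img@specimenId)
}

#' Score a set of patches
#'
#' Per-patch score `sigmoid(BN(mean logit))` with the model in
#' inference mode (dropout off, running batch-norm statistics); used
#' to rank patches from ER-positive to ER-negative evidence.
#'
#' @param model a trained [NucleoNet-class].
#' @param patches list of [FeaturePatch-class] (side >= 32 px).
#' @param bnEps batch-norm variance floor.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
scorePatches <- function(model, patches, bnEps = 1e-5) {
    stopifnot(is(model, "NucleoNet"))
    bn <- model@bn
    vapply(patches, function(p) {
        arr <- .applyInputScale(p@data, model@inputScale)
        lm <- cnn_logit_map(model@weights, arr, model@config$leakySlope)
        z <- bn$gamma * (mean(lm) - bn$rmean) / sqrt(bn$rvar + bnEps) +
            bn$beta
        1 / (1 + exp(-z))
    }, numeric(1))
}

#' Score a set of specimens
#'
#' @param model a trained [NucleoNet-class].
#' @param objects list of [SparseFeatureImage-class] or
#'   [TissueSnapshot-class] (snapshots are encoded first).
#' @return data.frame with columns `specimen_id`, `score`, `label`,
#'   one row per input in input order.
#' @export
scoreSpecimens <- function(model, objects) {
    rows <- lapply(objects, function(ob) {
        if (is(ob, "TissueSnapshot")) ob <- encodeSnapshot(ob)
        hm <- predictHeatmap(model, ob)
        data.frame(specimen_id = ob@specimenId, score = hm@score,
                   label = ob@label)
    })
    if (!length(rows))
        return(data.frame(specimen_id = character(), score = numeric(),
                          label = integer()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
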