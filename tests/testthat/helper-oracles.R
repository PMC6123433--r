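## Independent oracles used across the suite. These deliberately do
## not call the package's own implementation paths.

## brute-force O(n^2) AUC: fraction of positive-negative pairs ordered
## correctly, ties counting one half
bruteAuc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

## exhaustive Otsu: the threshold t in 0..255 maximising between-class
## variance of the split {<= t} / {> t}
exhaustiveOtsu <- function(gray) {
    v <- as.integer(round(as.vector(gray)))
    best <- -Inf; bestT <- 0
    for (t in 0:254) {
        lo <- v[v <= t]; hi <- v[v > t]
        if (!length(lo) || !length(hi)) next
        w0 <- length(lo) / length(v); w1 <- 1 - w0
        bc <- w0 * w1 * (mean(lo) - mean(hi))^2
        if (bc > best) { best <- bc; bestT <- t }
    }
    bestT
}

## closed-form D4 transform of a snapshot's cells (coordinates in um,
## extent width x height, image convention y down); angle convention:
## degrees from +x towards +y, in (0, 180]
oracleTransformSnapshot <- function(snap, op) {
    df <- nuclei(snap)
    W <- snap@width; H <- snap@height
    pt <- switch(op,
        identity = list(x = df$x, y = df$y, W = W, H = H),
        rot90 = list(x = H - df$y, y = df$x, W = H, H = W),
        rot180 = list(x = W - df$x, y = H - df$y, W = W, H = H),
        rot270 = list(x = df$y, y = W - df$x, W = H, H = W),
        flip_h = list(x = W - df$x, y = df$y, W = W, H = H),
        flip_v = list(x = df$x, y = H - df$y, W = W, H = H),
        transpose = list(x = df$y, y = df$x, W = H, H = W),
        anti_transpose = list(x = H - df$y, y = W - df$x, W = H, H = W))
    ang <- switch(op,
        identity = df$theta, rot180 = df$theta,
        rot90 = df$theta + 90, rot270 = df$theta + 90,
        flip_h = 180 - df$theta, flip_v = 180 - df$theta,
        transpose = 90 - df$theta, anti_transpose = 90 - df$theta)
    ang <- ang %% 180
    ang[ang == 0] <- 180
    df$x <- pt$x; df$y <- pt$y; df$theta <- ang
    TissueSnapshot(snap@specimenId, df, width = pt$W, height = pt$H,
                   resolution = snap@resolution, label = snap@label)
}

## random valid snapshot with geometrically consistent shape fields
makeRandomSnapshot <- function(n, widthUm = 60, heightUm = 48, seed = 1,
                               avoid30 = FALSE, label = NA) {
    set.seed(seed)
    minor <- runif(n, 2, 6)
    ratio <- runif(n, 1, 2.5)
    major <- ratio * minor
    area <- pi * major * minor / 4
    a <- major / 2; b <- minor / 2
    perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
    theta <- runif(n, 0, 180)
    if (avoid30) {
        off <- abs(theta %% 30)
        bad <- off < 0.5 | off > 29.5
        while (any(bad)) {
            theta[bad] <- runif(sum(bad), 0, 180)
            off <- abs(theta %% 30)
            bad <- off < 0.5 | off > 29.5
        }
    }
    theta[theta == 0] <- 180
    df <- data.frame(x = runif(n, 0, widthUm), y = runif(n, 0, heightUm),
                     major = major, minor = minor, ratio = ratio,
                     area = area, perimeter = perim,
                     circularity = pmin(4 * pi * area / perim^2, 1),
                     theta = theta)
    TissueSnapshot(sprintf("rand_%d", seed), df, width = widthUm,
                   height = heightUm, resolution = 0.5, label = label)
}

## reference forward pass of the network in plain R (independent of
## the compiled backend): same-padding 3x3 convs, leaky ReLU, 2x2
## floor max pooling, 1x1 classifier, spatial mean
refForwardMeanLogit <- function(weights, x, slope = 0.01) {
    convSame <- function(a, W, b) {
        d <- dim(a); Cout <- dim(W)[4]
        ap <- array(0, c(d[1] + 2, d[2] + 2, d[3]))
        ap[2:(d[1] + 1), 2:(d[2] + 1), ] <- a
        out <- array(0, c(d[1], d[2], Cout))
        for (co in seq_len(Cout)) {
            acc <- matrix(b[co], d[1], d[2])
            for (ci in seq_len(d[3]))
                for (dc in -1:1) for (dr in -1:1)
                    acc <- acc + W[dr + 2, dc + 2, ci, co] *
                        ap[(2 + dr):(d[1] + 1 + dr),
                           (2 + dc):(d[2] + 1 + dc), ci]
            out[, , co] <- acc
        }
        out
    }
    pool2 <- function(a) {
        d <- dim(a); Ho <- d[1] %/% 2; Wo <- d[2] %/% 2
        out <- array(0, c(Ho, Wo, d[3]))
        for (ci in seq_len(d[3]))
            for (c in seq_len(Wo)) for (r in seq_len(Ho))
                out[r, c, ci] <- max(a[(2 * r - 1):(2 * r),
                                       (2 * c - 1):(2 * c), ci])
        out
    }
    a <- x
    for (l in 1:5) {
        z <- convSame(a, weights[[paste0("W", l)]],
                      weights[[paste0("b", l)]])
        z[z < 0] <- z[z < 0] * slope
        a <- pool2(z)
    }
    d <- dim(a)
    logit <- matrix(weights$b6, d[1], d[2])
    for (co in seq_len(d[3]))
        logit <- logit + weights$W6[co] * a[, , co]
    mean(logit)
}

## bind two 4-D arrays along the fourth dimension
abind_ <- function(a, b) {
    d <- dim(a)
    out <- array(0, c(d[1:3], d[4] + dim(b)[4]))
    out[, , , seq_len(d[4])] <- a
    out[, , , d[4] + seq_len(dim(b)[4])] <- b
    out
}

## sparse random feature-image-like array for backend tests
makeRandomFeatureArray <- function(H, W, nNuc, seed = 1) {
    set.seed(seed)
    arr <- array(0, dim = c(H, W, 12))
    pos <- cbind(sample(H, nNuc, replace = TRUE),
                 sample(W, nNuc, replace = TRUE))
    pos <- pos[!duplicated(pos), , drop = FALSE]
    for (k in seq_len(nrow(pos))) {
        arr[pos[k, 1], pos[k, 2], 1:6] <- runif(6, 0.5, 2)
        arr[pos[k, 1], pos[k, 2], 6 + sample.int(6, 1)] <- 1
    }
    arr
}
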