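## Seeded synthetic tissue: clustered nuclei point fields with
## class-dependent morphometric distributions, and rendered H&E-like
## RGB images for exercising the segmentation recipe.

#' Generator configuration
#'
#' Class-conditional distributions of a synthetic specimen. Nuclei
#' positions follow a Thomas cluster process (Poisson parents,
#' Gaussian offspring) mimicking epithelial nests. Nuclear areas are
#' log-normal; the class-1 (ER-negative) defaults have both a larger
#' area median and a larger log-sd than class 0, planting the
#' larger-and-more-heterogeneous-nuclei direction that the trained
#' classifier is expected to pick up. Magnitudes are desk-scale
#' fixture parameters, not measurements.
#'
#' @param widthUm,heightUm image extent in micrometres.
#' @param density nucleus density per square millimetre (both
#'   classes).
#' @param areaMedian length-2 vector: median nuclear area (um^2) for
#'   class 0 and class 1.
#' @param areaSigma length-2 vector: log-normal sigma of the area.
#' @param ratioMedian,ratioSigma log-normal parameters of the
#'   major/minor axis ratio (shared; resampled to stay >= 1).
#' @param parentDensity Thomas parent density per square millimetre.
#' @param clusterRadius Gaussian offspring sd in micrometres.
#' @param orientation `"uniform"` or `"nest"` (offspring of one parent
#'   share a preferred axis, exercising the orientation channels).
#' @param orientationKappa angular jitter sd (degrees) in nest mode.
#' @param minSpacing optional hard-core thinning distance in
#'   micrometres (0 = off); used by segmentation fixtures to keep
#'   nuclei non-touching.
#' @param edgeMargin keep nucleus centres at least this far (um) from
#'   the image border (0 = off); segmentation fixtures use it because
#'   border-clipped nuclei are discarded by design.
#' @return a list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(widthUm = 400, heightUm = 400, density = 3000,
                            areaMedian = c(35, 55),
                            areaSigma = c(0.25, 0.45),
                            ratioMedian = 1.4, ratioSigma = 0.2,
                            parentDensity = 60, clusterRadius = 20,
                            orientation = c("uniform", "nest"),
                            orientationKappa = 15, minSpacing = 0,
                            edgeMargin = 0) {
    orientation <- match.arg(orientation)
    stopifnot(widthUm > 0, heightUm > 0, density >= 0,
              all(areaMedian > 0), all(areaSigma > 0), ratioMedian >= 1,
              parentDensity > 0, clusterRadius > 0)
    structure(list(widthUm = widthUm, heightUm = heightUm,
                   density = density, areaMedian = areaMedian,
                   areaSigma = areaSigma, ratioMedian = ratioMedian,
                   ratioSigma = ratioSigma, parentDensity = parentDensity,
                   clusterRadius = clusterRadius, orientation = orientation,
                   orientationKappa = orientationKappa,
                   minSpacing = minSpacing, edgeMargin = edgeMargin),
              class = "GeneratorConfig")
}

## Ramanujan's ellipse perimeter approximation
.ellipsePerimeter <- function(major, minor) {
    a <- major / 2; b <- minor / 2
    pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Generate one synthetic labeled snapshot
#'
#' Thomas-process nucleus positions (parents Poisson with the
#' configured density, Gaussian offspring, points falling outside the
#' extent rejected), class-conditional log-normal areas and axis
#' ratios, orientations uniform on (0, 180] (or nest-aligned), minor
#' axis from `area = pi * major * minor / 4`, perimeter by Ramanujan's
#' approximation and circularity `4*pi*area/perimeter^2`. Fully
#' deterministic given the seed.
#'
#' @param config a [generatorConfig()].
#' @param classLabel 0 (ER-positive) or 1 (ER-negative).
#' @param seed RNG seed.
#' @param specimenId identifier (default derived from label and seed).
#' @return a [TissueSnapshot-class] at the 0.5 um/px source
#'   convention.
#' @export
generateSnapshot <- function(config = generatorConfig(), classLabel,
                             seed = 1L,
                             specimenId = sprintf("syn_c%d_s%d",
                                                  classLabel, seed)) {
    stopifnot(inherits(config, "GeneratorConfig"),
              classLabel %in% c(0, 1))
    W <- config$widthUm; H <- config$heightUm
    areaMm2 <- W * H / 1e6
    cls <- classLabel + 1L
    .withSeed(seed, {
        nParents <- rpois(1L, config$parentDensity * areaMm2)
        if (nParents == 0L && config$density > 0 && areaMm2 > 0)
            nParents <- 1L
        if (config$density == 0) nParents <- 0L
        px <- runif(nParents, 0, W)
        py <- runif(nParents, 0, H)
        meanOff <- if (nParents > 0)
            config$density * areaMm2 / nParents else 0
        xs <- ys <- numeric(0); parent <- integer(0)
        for (i in seq_len(nParents)) {
            k <- rpois(1L, meanOff)
            if (!k) next
            ox <- rnorm(k, px[i], config$clusterRadius)
            oy <- rnorm(k, py[i], config$clusterRadius)
            mg <- config$edgeMargin
            ok <- ox > mg & ox < W - mg & oy > mg & oy < H - mg
            xs <- c(xs, ox[ok]); ys <- c(ys, oy[ok])
            parent <- c(parent, rep(i, sum(ok)))
        }
        if (config$minSpacing > 0 && length(xs) > 1L) {
            keep <- rep(TRUE, length(xs))
            for (i in seq_along(xs)[-1L]) {
                d2 <- (xs[seq_len(i - 1L)][keep[seq_len(i - 1L)]] - xs[i])^2 +
                      (ys[seq_len(i - 1L)][keep[seq_len(i - 1L)]] - ys[i])^2
                if (length(d2) && min(d2) < config$minSpacing^2)
                    keep[i] <- FALSE
            }
            xs <- xs[keep]; ys <- ys[keep]; parent <- parent[keep]
        }
        n <- length(xs)
        df <- .emptyNuclei()
        if (n) {
            area <- stats::rlnorm(n, log(config$areaMedian[cls]),
                                  config$areaSigma[cls])
            ratio <- stats::rlnorm(n, log(config$ratioMedian),
                                   config$ratioSigma)
            bad <- ratio < 1
            while (any(bad)) {
                ratio[bad] <- stats::rlnorm(sum(bad),
                                            log(config$ratioMedian),
                                            config$ratioSigma)
                bad <- ratio < 1
            }
            theta <- if (config$orientation == "nest") {
                base <- runif(max(parent, 1L), 0, 180)
                (base[parent] + rnorm(n, 0, config$orientationKappa)) %% 180
            } else runif(n, 0, 180)
            theta[theta == 0] <- 180
            minor <- sqrt(4 * area / (pi * ratio))
            major <- ratio * minor
            perim <- .ellipsePerimeter(major, minor)
            df <- data.frame(x = xs, y = ys, major = major, minor = minor,
                             ratio = ratio, area = area, perimeter = perim,
                             circularity = pmin(4 * pi * area / perim^2, 1),
                             theta = theta)
        }
        TissueSnapshot(specimenId, df, width = W, height = H,
                       resolution = 0.5, label = as.integer(classLabel))
    })
}

#' Render a snapshot as an H&E-like RGB image
#'
#' Eosin-like pink background with additive Gaussian noise; each
#' nucleus drawn as a filled dark-purple (hematoxylin-like) ellipse
#' with its own major/minor axes and orientation, plus a per-nucleus
#' brightness jitter. A pixel belongs to a nucleus iff its centre lies
#' inside the ellipse. Deterministic given the seed. This is a test
#' fixture, not a photorealistic stain simulation (no stromal texture
#' or artefacts).
#'
#' @param snapshot a [TissueSnapshot-class].
#' @param resolution output resolution in micrometres per pixel.
#' @param seed RNG seed for the noise and jitter.
#' @param noiseSd background Gaussian noise sd (8-bit units).
#' @param overlapWarn warn if more than this fraction of nuclei
#'   overlap another nucleus (segmentation recovery not guaranteed).
#' @return numeric array `H x W x 3` in `[0, 255]`.
#' @export
renderHE <- function(snapshot, resolution = 0.5, seed = 1L, noiseSd = 6,
                     overlapWarn = 0.2) {
    stopifnot(is(snapshot, "TissueSnapshot"))
    W <- as.integer(round(snapshot@width / resolution))
    H <- as.integer(round(snapshot@height / resolution))
    df <- snapshot@nuclei
    bg <- c(231, 183, 200)
    nucCol <- c(74, 46, 112)
    .withSeed(seed, {
        img <- array(0, dim = c(H, W, 3L))
        for (ch in 1:3)
            img[, , ch] <- bg[ch] + matrix(rnorm(H * W, 0, noiseSd), H, W)
        if (nrow(df)) {
            if (nrow(df) > 1L) {
                D <- as.matrix(stats::dist(df[, c("x", "y")]))
                diag(D) <- Inf
                touch <- apply(D, 1L, min) < (df$major / 2 +
                                              mean(df$major) / 2)
                if (mean(touch) > overlapWarn)
                    warning(sprintf("%.0f%% of nuclei may overlap; segmentation recovery not guaranteed",
                                    100 * mean(touch)))
            }
            jitter <- rnorm(nrow(df), 0, 10)
            for (i in seq_len(nrow(df))) {
                a <- df$major[i] / 2; b <- df$minor[i] / 2
                th <- df$theta[i] * pi / 180
                ct <- cos(th); st <- sin(th)
                rr <- max(a, b)
                c0 <- max(1L, floor((df$x[i] - rr) / resolution))
                c1 <- min(W, ceiling((df$x[i] + rr) / resolution))
                r0 <- max(1L, floor((df$y[i] - rr) / resolution))
                r1 <- min(H, ceiling((df$y[i] + rr) / resolution))
                if (c1 < c0 || r1 < r0) next
                cc <- c0:c1; rrs <- r0:r1
                xp <- (cc - 0.5) * resolution - df$x[i]
                yp <- (rrs - 0.5) * resolution - df$y[i]
                XX <- matrix(xp, length(rrs), length(cc), byrow = TRUE)
                YY <- matrix(yp, length(rrs), length(cc))
                u <- (XX * ct + YY * st) / a
                v <- (-XX * st + YY * ct) / b
                inside <- u * u + v * v <= 1
                if (!any(inside)) next
                for (ch in 1:3) {
                    sl <- img[rrs, cc, ch]
                    sl[inside] <- nucCol[ch] + jitter[i]
                    img[rrs, cc, ch] <- sl
                }
            }
        }
        pmin(pmax(img, 0), 255)
    })
}

#' Generate a balanced labeled cohort
#'
#' `nPerClass` specimens of each class with per-specimen seeds derived
#' deterministically from the master seed.
#'
#' @param nPerClass specimens per class (>= 1).
#' @param config a [generatorConfig()].
#' @param seed master seed.
#' @return list of [TissueSnapshot-class] (class 0 then class 1).
#' @export
generateCohort <- function(nPerClass, config = generatorConfig(),
                           seed = 1L) {
    stopifnot(nPerClass >= 1)
    seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L,
                                        2L * nPerClass))
    out <- vector("list", 2L * nPerClass)
    for (i in seq_len(nPerClass)) {
        out[[i]] <- generateSnapshot(config, 0L, seeds[i],
            specimenId = sprintf("syn_c0_%03d", i))
        out[[nPerClass + i]] <- generateSnapshot(config, 1L,
            seeds[nPerClass + i],
            specimenId = sprintf("syn_c1_%03d", i))
    }
    out
}

#' Random specimen-level train/test split
#'
#' Splits specimens at random (no stratification beyond the random
#' draw), with `ceiling(n * trainFraction)` in the training set --
#' e.g. 113 specimens at the default fraction split 57/56. Set
#' `stratify = TRUE` to balance the labels across the two sets.
#'
#' @param cohort list of [TissueSnapshot-class] (or anything with a
#'   length).
#' @param trainFraction fraction in the training set.
#' @param seed RNG seed.
#' @param stratify balance class labels across the split.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitCohort <- function(cohort, trainFraction = 0.5, seed = 1L,
                        stratify = FALSE) {
    n <- length(cohort)
    .withSeed(seed, {
        if (stratify) {
            labs <- vapply(cohort, function(s) as.integer(s@label),
                           integer(1))
            train <- integer(0)
            for (cls in unique(labs)) {
                idx <- which(labs == cls)
                k <- ceiling(length(idx) * trainFraction)
                train <- c(train, idx[sample.int(length(idx), k)])
            }
            train <- sort(train)
        } else {
            k <- ceiling(n * trainFraction)
            train <- sort(sample.int(n, k))
        }
        list(train = train, test = setdiff(seq_len(n), train))
    })
}
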