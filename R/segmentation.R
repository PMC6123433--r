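## Classical nuclear segmentation: rescale -> brightness -> global Otsu
## AND local adaptive threshold -> distance-transform watershed ->
## per-label morphometry.

.asImageMatrix <- function(x) {
    if (is.array(x) && length(dim(x)) == 3L) x else x
}

#' Rescale an RGB image to the 0.5 um/px working resolution
#'
#' Bicubic (Keys, a = -0.5) interpolation to a grid of
#' `round(native_size * native_res / 0.5)` pixels per side. Images
#' already at 0.5 um/px are returned unchanged.
#'
#' @param rgb numeric array `H x W x 3`, values in `[0, 255]`.
#' @param nativeRes source resolution in micrometres per pixel (> 0).
#' @param targetRes target resolution (default 0.5).
#' @return numeric array at the target resolution.
#' @export
rescaleToWorkingResolution <- function(rgb, nativeRes, targetRes = 0.5) {
    if (!is.numeric(nativeRes) || length(nativeRes) != 1L ||
        !is.finite(nativeRes) || nativeRes <= 0)
        stop("nativeRes must be a single positive number", call. = FALSE)
    d <- dim(rgb)
    if (length(d) != 3L || d[3L] != 3L)
        stop("rgb must be an H x W x 3 array", call. = FALSE)
    if (nativeRes == targetRes) return(rgb)
    outH <- as.integer(round(d[1L] * nativeRes / targetRes))
    outW <- as.integer(round(d[2L] * nativeRes / targetRes))
    out <- array(0, dim = c(outH, outW, 3L))
    for (ch in 1:3)
        out[, , ch] <- bicubic_resize(rgb[, , ch], outH, outW)
    pmin(pmax(out, 0), 255)
}

#' Brightness channel of an RGB image
#'
#' The HSB "brightness" definition: per-pixel maximum of the R, G and B
#' channels. Nuclei (hematoxylin) are dark in this channel.
#'
#' @param rgb numeric array `H x W x 3` in `[0, 255]`.
#' @return numeric matrix `H x W`.
#' @export
rgbToBrightness <- function(rgb) {
    d <- dim(rgb)
    if (length(d) != 3L || d[3L] != 3L)
        stop("rgb must be an H x W x 3 array", call. = FALSE)
    matrix(pmax(rgb[, , 1L], rgb[, , 2L], rgb[, , 3L]), d[1L], d[2L])
}

#' Global Otsu foreground mask
#'
#' Computes the Otsu threshold on the full-image 256-bin histogram and
#' returns the pixels *darker* than it (nuclei are dark in the
#' brightness channel). Set `darkForeground = FALSE` to select the
#' bright side instead.
#'
#' @param gray numeric matrix in `[0, 255]` with at least two distinct
#'   values.
#' @param darkForeground logical; select pixels below the threshold.
#' @return logical matrix.
#' @export
globalOtsuMask <- function(gray, darkForeground = TRUE) {
    if (!is.matrix(gray)) stop("gray must be a matrix", call. = FALSE)
    v <- range(gray)
    if (v[1L] == v[2L]) stop("degenerate histogram", call. = FALSE)
    thr <- EBImage::otsu(EBImage::Image(t(gray) / 255),
                         range = c(0, 1), levels = 256) * 255
    if (darkForeground) gray < thr else gray > thr
}

#' Local adaptive (mean) foreground mask
#'
#' A pixel is foreground iff its value is below the local mean over a
#' disc of the given radius minus an offset `C` (mean-minus-offset
#' local thresholding; set `darkForeground = FALSE` for the opposite
#' polarity). The default radius of 20 px corresponds to 10 um at the
#' 0.5 um/px working resolution. Borders use replicated edges.
#'
#' @param gray numeric matrix in `[0, 255]`.
#' @param radius disc radius in pixels (>= 1).
#' @param C offset subtracted from the local mean (default 0).
#' @param darkForeground logical.
#' @return logical matrix.
#' @export
localAdaptiveMask <- function(gray, radius = 20L, C = 0,
                              darkForeground = TRUE) {
    if (!is.matrix(gray)) stop("gray must be a matrix", call. = FALSE)
    if (radius < 1) stop("radius must be >= 1", call. = FALSE)
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    brush <- brush / sum(brush)
    loc <- EBImage::filter2(EBImage::Image(t(gray)), brush,
                            boundary = "replicate")
    localMean <- t(EBImage::imageData(loc))
    if (darkForeground) gray < localMean - C else gray > localMean + C
}

#' Split a binary mask into labeled nuclei by watershed
#'
#' Distance-transform watershed: the Euclidean distance map of the
#' foreground is lightly smoothed (Gaussian, `sigma = 1` px) so that
#' rasterisation bumps do not seed spurious maxima, maxima closer than
#' `h` in height are merged (h-maxima suppression) and the watershed
#' assigns every foreground pixel a label.
#'
#' @param mask logical or 0/1 matrix.
#' @param h h-maxima suppression height in pixels (default 1).
#' @param resolution micrometres per pixel carried into the result.
#' @return a [LabeledMask-class]; an empty mask yields zero labels.
#' @export
watershedSplit <- function(mask, h = 1, resolution = 0.5) {
    if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
    m <- (mask > 0) * 1
    if (!any(m > 0))
        return(new("LabeledMask",
                   mask = matrix(0L, nrow(mask), ncol(mask)),
                   resolution = resolution))
    img <- EBImage::Image(t(m))
    dm <- EBImage::distmap(img)
    dms <- EBImage::gblur(dm, sigma = 1)
    dms <- dms * img                     # keep background at zero height
    lab <- EBImage::watershed(dms, tolerance = h, ext = 1)
    labm <- t(EBImage::imageData(lab))
    storage.mode(labm) <- "integer"
    new("LabeledMask", mask = labm, resolution = resolution)
}

## Vossepoel-Smeulders chain-code perimeter from an ordered 8-connected
## boundary: 0.980 per axial step, 1.406 per diagonal step, -0.091 per
## direction change (corner).
.chainPerimeter <- function(contour) {
    n <- nrow(contour)
    if (n < 2L) return(3.14)             # single-pixel object: ~circle d=1
    nxt <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
    step <- nxt - contour
    diagonal <- step[, 1L] != 0 & step[, 2L] != 0
    code <- atan2(step[, 2L], step[, 1L])
    corners <- sum(code != c(code[-1L], code[1L]))
    0.980 * sum(!diagonal) + 1.406 * sum(diagonal) - 0.091 * corners
}

#' Measure per-nucleus morphometry from a labeled mask
#'
#' For every label: centroid (micrometres, pixel-centre convention);
#' major/minor axis lengths and orientation of the ellipse with equal
#' second moments (orientation in degrees in `(0, 180]`, from +x
#' towards +y); area as pixel count times `resolution^2`; perimeter by
#' a Vossepoel-Smeulders weighted chain-code estimator (a naive
#' boundary-pixel count would push the circularity of a disc above 1);
#' circularity `4*pi*area/perimeter^2` clamped to at most 1. Components
#' touching the image border and components smaller than `minArea` are
#' discarded.
#'
#' @param labeled a [LabeledMask-class] or an integer label matrix.
#' @param resolution micrometres per pixel (used when `labeled` is a
#'   bare matrix).
#' @param minArea minimum object area in square micrometres (default 8).
#' @param dropBorder discard border-touching components (default TRUE).
#' @return data.frame in [TissueSnapshot-class] nucleus-table format.
#' @export
measureNuclei <- function(labeled, resolution = 0.5, minArea = 8,
                          dropBorder = TRUE) {
    if (is(labeled, "LabeledMask")) {
        resolution <- labeled@resolution
        lab <- labeled@mask
    } else lab <- labeled
    K <- max(lab)
    if (K == 0L) return(.emptyNuclei())
    idx <- which(lab > 0L)
    if (!length(idx)) return(.emptyNuclei())
    lb <- lab[idx]
    H <- nrow(lab); W <- ncol(lab)
    r <- ((idx - 1L) %% H) + 1L
    c <- ((idx - 1L) %/% H) + 1L
    npix <- tabulate(lb, nbins = K)
    sx <- rowsum(as.numeric(c), lb)[, 1L]
    sy <- rowsum(as.numeric(r), lb)[, 1L]
    sxx <- rowsum(as.numeric(c)^2, lb)[, 1L]
    syy <- rowsum(as.numeric(r)^2, lb)[, 1L]
    sxy <- rowsum(as.numeric(c) * r, lb)[, 1L]
    present <- which(npix > 0L)
    n <- npix[present]
    cx <- sx[as.character(present)] / n
    cy <- sy[as.character(present)] / n
    ## central second moments (+1/12 pixel-square correction)
    mxx <- sxx[as.character(present)] / n - cx^2 + 1 / 12
    myy <- syy[as.character(present)] / n - cy^2 + 1 / 12
    mxy <- sxy[as.character(present)] / n - cx * cy
    common <- (mxx + myy) / 2
    diff <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
    l1 <- common + diff                  # variance along major axis
    l2 <- pmax(common - diff, 1e-9)
    major <- 4 * sqrt(l1)                # full axis of equal-moments ellipse
    minor <- 4 * sqrt(l2)
    theta <- (atan2(2 * mxy, mxx - myy) / 2) * 180 / pi
    theta <- theta %% 180
    theta[theta == 0] <- 180
    touchesBorder <- rowsum(as.numeric(r == 1L | r == H | c == 1L | c == W),
                            lb)[, 1L]
    touches <- touchesBorder[as.character(present)] > 0
    areaUm <- n * resolution^2
    keep <- areaUm >= minArea
    if (dropBorder) keep <- keep & !touches
    if (!any(keep)) return(.emptyNuclei())
    keepLabels <- present[keep]          # ascending
    ## perimeter via ordered boundary chains (EBImage::ocontour);
    ## relabel kept objects 1..K' in ascending order so contour i
    ## corresponds to keepLabels[i]
    relab <- integer(K)
    relab[keepLabels] <- seq_along(keepLabels)
    sub <- matrix(0L, H, W)
    sub[idx] <- relab[lb]
    oc <- EBImage::ocontour(EBImage::Image(t(sub)))
    perimPx <- vapply(seq_along(keepLabels), function(i)
        if (i <= length(oc)) .chainPerimeter(oc[[i]])
        else 2 * pi * sqrt(n[keep][i] / pi), numeric(1))
    area <- areaUm[keep]
    perimeter <- perimPx * resolution
    circ <- pmin(4 * pi * area / perimeter^2, 1)
    data.frame(x = (cx[keep] - 0.5) * resolution,
               y = (cy[keep] - 0.5) * resolution,
               major = major[keep] * resolution,
               minor = minor[keep] * resolution,
               ratio = major[keep] / minor[keep],
               area = area,
               perimeter = perimeter,
               circularity = circ,
               theta = theta[keep])
}

#' Segment nuclei from an RGB H&E image
#'
#' Composes the full classical recipe: rescale to 0.5 um/px (bicubic),
#' keep the HSB brightness channel, global Otsu mask AND local adaptive
#' mask (radius 20 px = 10 um), distance-transform watershed, and
#' per-label morphometry.
#'
#' @param rgb numeric array `H x W x 3` in `[0, 255]`.
#' @param nativeRes source resolution in micrometres per pixel.
#' @param specimenId identifier stored in the result.
#' @param label optional binary label stored in the result.
#' @param localRadius local-threshold radius in pixels.
#' @param localC local-threshold offset.
#' @param h watershed h-maxima height.
#' @param minArea minimum nucleus area in square micrometres.
#' @param despeckle apply a 3x3 morphological opening to the combined
#'   mask before the watershed. Removes isolated threshold speckle
#'   (without it, sensor noise on object-free regions percolates into
#'   spurious "nuclei"); nuclei at the minimum area are unaffected.
#' @param verbose log the nucleus count.
#' @return a [TissueSnapshot-class] at 0.5 um/px.
#' @export
segmentImage <- function(rgb, nativeRes, specimenId = "image", label = NA,
                         localRadius = 20L, localC = 0, h = 1, minArea = 8,
                         despeckle = TRUE, verbose = TRUE) {
    rgb <- rescaleToWorkingResolution(rgb, nativeRes)
    gray <- rgbToBrightness(rgb)
    mask <- globalOtsuMask(gray) & localAdaptiveMask(gray, radius = localRadius,
                                                     C = localC)
    if (despeckle) {
        kern <- EBImage::makeBrush(3L, shape = "box")
        mimg <- EBImage::opening(EBImage::Image(t(mask * 1)), kern)
        mask <- t(EBImage::imageData(mimg)) > 0
    }
    lab <- watershedSplit(mask, h = h, resolution = 0.5)
    df <- measureNuclei(lab, minArea = minArea)
    if (verbose)
        message(sprintf("segmentImage: %d nuclei detected in '%s'",
                        nrow(df), specimenId))
    ## numerical safety: clamp measured centroids into the extent
    W <- ncol(gray) * 0.5; H <- nrow(gray) * 0.5
    df$x <- pmin(pmax(df$x, 0), W)
    df$y <- pmin(pmax(df$y, 0), H)
    TissueSnapshot(specimenId, df, width = W, height = H,
                   resolution = 0.5, label = label)
}

#' Concordance between a predicted and a ground-truth snapshot
#'
#' Greedy one-to-one matching of predicted to true nuclei by nearest
#' centroid within `tolUm`; returns the fraction of true nuclei that
#' were matched. A segmentation "passes QC" iff the fraction exceeds
#' 0.70 (strict), the same cut used for visual segmentation scoring.
#'
#' @param predicted,truth [TissueSnapshot-class] objects over the same
#'   extent.
#' @param tolUm matching tolerance in micrometres.
#' @return numeric fraction in `[0, 1]` with attribute `passesQC`.
#' @export
concordanceQC <- function(predicted, truth, tolUm = 2) {
    if (abs(predicted@width - truth@width) > 1e-6 ||
        abs(predicted@height - truth@height) > 1e-6)
        stop("snapshots have mismatched extents", call. = FALSE)
    nt <- nNuclei(truth)
    if (nt == 0L) {
        out <- 1
        attr(out, "passesQC") <- TRUE
        return(out)
    }
    np <- nNuclei(predicted)
    if (np == 0L) {
        out <- 0
        attr(out, "passesQC") <- FALSE
        return(out)
    }
    P <- as.matrix(nuclei(predicted)[, c("x", "y")])
    G <- as.matrix(nuclei(truth)[, c("x", "y")])
    D <- outer(P[, 1L], G[, 1L], "-")^2 + outer(P[, 2L], G[, 2L], "-")^2
    cand <- which(D <= tolUm^2, arr.ind = TRUE)
    matched <- 0L
    if (nrow(cand)) {
        ord <- cand[order(D[cand]), , drop = FALSE]
        usedP <- logical(np); usedT <- logical(nt)
        for (i in seq_len(nrow(ord))) {
            p <- ord[i, 1L]; t <- ord[i, 2L]
            if (!usedP[p] && !usedT[t]) {
                usedP[p] <- TRUE; usedT[t] <- TRUE
                matched <- matched + 1L
            }
        }
    }
    out <- matched / nt
    attr(out, "passesQC") <- out > 0.70
    out
}
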