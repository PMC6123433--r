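## Sparse 12-channel encoding of nuclei point fields, dihedral (D4)
## transforms with orientation-bin permutation, and patch extraction.

#' The eight dihedral (D4) operations
#'
#' Names accepted by [transformFeatureImage()]: `identity`, `rot90`,
#' `rot180`, `rot270` (rotations in the image plane, `rot90` maps the
#' orientation `theta` to `theta + 90` mod 180), `flip_h` (mirror
#' left-right), `flip_v` (mirror top-bottom), `transpose` and
#' `anti_transpose` (the two diagonal reflections).
#' @export
d4Ops <- c("identity", "rot90", "rot180", "rot270",
           "flip_h", "flip_v", "transpose", "anti_transpose")

## apply a D4 element to a matrix (rows = y, cols = x)
.d4Matrix <- function(M, op) {
    H <- nrow(M); W <- ncol(M)
    switch(op,
        identity = M,
        rot90 = t(M)[, H:1, drop = FALSE],
        rot180 = M[H:1, W:1, drop = FALSE],
        rot270 = t(M[, W:1, drop = FALSE]),
        flip_h = M[, W:1, drop = FALSE],
        flip_v = M[H:1, , drop = FALSE],
        transpose = t(M),
        anti_transpose = t(M)[W:1, H:1, drop = FALSE],
        stop("unknown D4 op: ", op, call. = FALSE))
}

## map an angle in (0,180] through a D4 element (degrees)
.d4Angle <- function(theta, op) {
    out <- switch(op,
        identity = theta, rot180 = theta,
        rot90 = theta + 90, rot270 = theta + 90,
        flip_h = 180 - theta, flip_v = 180 - theta,
        transpose = 90 - theta, anti_transpose = 90 - theta,
        stop("unknown D4 op: ", op, call. = FALSE))
    out <- out %% 180
    ifelse(out == 0, 180, out)
}

## map points (x, y) in a width x height extent through a D4 element;
## returns list(x, y, width, height)
.d4Point <- function(x, y, width, height, op) {
    switch(op,
        identity = list(x = x, y = y, width = width, height = height),
        rot90 = list(x = height - y, y = x, width = height, height = width),
        rot180 = list(x = width - x, y = height - y,
                      width = width, height = height),
        rot270 = list(x = y, y = width - x, width = height, height = width),
        flip_h = list(x = width - x, y = y, width = width, height = height),
        flip_v = list(x = x, y = height - y, width = width, height = height),
        transpose = list(x = y, y = x, width = height, height = width),
        anti_transpose = list(x = height - y, y = width - x,
                              width = height, height = width),
        stop("unknown D4 op: ", op, call. = FALSE))
}

## permutation of the six 30-degree bins under a D4 element:
## perm[k] = destination bin of source bin k, derived by pushing each
## bin's representative angle (30k - 15) through the angle map
.d4BinPermutation <- function(op) {
    rep <- 30 * (1:6) - 15
    ceiling(.d4Angle(rep, op) / 30)
}

#' One-hot binary angle features
#'
#' Encodes a major-axis orientation into six 30-degree bins: component
#' `j` is 1 iff `30*(j-1) < theta <= 30*j`. An input of exactly 0
#' degrees is first remapped to 180 (0 and 180 are the same undirected
#' axis).
#'
#' @param theta numeric vector of angles in degrees, in `(0, 180]`
#'   (0 allowed, remapped to 180).
#' @return for a single angle, an integer 6-vector with exactly one 1;
#'   for `n` angles an `n x 6` matrix.
#' @examples
#' binaryAngleFeatures(45)   # bin 2
#' binaryAngleFeatures(30)   # bin 1: upper edge is closed
#' binaryAngleFeatures(180)  # bin 6
#' @export
binaryAngleFeatures <- function(theta) {
    theta <- ifelse(theta == 0, 180, theta)
    if (any(!is.finite(theta) | theta <= 0 | theta > 180))
        stop("theta must be in (0, 180] after the 0 -> 180 remap",
             call. = FALSE)
    bin <- ceiling(theta / 30)
    out <- matrix(0L, length(theta), 6L)
    out[cbind(seq_along(theta), bin)] <- 1L
    if (length(theta) == 1L) out[1L, ] else out
}

#' Encode a snapshot as a sparse 12-channel feature image
#'
#' Builds the `H x W x 12` feature image at 2 micrometres per pixel
#' (a 4x reduction of the 0.5 um/px source grid). Each nucleus is
#' placed directly at the floor-mapped pixel
#' `(floor(x_px/4), floor(y_px/4))` of its centroid -- the operative
#' downscaling definition; resampling a sparse image would discard
#' most nuclei. Channels 1-6 carry `major, minor, ratio, area,
#' perimeter, circularity` in snapshot units; channels 7-12 the one-hot
#' orientation bins from [binaryAngleFeatures()]. When two nuclei map
#' to the same pixel the larger-area nucleus is kept (ties: first in
#' table order) and the collision is counted.
#'
#' @param snapshot a [TissueSnapshot-class] (source convention
#'   0.5 um/px).
#' @return a [SparseFeatureImage-class] with grid
#'   `ceil(source_px / 4)` per side.
#' @export
encodeSnapshot <- function(snapshot) {
    stopifnot(is(snapshot, "TissueSnapshot"))
    srcRes <- snapshot@resolution
    outRes <- 4 * srcRes               # 2 um/px for the 0.5 um/px convention
    W <- as.integer(ceiling(snapshot@width / srcRes / 4))
    H <- as.integer(ceiling(snapshot@height / srcRes / 4))
    df <- snapshot@nuclei
    arr <- array(0, dim = c(H, W, 12L))
    collisions <- 0L
    if (nrow(df)) {
        col0 <- floor(df$x / outRes)   # floor(x_px / 4), 0-based
        row0 <- floor(df$y / outRes)
        col0 <- pmin(col0, W - 1L)     # boundary x == width lands inside
        row0 <- pmin(row0, H - 1L)
        if (any(col0 < 0 | row0 < 0))
            stop("nucleus outside image extent", call. = FALSE)
        key <- row0 * W + col0
        ## larger-area nucleus wins a collision; ties keep first row
        ord <- order(key, -df$area, seq_len(nrow(df)))
        keep <- ord[!duplicated(key[ord])]
        collisions <- nrow(df) - length(keep)
        r <- row0[keep] + 1L; c <- col0[keep] + 1L
        shape <- cbind(df$major, df$minor, df$ratio, df$area,
                       df$perimeter, df$circularity)[keep, , drop = FALSE]
        ang <- binaryAngleFeatures(df$theta[keep])
        if (is.null(dim(ang))) ang <- matrix(ang, 1L)
        for (ch in 1:6) {
            arr[cbind(r, c, ch)] <- shape[, ch]
            arr[cbind(r, c, ch + 6L)] <- ang[, ch]
        }
    }
    new("SparseFeatureImage", data = arr, specimenId = snapshot@specimenId,
        label = snapshot@label, resolution = outRes, collisions = collisions)
}

#' Apply a dihedral transform to a feature image or patch
#'
#' Transforms the spatial grid by one of the eight D4 elements and
#' permutes the six orientation-bin channels so the encoded angles stay
#' consistent with the new geometry: a 90-degree rotation cyclically
#' shifts the bins by 3, a flip reverses them (`k -> 7 - k`), rot180
#' leaves them untouched and the diagonal reflections swap bins 1/3 and
#' 4/6. Shape channels are moved spatially but their values are
#' unchanged. This is what makes flip/rotate augmentation valid for
#' orientation-carrying inputs.
#'
#' @param img a [SparseFeatureImage-class] or [FeaturePatch-class].
#' @param op one of [d4Ops].
#' @return an object of the same class as `img`.
#' @export
transformFeatureImage <- function(img, op) {
    if (!op %in% d4Ops) stop("unknown D4 op: ", op, call. = FALSE)
    arr <- if (is(img, "SparseFeatureImage") || is(img, "FeaturePatch"))
        img@data else stop("img must be a SparseFeatureImage or FeaturePatch",
                           call. = FALSE)
    out <- .transformFeatureArray(arr, op)
    res <- img
    res@data <- out
    res
}

.transformFeatureArray <- function(arr, op) {
    M1 <- .d4Matrix(arr[, , 1L], op)
    out <- array(0, dim = c(nrow(M1), ncol(M1), 12L))
    out[, , 1L] <- M1
    for (ch in 2:6) out[, , ch] <- .d4Matrix(arr[, , ch], op)
    perm <- .d4BinPermutation(op)
    for (k in 1:6) out[, , 6L + perm[k]] <- .d4Matrix(arr[, , 6L + k], op)
    out
}

#' Extract one patch from a feature image
#'
#' @param img a [SparseFeatureImage-class].
#' @param x0,y0 1-based column/row of the window's top-left pixel.
#' @param size window side length in pixels (100 px spans 200 um at
#'   the 2 um/px grid).
#' @return a [FeaturePatch-class] inheriting the source image's label.
#' @export
extractPatch <- function(img, x0, y0, size) {
    stopifnot(is(img, "SparseFeatureImage"))
    d <- dim(img@data)
    x0 <- as.integer(x0); y0 <- as.integer(y0); size <- as.integer(size)
    if (x0 < 1L || y0 < 1L || x0 + size - 1L > d[2L] || y0 + size - 1L > d[1L])
        stop("patch window out of bounds", call. = FALSE)
    new("FeaturePatch",
        data = img@data[y0:(y0 + size - 1L), x0:(x0 + size - 1L), ,
                        drop = FALSE],
        specimenId = img@specimenId, label = img@label,
        x0 = x0, y0 = y0, resolution = img@resolution)
}

#' Physical extent of a patch
#'
#' @param patch a [FeaturePatch-class].
#' @return side length in micrometres.
#' @export
patchExtentUm <- function(patch) {
    dim(patch@data)[1L] * patch@resolution
}

#' Tile a feature image into non-overlapping patches
#'
#' Lays a regular grid of `size x size` windows (stride `stride`,
#' default non-overlapping) over the image, dropping partial tiles at
#' the right/bottom edges.
#'
#' @param img a [SparseFeatureImage-class].
#' @param size patch side in pixels (default 64 px = 128 um).
#' @param stride grid stride in pixels.
#' @return list of [FeaturePatch-class]; empty (with a warning) if the
#'   image is smaller than `size`.
#' @export
tilePatches <- function(img, size = 64L, stride = size) {
    stopifnot(is(img, "SparseFeatureImage"))
    d <- dim(img@data)
    size <- as.integer(size); stride <- as.integer(stride)
    if (size > d[1L] || size > d[2L]) {
        warning("image smaller than patch size; no complete tile")
        return(list())
    }
    xs <- seq.int(1L, d[2L] - size + 1L, by = stride)
    ys <- seq.int(1L, d[1L] - size + 1L, by = stride)
    out <- vector("list", length(xs) * length(ys))
    i <- 0L
    for (y0 in ys) for (x0 in xs) {
        i <- i + 1L
        out[[i]] <- extractPatch(img, x0, y0, size)
    }
    out
}
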