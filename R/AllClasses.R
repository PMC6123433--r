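#' @import methods
#' @importFrom stats rnorm runif rpois rbinom quantile sd var median cor
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib nucleomorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## canonical per-nucleus columns, all in micrometre-based units
.nucleusCols <- c("x", "y", "major", "minor", "ratio", "area",
                  "perimeter", "circularity", "theta")

.emptyNuclei <- function() {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(.nucleusCols)),
                                 .nucleusCols))
    df
}

#' TissueSnapshot: nuclei of one specimen image
#'
#' Container for the segmented nuclei of a single tissue image together
#' with specimen metadata. Coordinates and lengths are stored in
#' micrometres with the image convention: origin at the top-left corner,
#' x increasing rightwards, y increasing downwards. The major-axis
#' orientation `theta` is in degrees in `(0, 180]`, measured from the
#' positive x axis towards positive y.
#'
#' @slot specimenId single character identifier.
#' @slot label integer `1` (ER-negative), `0` (ER-positive) or `NA`
#'   (unknown).
#' @slot resolution micrometres per pixel of the source image.
#' @slot width,height physical extent of the image in micrometres.
#' @slot nuclei data.frame with one row per nucleus and columns
#'   `x, y, major, minor, ratio, area, perimeter, circularity, theta`.
#'
#' @seealso [TissueSnapshot()], [readSnapshotXML()], [segmentImage()]
#' @exportClass TissueSnapshot
setClass("TissueSnapshot",
    representation(specimenId = "character",
                   label = "integer",
                   resolution = "numeric",
                   width = "numeric",
                   height = "numeric",
                   nuclei = "data.frame"))

.validNuclei <- function(df, width, height) {
    missing <- setdiff(.nucleusCols, names(df))
    if (length(missing))
        return(sprintf("nuclei table lacks column(s): %s",
                       paste(missing, collapse = ", ")))
    if (!nrow(df)) return(TRUE)
    chk <- function(bad, what) {
        i <- which(bad)
        if (length(i))
            sprintf("nucleus %d: invalid %s", i[1L], what)
        else NULL
    }
    msgs <- c(
        chk(!is.finite(df$x) | df$x < 0 | df$x > width,
            sprintf("x (outside [0, %g])", width)),
        chk(!is.finite(df$y) | df$y < 0 | df$y > height,
            sprintf("y (outside [0, %g])", height)),
        chk(!is.finite(df$minor) | df$minor <= 0, "minor (must be > 0)"),
        chk(!is.finite(df$major) | df$major < df$minor,
            "major (must be >= minor)"),
        chk(abs(df$ratio - df$major / df$minor) > 1e-9,
            "ratio (must equal major/minor)"),
        chk(!is.finite(df$area) | df$area <= 0, "area (must be > 0)"),
        chk(!is.finite(df$perimeter) | df$perimeter <= 0,
            "perimeter (must be > 0)"),
        chk(!is.finite(df$circularity) | df$circularity <= 0 |
            df$circularity > 1, "circularity (must be in (0, 1])"),
        chk(!is.finite(df$theta) | df$theta <= 0 | df$theta > 180,
            "theta (must be in (0, 180])"))
    if (length(msgs)) msgs[[1L]] else TRUE
}

setValidity("TissueSnapshot", function(object) {
    if (length(object@specimenId) != 1L)
        return("specimenId must be a single string")
    if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
        object@resolution <= 0)
        return("resolution must be a single positive number")
    if (length(object@label) != 1L ||
        (!is.na(object@label) && !object@label %in% c(0L, 1L)))
        return("label must be 0, 1 or NA")
    if (object@width <= 0 || object@height <= 0)
        return("width and height must be positive")
    .validNuclei(object@nuclei, object@width, object@height)
})

#' LabeledMask: integer label image of segmented nuclei
#'
#' Pixel grid in which `0` is background and each positive integer `k`
#' marks the pixels of nucleus `k`. Labels are contiguous `1..K`.
#'
#' @slot mask integer matrix (rows = y, columns = x).
#' @slot resolution micrometres per pixel.
#' @exportClass LabeledMask
setClass("LabeledMask",
    representation(mask = "matrix", resolution = "numeric"))

setValidity("LabeledMask", function(object) {
    m <- object@mask
    if (any(m < 0)) return("labels must be non-negative")
    k <- max(m)
    if (k > 0) {
        present <- tabulate(m[m > 0], nbins = k)
        if (any(present == 0))
            return("labels must be contiguous positive integers")
    }
    if (object@resolution <= 0) return("resolution must be positive")
    TRUE
})

#' SparseFeatureImage: sparse 12-channel nuclear-feature image
#'
#' H x W x 12 array at 2 micrometres per pixel, zero everywhere except
#' at nucleus-centre pixels. Channels 1-6 hold the shape features
#' (major, minor, ratio, area, perimeter, circularity) in snapshot
#' units; channels 7-12 are the one-hot 30-degree orientation bins.
#'
#' @slot data numeric array `H x W x 12` (rows = y, columns = x).
#' @slot specimenId source specimen identifier.
#' @slot label inherited binary label (or `NA`).
#' @slot resolution micrometres per pixel of the feature grid (2).
#' @slot collisions number of nuclei dropped because another nucleus
#'   mapped to the same pixel.
#' @exportClass SparseFeatureImage
setClass("SparseFeatureImage",
    representation(data = "array", specimenId = "character",
                   label = "integer", resolution = "numeric",
                   collisions = "integer"))

setValidity("SparseFeatureImage", function(object) {
    d <- dim(object@data)
    if (length(d) != 3L || d[3L] != 12L)
        return("data must be an H x W x 12 array")
    ang <- object@data[, , 7:12, drop = FALSE]
    if (any(ang != 0 & ang != 1))
        return("angle channels must be binary")
    nAct <- rowSums(ang, dims = 2L)
    occupied <- nAct > 0
    if (any(nAct[occupied] != 1L))
        return("every occupied pixel must have exactly one active angle bin")
    shp <- object@data[, , 1:6, drop = FALSE]
    for (ch in 1:6) {
        v <- shp[, , ch][occupied]
        if (any(v <= 0))
            return(sprintf("occupied pixels must have positive shape channel %d", ch))
        if (any(shp[, , ch][!occupied] != 0))
            return("background pixels must be all-zero")
    }
    TRUE
})

#' FeaturePatch: one window of a SparseFeatureImage
#'
#' @slot data numeric array `P x P x 12`.
#' @slot specimenId source specimen id.
#' @slot label label inherited from the source image.
#' @slot x0,y0 1-based column/row of the window's top-left pixel in the
#'   source grid.
#' @slot resolution micrometres per pixel (2).
#' @exportClass FeaturePatch
setClass("FeaturePatch",
    representation(data = "array", specimenId = "character",
                   label = "integer", x0 = "integer", y0 = "integer",
                   resolution = "numeric"))

setValidity("FeaturePatch", function(object) {
    d <- dim(object@data)
    if (length(d) != 3L || d[3L] != 12L || d[1L] != d[2L])
        return("data must be a P x P x 12 array")
    TRUE
})

#' ERHeatmap: spatial class-evidence map plus specimen score
#'
#' Output of [predictHeatmap()]: one logit per output location of the
#' fully convolutional network (input size reduced by the five pooling
#' stages), the per-location probabilities after batch-normalisation
#' (running statistics) and sigmoid, and the aggregated specimen score
#' `sigmoid(BN(mean logit))` in `[0, 1]`. Higher values mean more
#' ER-negative evidence.
#'
#' @slot logits numeric matrix of per-location logits.
#' @slot prob numeric matrix of per-location probabilities.
#' @slot score single number in `[0, 1]`.
#' @slot specimenId source specimen id.
#' @exportClass ERHeatmap
setClass("ERHeatmap",
    representation(logits = "matrix", prob = "matrix",
                   score = "numeric", specimenId = "character"))

setValidity("ERHeatmap", function(object) {
    if (length(object@score) != 1L || object@score < 0 || object@score > 1)
        return("score must be a single value in [0, 1]")
    TRUE
})

#' NucleoNet: the fully convolutional classifier
#'
#' Weights and state of the six-convolution fully convolutional network
#' (five 3x3 feature convolutions with leaky-ReLU and 2x2 max pooling,
#' dropout, a 1x1 single-logit classifier convolution, a global mean
#' over the logit map and one batch-normalisation applied to the scalar
#' mean logit before the sigmoid).
#'
#' @slot config network configuration list, see [networkConfig()].
#' @slot weights named list `W1..W6`, `b1..b6` of numeric arrays.
#' @slot bn list with `gamma`, `beta`, `rmean`, `rvar` (running
#'   statistics of the mean logit).
#' @slot inputScale `NULL` or list with per-shape-channel `mean` and
#'   `sd` used to standardise channels 1-6 at the input layer.
#' @slot trained logical flag.
#' @slot seed integer seed the weights were initialised (and trained)
#'   with.
#' @slot history per-epoch training record.
#' @exportClass NucleoNet
setClass("NucleoNet",
    representation(config = "list", weights = "list", bn = "list",
                   inputScale = "ANY", trained = "logical",
                   seed = "integer", history = "data.frame"))

## ---- show methods ----

setMethod("show", "TissueSnapshot", function(object) {
    cat(sprintf("TissueSnapshot '%s': %d nuclei, %.0f x %.0f um @ %g um/px, label=%s\n",
        object@specimenId, nrow(object@nuclei), object@width, object@height,
        object@resolution,
        if (is.na(object@label)) "NA" else as.character(object@label)))
})

setMethod("show", "SparseFeatureImage", function(object) {
    d <- dim(object@data)
    occ <- sum(object@data[, , 7] != 0 | object@data[, , 8] != 0 |
               object@data[, , 9] != 0 | object@data[, , 10] != 0 |
               object@data[, , 11] != 0 | object@data[, , 12] != 0)
    cat(sprintf("SparseFeatureImage '%s': %d x %d x 12 @ %g um/px, %d occupied px, %d collision(s)\n",
        object@specimenId, d[1L], d[2L], object@resolution, occ,
        object@collisions))
})

setMethod("show", "ERHeatmap", function(object) {
    cat(sprintf("ERHeatmap '%s': %d x %d locations, score = %.4f\n",
        object@specimenId, nrow(object@logits), ncol(object@logits),
        object@score))
})

setMethod("show", "NucleoNet", function(object) {
    cat(sprintf("NucleoNet: widths [%s], %d parameters, %s\n",
        paste(object@config$widths, collapse = ","),
        parameterCount(object),
        if (object@trained) "trained" else "untrained"))
})

setMethod("show", "LabeledMask", function(object) {
    cat(sprintf("LabeledMask: %d x %d px @ %g um/px, %d object(s)\n",
        nrow(object@mask), ncol(object@mask), object@resolution,
        max(object@mask)))
})
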