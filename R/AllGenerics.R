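#' @importFrom stats setNames
NULL

#' Accessors for nucleomorph objects
#'
#' `specimenId()` returns the specimen identifier; `erLabel()` the
#' binary label (1 = ER-negative, 0 = ER-positive, `NA` = unknown);
#' `resolutionUm()` the grid resolution in micrometres per pixel;
#' `nuclei()` the per-nucleus morphometry table; `nNuclei()` its row
#' count; `featureArray()` the raw `H x W x 12` array of a
#' [SparseFeatureImage-class] or [FeaturePatch-class];
#' `heatmapScore()` the aggregated specimen score of an
#' [ERHeatmap-class].
#'
#' @param object a nucleomorph S4 object.
#' @return see description.
#' @name accessors
#' @aliases specimenId erLabel resolutionUm nuclei nNuclei featureArray
#'   heatmapScore
NULL

#' @rdname accessors
#' @export
setGeneric("specimenId", function(object) standardGeneric("specimenId"))
#' @rdname accessors
#' @export
setGeneric("erLabel", function(object) standardGeneric("erLabel"))
#' @rdname accessors
#' @export
setGeneric("resolutionUm", function(object) standardGeneric("resolutionUm"))
#' @rdname accessors
#' @export
setGeneric("nuclei", function(object) standardGeneric("nuclei"))
#' @rdname accessors
#' @export
setGeneric("nNuclei", function(object) standardGeneric("nNuclei"))
#' @rdname accessors
#' @export
setGeneric("featureArray", function(object) standardGeneric("featureArray"))
#' @rdname accessors
#' @export
setGeneric("heatmapScore", function(object) standardGeneric("heatmapScore"))

#' @rdname accessors
setMethod("specimenId", "TissueSnapshot", function(object) object@specimenId)
#' @rdname accessors
setMethod("specimenId", "SparseFeatureImage", function(object) object@specimenId)
#' @rdname accessors
setMethod("specimenId", "FeaturePatch", function(object) object@specimenId)
#' @rdname accessors
setMethod("specimenId", "ERHeatmap", function(object) object@specimenId)

#' @rdname accessors
setMethod("erLabel", "TissueSnapshot", function(object) object@label)
#' @rdname accessors
setMethod("erLabel", "SparseFeatureImage", function(object) object@label)
#' @rdname accessors
setMethod("erLabel", "FeaturePatch", function(object) object@label)

#' @rdname accessors
setMethod("resolutionUm", "TissueSnapshot", function(object) object@resolution)
#' @rdname accessors
setMethod("resolutionUm", "SparseFeatureImage", function(object) object@resolution)
#' @rdname accessors
setMethod("resolutionUm", "FeaturePatch", function(object) object@resolution)
#' @rdname accessors
setMethod("resolutionUm", "LabeledMask", function(object) object@resolution)

#' @rdname accessors
setMethod("nuclei", "TissueSnapshot", function(object) object@nuclei)
#' @rdname accessors
setMethod("nNuclei", "TissueSnapshot", function(object) nrow(object@nuclei))

#' @rdname accessors
setMethod("featureArray", "SparseFeatureImage", function(object) object@data)
#' @rdname accessors
setMethod("featureArray", "FeaturePatch", function(object) object@data)

#' @rdname accessors
setMethod("heatmapScore", "ERHeatmap", function(object) object@score)

#' Number of trainable parameters of a NucleoNet
#'
#' Counts every convolutional weight and bias plus the two affine
#' batch-normalisation parameters.
#'
#' @param object a [NucleoNet-class].
#' @return integer parameter count.
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))

#' @rdname parameterCount
setMethod("parameterCount", "NucleoNet", function(object) {
    sum(vapply(object@weights, length, integer(1))) + 2L
})
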