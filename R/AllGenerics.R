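#' @include AllClasses.R
NULL

#' Pixel matrix of an image-like object
#' @param x a [SliceImage-class], [BinaryMask-class] or [Skeleton-class].
#' @return the underlying matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
setMethod("pixels", "SliceImage", function(x) x@pixels)
#' @rdname pixels
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' Pixel size in micrometers
#' @param x an image-like or graph object.
#' @return pixel size in micrometers.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
setMethod("pixelSize", "SliceImage", function(x) x@pixelSizeUm)
#' @rdname pixelSize
setMethod("pixelSize", "BinaryMask", function(x) x@pixelSizeUm)
#' @rdname pixelSize
setMethod("pixelSize", "TrabecularGraph", function(x) x@pixelSizeUm)

#' Depth of a slice
#' @param x a [SliceImage-class].
#' @return 0-based depth index / depth in millimeters (index x pixel size,
#'   isotropic slice spacing).
#' @export
setGeneric("depthIndex", function(x) standardGeneric("depthIndex"))
#' @rdname depthIndex
setMethod("depthIndex", "SliceImage", function(x) x@depthIndex)

#' @rdname depthIndex
#' @export
setGeneric("depthMm", function(x) standardGeneric("depthMm"))
#' @rdname depthIndex
setMethod("depthMm", "SliceImage",
          function(x) x@depthIndex * x@pixelSizeUm / 1000)

#' Vertex and edge counts
#' @param x a [TrabecularGraph-class], [SimpleGraph-class] or
#'   [GroundTruth-class].
#' @return integer count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname nVertices
setMethod("nVertices", "TrabecularGraph", function(x) nrow(x@vertices))
#' @rdname nVertices
setMethod("nVertices", "SimpleGraph", function(x) x@nVertices)
#' @rdname nVertices
setMethod("nVertices", "GroundTruth", function(x) nrow(x@vertices))

#' @rdname nVertices
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname nVertices
setMethod("nEdges", "TrabecularGraph", function(x) nrow(x@edges))
#' @rdname nVertices
setMethod("nEdges", "SimpleGraph", function(x) nrow(x@edges))
#' @rdname nVertices
setMethod("nEdges", "GroundTruth", function(x) nrow(x@edges))

#' Vertex and edge tables of a graph
#' @param x a [TrabecularGraph-class].
#' @return a data.frame.
#' @export
setGeneric("vertexTable", function(x) standardGeneric("vertexTable"))
#' @rdname vertexTable
setMethod("vertexTable", "TrabecularGraph", function(x) x@vertices)

#' @rdname vertexTable
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname vertexTable
setMethod("edgeTable", "TrabecularGraph", function(x) x@edges)

#' Physical edge lengths of a network
#' @param x a [TrabecularGraph-class].
#' @return numeric vector of edge lengths in micrometers.
#' @export
setGeneric("edgeLengths", function(x) standardGeneric("edgeLengths"))
#' @rdname edgeLengths
setMethod("edgeLengths", "TrabecularGraph", function(x) x@edges$lengthUm)

setMethod("show", "SliceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SliceImage %dx%d px, %.3g um/px, depth index %d (%.3f mm)\n",
              d[1], d[2], object@pixelSizeUm, object@depthIndex,
              depthMm(object)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("%s %dx%d px, %.3g um/px, %d foreground px (%.1f%%)\n",
              class(object), d[1], d[2], object@pixelSizeUm,
              sum(object@pixels), 100 * mean(object@pixels)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec: %d slices of %dx%d px (%.3g um/px)\n",
    "  seedPoints %d, strutThicknessPx %d, anisotropy %.2f,\n",
    "  fragmentationProb %.2f, noiseSigma %.2f, rngSeed %d\n"),
    object@nSlices, object@imageSize, object@imageSize, object@pixelSizeUm,
    object@seedPoints, object@strutThicknessPx, object@anisotropy,
    object@fragmentationProb, object@noiseSigma, object@rngSeed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d vertices, %d edges, %d components\n",
              nrow(object@vertices), nrow(object@edges), object@nComponents))
})

setMethod("show", "TrabecularGraph", function(object) {
  k <- table(factor(object@vertices$kind,
                    levels = c("junction", "endpoint", "anchor")))
  cat(sprintf(paste0(
    "TrabecularGraph: %d vertices (%d junctions, %d endpoints, %d anchors),",
    " %d edges\n  image %dx%d px, %.3g um/px\n"),
    nrow(object@vertices), k[["junction"]], k[["endpoint"]], k[["anchor"]],
    nrow(object@edges), object@imageDim[1], object@imageDim[2],
    object@pixelSizeUm))
})

setMethod("show", "SimpleGraph", function(object) {
  cat(sprintf("SimpleGraph: %d vertices, %d edges\n",
              object@nVertices, nrow(object@edges)))
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile '%s' (%s): %d slices, depth %.2f-%.2f mm\n",
              object@specimenId, object@group, nrow(object@records),
              min(object@records$depthMm), max(object@records$depthMm)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(paste0(
    "EvalReport [%s]: accuracy %.3f, AUC %s\n",
    "  confusion: TP %d  FN %d  FP %d  TN %d\n"),
    object@arm, object@accuracy,
    ifelse(is.na(object@auc), "undefined", sprintf("%.3f", object@auc)),
    object@tp, object@fn, object@fp, object@tn))
})
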