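#' @include utils.R
NULL

#' A single grayscale micro-CT slice
#'
#' Holds one 2D grayscale slice with values normalized to \[0, 1\], the
#' isotropic pixel size in micrometers, and the 0-based depth index of the
#' slice within its stack.  Slice spacing is assumed equal to the in-plane
#' pixel size (isotropic acquisition).
#'
#' @slot pixels numeric matrix in \[0, 1\] (rows = image rows).
#' @slot pixelSizeUm isotropic pixel size in micrometers.
#' @slot depthIndex 0-based slice index within the stack.
#' @exportClass SliceImage
setClass("SliceImage",
  representation(pixels = "matrix", pixelSizeUm = "numeric",
                 depthIndex = "integer"),
  prototype(pixelSizeUm = 20.5, depthIndex = 0L))

setValidity("SliceImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(dim(p)) != 2)
    return("pixels must be a 2D numeric matrix")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    return("pixel values must lie in [0, 1]")
  if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (length(object@depthIndex) != 1 || object@depthIndex < 0)
    return("depthIndex must be a single non-negative integer")
  TRUE
})

#' @rdname SliceImage-class
#' @param pixels,pixelSizeUm,depthIndex slot values.
#' @export
SliceImage <- function(pixels, pixelSizeUm = 20.5, depthIndex = 0L) {
  new("SliceImage", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm),
      depthIndex = as.integer(depthIndex))
}

#' Binary bone mask
#'
#' Boolean 2D mask (TRUE = bone) with its pixel size.
#'
#' @slot pixels logical matrix.
#' @slot pixelSizeUm isotropic pixel size in micrometers.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", pixelSizeUm = "numeric"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels) || length(dim(object@pixels)) != 2)
    return("pixels must be a 2D logical matrix")
  if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  TRUE
})

#' @rdname BinaryMask-class
#' @param pixels,pixelSizeUm slot values.
#' @export
BinaryMask <- function(pixels, pixelSizeUm = 20.5) {
  storage.mode(pixels) <- "logical"
  new("BinaryMask", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' One-pixel-wide skeleton
#'
#' A [BinaryMask-class] obtained by topology-preserving thinning.
#' @exportClass Skeleton
setClass("Skeleton", contains = "BinaryMask")

#' @rdname Skeleton-class
#' @param pixels,pixelSizeUm slot values.
#' @export
Skeleton <- function(pixels, pixelSizeUm = 20.5) {
  storage.mode(pixels) <- "logical"
  new("Skeleton", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Specification of a synthetic trabecular phantom stack
#'
#' Parameters and seed for one reproducible stack of synthetic trabecular
#' slices with exact ground-truth network topology.  Each slice is the raster
#' of a planar Voronoi ridge lattice: `seedPoints` uniform random seeds are
#' scattered over a padded frame (so finite ridges cover the image window),
#' the lattice is stretched along rows by `anisotropy`, each ridge is deleted
#' independently with probability `fragmentationProb`, survivors are
#' rasterized, dilated to `strutThicknessPx` (a dilation radius; 1 means the
#' raw one-pixel raster) and Gaussian grayscale noise of sd `noiseSigma` is
#' added and clipped to \[0, 1\].
#'
#' `depthProfile` is a function `(sliceIndex, nSlices)` returning named
#' multiplicative modifiers (`seedPoints`, `strutThicknessPx`,
#' `fragmentationProb`) applied at that depth; the default is the identity.
#' Slice `i` is drawn under seed `rngSeed + i`, so slices are individually
#' reproducible and a stack equals its per-slice regenerations.
#'
#' @slot imageSize square image side in pixels.
#' @slot pixelSizeUm micrometers per pixel.
#' @slot nSlices number of slices in the stack.
#' @slot seedPoints Voronoi seed count per slice (controls cell size, i.e.
#'   trabecular separation).
#' @slot strutThicknessPx strut dilation radius in pixels (>= 1).
#' @slot anisotropy row-axis stretch factor (>= 1).
#' @slot fragmentationProb probability in \[0, 1\] of deleting a ridge.
#' @slot noiseSigma grayscale noise standard deviation in \[0, 1\].
#' @slot depthProfile function of (sliceIndex, nSlices) -> named multipliers.
#' @slot rngSeed integer seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(imageSize = "integer", pixelSizeUm = "numeric",
                 nSlices = "integer", seedPoints = "integer",
                 strutThicknessPx = "integer", anisotropy = "numeric",
                 fragmentationProb = "numeric", noiseSigma = "numeric",
                 depthProfile = "function", rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@imageSize < 16) return("imageSize must be >= 16")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (object@nSlices < 1) return("nSlices must be >= 1")
  if (object@seedPoints < 4) return("seedPoints must be >= 4")
  if (object@strutThicknessPx < 1) return("strutThicknessPx must be >= 1")
  if (object@anisotropy < 1) return("anisotropy must be >= 1")
  if (object@fragmentationProb < 0 || object@fragmentationProb > 1)
    return("fragmentationProb must lie in [0, 1]")
  if (object@noiseSigma < 0 || object@noiseSigma > 1)
    return("noiseSigma must lie in [0, 1]")
  TRUE
})

#' Ground-truth lattice graph of a phantom slice
#'
#' The surviving Voronoi ridge lattice behind a generated slice: junction
#' coordinates, edges with rasterized polylines, and the component count of
#' the (vertices, edges) graph.  Only vertices referenced by surviving edges
#' are kept, so the graph is exactly the structure present in the image.
#'
#' @slot vertices integer matrix (row, col) of lattice vertex pixels.
#' @slot edges data.frame with columns `from`, `to` (vertex indices).
#' @slot paths list of integer (row, col) polyline matrices, one per edge.
#' @slot nComponents connected-component count of the lattice graph.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(vertices = "matrix", edges = "data.frame", paths = "list",
                 nComponents = "integer"))

setValidity("GroundTruth", function(object) {
  ne <- nrow(object@edges)
  nv <- nrow(object@vertices)
  if (ne > 0) {
    if (!all(c("from", "to") %in% names(object@edges)))
      return("edges needs columns from, to")
    idx <- c(object@edges$from, object@edges$to)
    if (any(idx < 1) || any(idx > nv))
      return("edge endpoints must reference existing vertices")
    if (length(object@paths) != ne)
      return("one path per edge required")
  }
  TRUE
})

#' Spatial trabecular network graph
#'
#' Multigraph of junctions and endpoints extracted from a skeleton.  Vertices
#' carry their pixel centroid and kind (`junction`: merged cluster of
#' skeleton pixels with >= 3 neighbors; `endpoint`: pixel with <= 1 neighbor;
#' `anchor`: synthetic degree-2 vertex placed on an isolated cycle).  Edges
#' store the ordered pixel path of the traced ridge and its physical length
#' (chamfer arc length x pixel size).  Parallel edges and self-loops are
#' retained; simplification is a metrics-level decision.
#'
#' @slot vertices data.frame: `id`, `row`, `col` (centroid), `kind`.
#' @slot edges data.frame: `id`, `from`, `to`, `lengthUm`, `nPathPixels`.
#' @slot paths list of integer (row, col) path matrices, one per edge.
#' @slot pixelSizeUm micrometers per pixel.
#' @slot imageDim integer length-2 source image dimensions.
#' @exportClass TrabecularGraph
setClass("TrabecularGraph",
  representation(vertices = "data.frame", edges = "data.frame",
                 paths = "list", pixelSizeUm = "numeric",
                 imageDim = "integer"))

setValidity("TrabecularGraph", function(object) {
  v <- object@vertices; e <- object@edges
  if (nrow(v) > 0 && !all(c("id", "row", "col", "kind") %in% names(v)))
    return("vertices needs columns id, row, col, kind")
  if (nrow(e) > 0) {
    if (!all(c("id", "from", "to", "lengthUm", "nPathPixels") %in% names(e)))
      return("edges needs columns id, from, to, lengthUm, nPathPixels")
    if (any(!(e$from %in% v$id)) || any(!(e$to %in% v$id)))
      return("edge endpoints must reference existing vertex ids")
    if (any(e$nPathPixels > 0 & e$lengthUm <= 0))
      return("edges with a nonempty path must have positive length")
  }
  TRUE
})

#' Undirected simple graph for metric computations
#'
#' Vertex count plus a deduplicated, loop-free edge list (columns u < v).
#' @slot nVertices vertex count.
#' @slot edges 2-column integer matrix of edges (u < v).
#' @exportClass SimpleGraph
setClass("SimpleGraph",
  representation(nVertices = "integer", edges = "matrix"))

setValidity("SimpleGraph", function(object) {
  e <- object@edges
  if (nrow(e) > 0) {
    if (ncol(e) != 2) return("edges must have 2 columns")
    if (any(e[, 1] >= e[, 2])) return("edges must satisfy u < v")
    if (any(e > object@nVertices) || any(e < 1))
      return("edge endpoints out of range")
    if (anyDuplicated(e[, 1] + e[, 2] * (object@nVertices + 1)))
      return("duplicate edges")
  }
  TRUE
})

#' @rdname SimpleGraph-class
#' @param nVertices,edges slot values.
#' @export
SimpleGraph <- function(nVertices, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  new("SimpleGraph", nVertices = as.integer(nVertices), edges = edges)
}

#' Per-specimen depth profile of network metrics
#'
#' Ordered per-slice metric records for one specimen with physical depths.
#' @slot specimenId specimen label.
#' @slot group group label (e.g. "CTRL" or "HOA").
#' @slot records data.frame of per-slice metrics ordered by depth, with
#'   columns `depthIndex` and `depthMm` plus metric columns.
#' @exportClass DepthProfile
setClass("DepthProfile",
  representation(specimenId = "character", group = "character",
                 records = "data.frame"))

setValidity("DepthProfile", function(object) {
  r <- object@records
  if (!all(c("depthIndex", "depthMm") %in% names(r)))
    return("records needs depthIndex and depthMm columns")
  if (anyDuplicated(r$depthIndex)) return("duplicate depth indices")
  if (is.unsorted(r$depthMm, strictly = TRUE))
    return("depthMm must be strictly increasing")
  TRUE
})

#' Compact convolutional classifier
#'
#' Four conv blocks (3x3 kernels, stride 1, batch normalization, ReLU) with
#' 2x2 stride-2 max pooling after blocks 1-3, then two fully connected layers
#' and a softmax over the two classes.
#'
#' @slot config list of architecture/training settings (see [cnnConfig()]).
#' @slot params named list of weight arrays.
#' @slot state named list of batch-norm running statistics.
#' @slot classes character vector of the two class labels.
#' @exportClass CNNModel
setClass("CNNModel",
  representation(config = "list", params = "list", state = "list",
                 classes = "character"))

#' Classifier evaluation report
#'
#' Confusion counts at the argmax decision, accuracy, ROC curve over softmax
#' score thresholds, and trapezoidal AUC.
#' @slot tp,tn,fp,fn confusion counts.
#' @slot accuracy fraction correct.
#' @slot roc data.frame of (fpr, tpr, threshold) points.
#' @slot auc area under the ROC curve (NA when undefined).
#' @slot arm input arm label ("raw_images" or "extracted_networks").
#' @exportClass EvalReport
setClass("EvalReport",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer", accuracy = "numeric", roc = "data.frame",
                 auc = "numeric", arm = "character"))

setValidity("EvalReport", function(object) {
  n <- object@tp + object@tn + object@fp + object@fn
  acc <- (object@tp + object@tn) / n
  if (n > 0 && abs(acc - object@accuracy) > 1e-12)
    return("accuracy must equal (tp+tn)/(tp+tn+fp+fn)")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    return("auc must lie in [0, 1]")
  TRUE
})
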