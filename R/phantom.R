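#' @include AllClasses.R AllGenerics.R
NULL

#' Create a phantom specification
#'
#' Constructs a validated [PhantomSpec-class]. Defaults describe a
#' control-like trabecular slice at a typical ex vivo femoral-head
#' acquisition scale: 20.5 um
#' isotropic pixels, a 512 px frame (about 10.5 mm across), 150 Voronoi seeds
#' (mean cell size about 0.8 mm, the scale of trabecular separation), strut
#' dilation radius 3 (strut width about 100 um) and mild fragmentation/noise.
#'
#' @param imageSize square image side in pixels.
#' @param pixelSizeUm micrometers per pixel.
#' @param nSlices number of slices.
#' @param seedPoints Voronoi seeds per slice.
#' @param strutThicknessPx strut dilation radius in pixels; 1 = raw raster.
#' @param anisotropy row-axis stretch factor >= 1.
#' @param fragmentationProb per-ridge deletion probability in \[0, 1\].
#' @param noiseSigma grayscale Gaussian noise sd in \[0, 1\].
#' @param depthProfile function `(sliceIndex, nSlices)` returning named
#'   multipliers for `seedPoints`, `strutThicknessPx`, `fragmentationProb`.
#' @param rngSeed integer seed; slice `i` uses `rngSeed + i`.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- PhantomSpec(imageSize = 128, seedPoints = 20, rngSeed = 1)
#' @export
PhantomSpec <- function(imageSize = 512L, pixelSizeUm = 20.5, nSlices = 1L,
                        seedPoints = 150L, strutThicknessPx = 3L,
                        anisotropy = 1.2, fragmentationProb = 0.05,
                        noiseSigma = 0.08, depthProfile = identityProfile,
                        rngSeed = 1L) {
  new("PhantomSpec", imageSize = as.integer(imageSize),
      pixelSizeUm = as.numeric(pixelSizeUm), nSlices = as.integer(nSlices),
      seedPoints = as.integer(seedPoints),
      strutThicknessPx = as.integer(strutThicknessPx),
      anisotropy = as.numeric(anisotropy),
      fragmentationProb = as.numeric(fragmentationProb),
      noiseSigma = as.numeric(noiseSigma), depthProfile = depthProfile,
      rngSeed = as.integer(rngSeed))
}

#' @rdname PhantomSpec
#' @param sliceIndex,nSlices arguments of a depth profile function.
#' @export
identityProfile <- function(sliceIndex, nSlices) {
  c(seedPoints = 1, strutThicknessPx = 1, fragmentationProb = 1)
}

#' Control-like and HOA-like phantom presets
#'
#' Fixed parameter regimes emulating the qualitative contrasts reported for
#' osteoarthritic femoral heads against controls: the HOA-like regime has
#' thicker struts (sclerotic thickening), more and therefore shorter ridges
#' (compressed trabecular structure), heavier fragmentation (more graph
#' components) and weaker directional anisotropy.
#'
#' @param regime `"control"` or `"hoa"`.
#' @param imageSize,nSlices,rngSeed passed to [PhantomSpec()].
#' @return a [PhantomSpec-class].
#' @export
phantomPreset <- function(regime = c("control", "hoa"), imageSize = 512L,
                          nSlices = 1L, rngSeed = 1L) {
  regime <- match.arg(regime)
  if (regime == "control")
    PhantomSpec(imageSize = imageSize, nSlices = nSlices, seedPoints = 150L,
                strutThicknessPx = 3L, anisotropy = 1.3,
                fragmentationProb = 0.05, noiseSigma = 0.08,
                rngSeed = rngSeed)
  else
    PhantomSpec(imageSize = imageSize, nSlices = nSlices, seedPoints = 300L,
                strutThicknessPx = 6L, anisotropy = 1.1,
                fragmentationProb = 0.25, noiseSigma = 0.08,
                rngSeed = rngSeed)
}

# Per-slice depth-modified parameters.
sliceParams <- function(spec, sliceIndex) {
  m <- spec@depthProfile(sliceIndex, spec@nSlices)
  list(
    seedPoints = max(4L, as.integer(round(spec@seedPoints *
                                            m[["seedPoints"]]))),
    strutThicknessPx = max(1L, as.integer(round(spec@strutThicknessPx *
                                                  m[["strutThicknessPx"]]))),
    fragmentationProb = min(1, max(0, spec@fragmentationProb *
                                     m[["fragmentationProb"]])))
}

# Voronoi ridge lattice of one slice, drawn under seed rngSeed + sliceIndex.
# Returns all finite ridges (float endpoints in row/col), the seeded Bernoulli
# survival mask, and the surviving segments clipped to the frame.
phantomLattice <- function(spec, sliceIndex, seedCoords = NULL) {
  size <- spec@imageSize
  par <- sliceParams(spec, sliceIndex)
  withSeed(spec@rngSeed + sliceIndex, {
    if (is.null(seedCoords)) {
      margin <- round(0.18 * size)
      rows <- runif(par$seedPoints, 1 - margin, size + margin)
      cols <- runif(par$seedPoints, 1 - margin, size + margin)
    } else {
      rows <- seedCoords[, 1]; cols <- seedCoords[, 2]
    }
    # anisotropy: compute the diagram in row-compressed space, map back
    dl <- delaunay_cpp(cols, rows / spec@anisotropy)
    tri <- dl$triangles
    cc <- cbind(row = dl$circumcenters[, 2] * spec@anisotropy,
                col = dl$circumcenters[, 1])
    # Voronoi ridge = shared triangle edge -> segment between circumcenters
    ridges <- matrix(integer(0), ncol = 2)
    if (nrow(tri) > 1) {
      pairs <- rbind(tri[, c(1, 2)], tri[, c(1, 3)], tri[, c(2, 3)])
      pairs <- t(apply(pairs, 1, sort))
      key <- paste(pairs[, 1], pairs[, 2])
      triId <- rep(seq_len(nrow(tri)), 3)
      byKey <- split(triId, key)
      shared <- byKey[lengths(byKey) == 2]
      if (length(shared) > 0) {
        ridges <- do.call(rbind, lapply(shared, sort))
        ridges <- ridges[order(ridges[, 1], ridges[, 2]), , drop = FALSE]
      }
    }
    nr <- nrow(ridges)
    keep <- if (nr > 0) runif(nr) >= par$fragmentationProb else logical(0)
    segments <- vector("list", nr)
    for (i in seq_len(nr)) {
      if (!keep[i]) next
      seg <- clipSegment(cc[ridges[i, 1], ], cc[ridges[i, 2], ], 1, size)
      if (!is.null(seg) && sqrt(sum((seg[2, ] - seg[1, ])^2)) >= 0.5)
        segments[[i]] <- seg
    }
    list(ridges = ridges, circumcenters = cc, keep = keep,
         segments = segments, params = par)
  })
}

# Assemble a GroundTruth from clipped surviving segments.
latticeGroundTruth <- function(segments, size) {
  segs <- Filter(Negate(is.null), segments)
  if (length(segs) == 0)
    return(new("GroundTruth", vertices = matrix(integer(0), ncol = 2),
               edges = data.frame(from = integer(0), to = integer(0)),
               paths = list(), nComponents = 0L))
  ends <- do.call(rbind, lapply(segs, function(s)
    pmin(pmax(round(s), 1), size)))
  keyOf <- function(rc) rc[, 1] + (rc[, 2] - 1) * size
  from <- ends[seq(1, nrow(ends), 2), , drop = FALSE]
  to <- ends[seq(2, nrow(ends), 2), , drop = FALSE]
  ok <- keyOf(from) != keyOf(to)   # drop ridges collapsing to one pixel
  from <- from[ok, , drop = FALSE]; to <- to[ok, , drop = FALSE]
  if (nrow(from) == 0)
    return(new("GroundTruth", vertices = matrix(integer(0), ncol = 2),
               edges = data.frame(from = integer(0), to = integer(0)),
               paths = list(), nComponents = 0L))
  allKeys <- c(keyOf(from), keyOf(to))
  uk <- unique(allKeys)
  vid <- match(allKeys, uk)
  nv <- length(uk)
  vertices <- cbind(row = (uk - 1) %% size + 1, col = (uk - 1) %/% size + 1)
  ne <- nrow(from)
  edges <- data.frame(from = vid[seq_len(ne)], to = vid[ne + seq_len(ne)])
  paths <- lapply(seq_len(ne), function(i)
    bresenham(from[i, 1], from[i, 2], to[i, 1], to[i, 2]))
  comp <- unionFindComponents(nv, edges$from, edges$to)
  new("GroundTruth", vertices = vertices, edges = edges, paths = paths,
      nComponents = length(unique(comp)))
}

#' Generate one synthetic trabecular slice with ground truth
#'
#' Builds the Voronoi ridge lattice of `seedPoints` uniform random seeds
#' (row-stretched by `anisotropy`), deletes each ridge independently with
#' probability `fragmentationProb`, rasterizes the survivors, dilates them to
#' the requested strut thickness, adds Gaussian grayscale noise and clips to
#' \[0, 1\].  The surviving lattice is returned as exact ground truth.
#'
#' @param spec a [PhantomSpec-class].
#' @param sliceIndex 0-based slice index, `0 <= sliceIndex < nSlices`.
#' @param seedCoords optional matrix of fixed (row, col) seed coordinates,
#'   bypassing random placement (for controlled experiments).
#' @return list with elements `image` ([SliceImage-class]) and
#'   `groundTruth` ([GroundTruth-class]).
#' @examples
#' sl <- generateSlice(PhantomSpec(imageSize = 96, seedPoints = 8,
#'                                 noiseSigma = 0, rngSeed = 3), 0)
#' nEdges(sl$groundTruth)
#' @export
generateSlice <- function(spec, sliceIndex, seedCoords = NULL) {
  validObject(spec)
  if (sliceIndex < 0 || sliceIndex >= spec@nSlices)
    stop("sliceIndex must lie in [0, nSlices)")
  size <- spec@imageSize
  lat <- phantomLattice(spec, sliceIndex, seedCoords)
  gt <- latticeGroundTruth(lat$segments, size)
  bone <- matrix(0, size, size)
  for (p in gt@paths) bone[cbind(p[, 1], p[, 2])] <- 1
  t <- lat$params$strutThicknessPx
  if (t > 1) {
    brush <- EBImage::makeBrush(2L * (t - 1L) + 1L, shape = "disc")
    bone <- EBImage::dilate(bone, brush)
  }
  img <- withSeed(spec@rngSeed + sliceIndex + 500000L, {
    if (spec@noiseSigma > 0)
      pmin(pmax(bone + rnorm(length(bone), sd = spec@noiseSigma), 0), 1)
    else bone
  })
  img <- matrix(img, size, size)
  list(image = SliceImage(img, spec@pixelSizeUm, sliceIndex),
       groundTruth = gt)
}

#' Generate a full phantom stack
#'
#' Applies the spec's depth profile per slice; slice `i` is drawn under seed
#' `rngSeed + i`, so the stack is bit-identical to per-slice regeneration.
#'
#' @param spec a [PhantomSpec-class].
#' @return list of length `nSlices`; each element as in [generateSlice()].
#' @export
generateStack <- function(spec) {
  validObject(spec)
  lapply(seq_len(spec@nSlices) - 1L, function(i) generateSlice(spec, i))
}

#' Generate a labeled two-group phantom cohort
#'
#' Draws `nPerGroup` independent slices per regime with per-sample seeds
#' `rngSeed + sample index`, mirroring a balanced expert-labeled image set.
#'
#' @param controlSpec,hoaSpec [PhantomSpec-class] objects for the two groups.
#' @param nPerGroup samples per group (>= 1).
#' @return list with `images` (list of [SliceImage-class]), `labels` (factor
#'   with levels `CTRL`, `HOA`), `sampleIds`, and `groundTruths`.
#' @export
makeCohort <- function(controlSpec, hoaSpec, nPerGroup) {
  if (nPerGroup < 1) stop("nPerGroup must be >= 1")
  oneGroup <- function(spec, label, offset) {
    lapply(seq_len(nPerGroup), function(i) {
      s <- spec
      s@rngSeed <- spec@rngSeed + offset + i
      out <- generateSlice(s, 0L)
      list(image = out$image, groundTruth = out$groundTruth,
           label = label,
           sampleId = sprintf("%s_%03d", label, i))
    })
  }
  ctrl <- oneGroup(controlSpec, "CTRL", 0L)
  hoa <- oneGroup(hoaSpec, "HOA", nPerGroup)
  all <- c(ctrl, hoa)
  list(images = lapply(all, `[[`, "image"),
       labels = factor(vapply(all, `[[`, "", "label"),
                       levels = c("CTRL", "HOA")),
       sampleIds = vapply(all, `[[`, "", "sampleId"),
       groundTruths = lapply(all, `[[`, "groundTruth"))
}
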