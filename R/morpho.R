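#' @include AllClasses.R
NULL

#' Bone area fraction
#'
#' Fraction of bone pixels in the mask — the 2D per-slice analogue of
#' trabecular bone volume fraction.
#'
#' @param mask a [BinaryMask-class].
#' @return fraction in \[0, 1\].
#' @export
areaFraction <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  mean(mask@pixels)
}

#' Mean local thickness or separation
#'
#' Mean over foreground pixels of the diameter of the largest inscribed disc
#' covering each pixel (local thickness transform on the Euclidean distance
#' map) — the 2D analogue of mean trabecular thickness.  With
#' `invert = TRUE` the transform runs on the background, giving trabecular
#' separation (the thickness of the marrow spaces).
#'
#' @param mask a [BinaryMask-class].
#' @param invert measure the background (separation) instead of the bone.
#' @return mean thickness in micrometers, or NA (with a warning) when the
#'   measured phase is empty.
#' @export
localThickness <- function(mask, invert = FALSE) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@pixels
  if (invert) m <- !m
  if (!any(m)) {
    warning("local thickness undefined: empty ", if (invert) "background"
            else "foreground")
    return(NA_real_)
  }
  dist <- EBImage::distmap(matrix(as.numeric(m), nrow(m)), metric = "euclidean")
  th <- local_thickness_cpp(matrix(dist, nrow(m)))
  mean(th[m]) * mask@pixelSizeUm
}

#' Box-counting fractal dimension
#'
#' Slope of log(box count) versus log(1/box size) by least squares.  In the
#' default `"boundary"` mode, boxes are counted that contain at least one
#' boundary pixel (a bone pixel 4-adjacent to background or the frame);
#' `"area"` mode counts boxes containing any bone pixel.
#'
#' @param mask a [BinaryMask-class].
#' @param boxSizes box sides in pixels; at least 3 sizes spanning at least
#'   one octave.
#' @param mode `"boundary"` (surface complexity) or `"area"`.
#' @return estimated dimension, or NA (with a warning) for degenerate masks.
#' @export
fractalDimension <- function(mask, boxSizes = c(2L, 4L, 8L, 16L, 32L),
                             mode = c("boundary", "area")) {
  stopifnot(is(mask, "BinaryMask"))
  mode <- match.arg(mode)
  boxSizes <- sort(unique(as.integer(boxSizes)))
  if (length(boxSizes) < 3 || max(boxSizes) < 2 * min(boxSizes))
    stop("need >= 3 box sizes spanning at least one octave")
  m <- mask@pixels
  if (!any(m)) {
    warning("fractal dimension undefined: empty mask")
    return(NA_real_)
  }
  target <- if (mode == "boundary") maskBoundary(m) else m
  if (!any(target)) {
    warning("fractal dimension undefined: no boundary pixels")
    return(NA_real_)
  }
  counts <- vapply(boxSizes, function(s) {
    idx <- which(target, arr.ind = TRUE)
    boxes <- paste((idx[, 1] - 1L) %/% s, (idx[, 2] - 1L) %/% s)
    length(unique(boxes))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / boxSizes))
  unname(coef(fit)[2])
}

# bone pixels 4-adjacent to background or the image frame
maskBoundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  m & !interior
}

#' Compute the conventional 2D morphometric panel for one slice
#'
#' Per-slice 2D analogues of the conventional morphometric parameters: bone
#' area fraction, mean trabecular thickness, mean trabecular separation, and
#' box-counting fractal dimension.  These are single-slice analogues of
#' volumetric measures, and outputs are labeled as such (`*2d` columns).
#'
#' @param mask a [BinaryMask-class].
#' @param boxSizes passed to [fractalDimension()].
#' @return one-row data.frame with columns `boneAreaFraction2d`,
#'   `meanThicknessUm2d`, `meanSeparationUm2d`, `fractalDimension2d`.
#' @export
computeMorpho <- function(mask, boxSizes = c(2L, 4L, 8L, 16L, 32L)) {
  data.frame(
    boneAreaFraction2d = areaFraction(mask),
    meanThicknessUm2d = suppressWarnings(localThickness(mask)),
    meanSeparationUm2d = suppressWarnings(localThickness(mask,
                                                         invert = TRUE)),
    fractalDimension2d = suppressWarnings(
      tryCatch(fractalDimension(mask, boxSizes), error = function(e)
        NA_real_)))
}
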