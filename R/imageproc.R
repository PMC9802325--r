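#' @include AllClasses.R
NULL

#' Read a micro-CT slice from TIFF or PNG
#'
#' Reads an 8- or 16-bit grayscale image (RGB is converted by ITU-R BT.709
#' luminance) and rescales values to \[0, 1\] by bit depth.
#'
#' @param path file path (extension .tif, .tiff or .png).
#' @param pixelSizeUm isotropic pixel size in micrometers.
#' @param depthIndex 0-based depth index of the slice.
#' @return a [SliceImage-class].
#' @export
readSlice <- function(path, pixelSizeUm = 20.5, depthIndex = 0L) {
  if (!file.exists(path)) stop("cannot read slice: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
           tif = , tiff = tiff::readTIFF(path),
           png = png::readPNG(path),
           stop("unsupported image format: ", path)),
    error = function(e) stop("cannot read image file ", path, ": ",
                             conditionMessage(e)))
  if (length(dim(px)) == 3) {
    if (dim(px)[3] < 3) px <- px[, , 1]
    else px <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  }
  if (length(dim(px)) != 2)
    stop("not a 2D grayscale image: ", path)
  px <- pmin(pmax(px, 0), 1)
  SliceImage(matrix(px, nrow = nrow(px)), pixelSizeUm, depthIndex)
}

#' Linear contrast stretch between percentiles
#'
#' Maps the `lowPct`/`highPct` intensity percentiles to 0/1 with clipping.
#' A constant image is returned unchanged with a warning.  Applying the
#' (0, 100) stretch twice equals applying it once.
#'
#' @param img a [SliceImage-class].
#' @param lowPct,highPct percentiles in \[0, 100\] with `lowPct < highPct`.
#' @return a contrast-stretched [SliceImage-class].
#' @export
adjustIntensity <- function(img, lowPct = 1, highPct = 99) {
  stopifnot(is(img, "SliceImage"))
  if (lowPct < 0 || highPct > 100 || lowPct >= highPct)
    stop("need 0 <= lowPct < highPct <= 100")
  p <- img@pixels
  q <- quantile(p, c(lowPct, highPct) / 100, names = FALSE)
  if (q[2] <= q[1]) q <- range(p)
  if (q[2] <= q[1]) {
    warning("constant image: contrast adjustment skipped")
    return(img)
  }
  out <- pmin(pmax((p - q[1]) / (q[2] - q[1]), 0), 1)
  SliceImage(matrix(out, nrow = nrow(p)), img@pixelSizeUm, img@depthIndex)
}

#' Restrict a slice to a region of interest
#'
#' Sets pixels outside the region to 0.  `roi = NULL` is the identity.
#' Supported regions: `list(type = "disc", center = c(row, col), radius = r)`,
#' `list(type = "rect", rows = c(r0, r1), cols = c(c0, c1))`, or
#' `list(type = "polygon", vertices = <n x 2 (row, col) matrix>)` (even-odd
#' rule).
#'
#' @param img a [SliceImage-class].
#' @param roi region description or NULL.
#' @return a masked [SliceImage-class].
#' @export
segmentROI <- function(img, roi = NULL) {
  stopifnot(is(img, "SliceImage"))
  if (is.null(roi)) return(img)
  d <- dim(img@pixels)
  inside <- switch(roi$type,
    disc = {
      ctr <- roi$center; r <- roi$radius
      if (ctr[1] - r < 0.5 || ctr[2] - r < 0.5 ||
          ctr[1] + r > d[1] + 0.5 || ctr[2] + r > d[2] + 0.5)
        stop("roi lies outside the image frame")
      rows <- matrix(seq_len(d[1]), d[1], d[2])
      cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
      (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2
    },
    rect = {
      if (roi$rows[1] < 1 || roi$cols[1] < 1 ||
          roi$rows[2] > d[1] || roi$cols[2] > d[2])
        stop("roi lies outside the image frame")
      m <- matrix(FALSE, d[1], d[2])
      m[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]] <- TRUE
      m
    },
    polygon = {
      v <- roi$vertices
      if (min(v) < 1 || max(v[, 1]) > d[1] || max(v[, 2]) > d[2])
        stop("roi lies outside the image frame")
      rows <- matrix(seq_len(d[1]), d[1], d[2])
      cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
      pointInPolygon(rows, cols, v)
    },
    stop("unknown roi type: ", roi$type))
  out <- img@pixels
  out[!inside] <- 0
  SliceImage(out, img@pixelSizeUm, img@depthIndex)
}

# even-odd point-in-polygon test, vectorized over pixel grids
pointInPolygon <- function(rows, cols, v) {
  n <- nrow(v)
  inside <- matrix(FALSE, nrow(rows), ncol(rows))
  j <- n
  for (i in seq_len(n)) {
    ri <- v[i, 1]; ci <- v[i, 2]; rj <- v[j, 1]; cj <- v[j, 2]
    crosses <- ((ci > cols) != (cj > cols)) &
      (rows < (rj - ri) * (cols - ci) / (cj - ci) + ri)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Binarize a slice to a bone mask
#'
#' With an explicit threshold, pixels strictly above it are bone.  Without
#' one, a global automatic threshold is chosen by Otsu's between-class
#' variance criterion (256 bins), the standard choice for the bimodal
#' bone/background histograms of micro-CT.  A constant image yields an
#' all-background mask with a warning.
#'
#' @param img a [SliceImage-class].
#' @param threshold optional threshold in \[0, 1\].
#' @return a [BinaryMask-class].
#' @export
binarize <- function(img, threshold = NULL) {
  stopifnot(is(img, "SliceImage"))
  p <- img@pixels
  if (is.null(threshold)) {
    if (diff(range(p)) == 0) {
      warning("constant image: no foreground found")
      return(BinaryMask(matrix(FALSE, nrow(p), ncol(p)), img@pixelSizeUm))
    }
    threshold <- EBImage::otsu(p, range = c(0, 1), levels = 256)
  }
  BinaryMask(p > threshold, img@pixelSizeUm)
}

#' Remove small objects and fill small holes
#'
#' Deletes 8-connected foreground components smaller than `minObjectPx`
#' (scanner speckle, disconnected scatter) and fills 4-connected background
#' holes smaller than `minHolePx`.  The defaults, 20 px each at 20.5 um
#' pixels (~0.008 mm^2), are below one trabecular width.
#'
#' @param mask a [BinaryMask-class].
#' @param minObjectPx,minHolePx minimum surviving object/hole size in pixels.
#' @return a cleaned [BinaryMask-class].
#' @export
cleanMask <- function(mask, minObjectPx = 20L, minHolePx = 20L) {
  stopifnot(is(mask, "BinaryMask"))
  if (minObjectPx < 0 || minHolePx < 0)
    stop("minObjectPx and minHolePx must be >= 0")
  m <- mask@pixels
  if (minObjectPx > 0 && any(m)) {
    lab <- label_mask_cpp(m, 8L)
    sizes <- tabulate(lab)
    m[lab > 0 & sizes[pmax(lab, 1)] < minObjectPx] <- FALSE
  }
  if (minHolePx > 0 && any(!m)) {
    labBg <- label_mask_cpp(!m, 4L)
    border <- unique(c(labBg[1, ], labBg[nrow(m), ], labBg[, 1],
                       labBg[, ncol(m)]))
    sizes <- tabulate(labBg)
    isHole <- labBg > 0 & !(labBg %in% border) & sizes[pmax(labBg, 1)] < minHolePx
    m[isHole] <- TRUE
  }
  BinaryMask(m, mask@pixelSizeUm)
}

#' Reduce a mask to a one-pixel-wide skeleton
#'
#' Topology-preserving medial-line thinning: simple pixels (Yokoi
#' connectivity number 1 for the 8-connected foreground) that are not
#' endpoints are deleted sequentially in four directional subiterations until
#' stable.  Every deletion is individually topology-safe, so the 8-connected
#' component structure of the mask is preserved exactly; endpoints are kept
#' so line arms retain their length; components that thin to a single pixel
#' survive as isolated pixels.
#'
#' @param mask a [BinaryMask-class].
#' @return a [Skeleton-class].
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  Skeleton(thin_cpp(mask@pixels), mask@pixelSizeUm)
}
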