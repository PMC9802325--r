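#' @include AllClasses.R graph.R
NULL

#' Convert a trabecular network to an igraph object
#'
#' Vertex attributes: `row`, `col`, `kind`; edge attributes: `lengthUm`,
#' `nPathPixels`.  Pixel paths are not carried over (igraph has no list
#' attributes in GraphML); use the CSV writers for lossless round trips.
#'
#' @param g a [TrabecularGraph-class].
#' @return an igraph multigraph.
#' @export
asIgraph <- function(g) {
  stopifnot(is(g, "TrabecularGraph"))
  v <- g@vertices
  e <- g@edges
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(e$from), to = as.character(e$to),
                   lengthUm = e$lengthUm, nPathPixels = e$nPathPixels),
    directed = FALSE,
    vertices = data.frame(name = as.character(v$id), row = v$row,
                          col = v$col, kind = v$kind))
}

#' Write a network as GraphML
#'
#' @param g a [TrabecularGraph-class].
#' @param path output .graphml path.
#' @export
writeGraphML <- function(g, path) {
  igraph::write_graph(asIgraph(g), path, format = "graphml")
  invisible(path)
}

#' Write / read a network as paired CSV tables
#'
#' `vertices.csv` holds `id, row, col, kind`; `edges.csv` holds
#' `id, from, to, lengthUm, nPathPixels, path` with the pixel path
#' serialized as `row:col` pairs joined by `;`, making the round trip
#' lossless up to floating-point printing.
#'
#' @param g a [TrabecularGraph-class].
#' @param verticesPath,edgesPath output CSV paths.
#' @export
writeNetworkCSV <- function(g, verticesPath, edgesPath) {
  write.csv(g@vertices, verticesPath, row.names = FALSE)
  e <- g@edges
  e$path <- vapply(g@paths, function(p)
    paste(paste(p[, 1], p[, 2], sep = ":"), collapse = ";"), "")
  write.csv(e, edgesPath, row.names = FALSE)
  invisible(c(verticesPath, edgesPath))
}

#' @rdname writeNetworkCSV
#' @param pixelSizeUm,imageDim metadata restored on read.
#' @return `readNetworkCSV`: a [TrabecularGraph-class].
#' @export
readNetworkCSV <- function(verticesPath, edgesPath, pixelSizeUm = 20.5,
                           imageDim = c(0L, 0L)) {
  v <- read.csv(verticesPath, stringsAsFactors = FALSE)
  e <- read.csv(edgesPath, stringsAsFactors = FALSE)
  paths <- lapply(e$path, function(s) {
    if (is.na(s) || s == "") return(matrix(integer(0), ncol = 2))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    do.call(rbind, lapply(parts, as.integer))
  })
  e$path <- NULL
  if (nrow(v) == 0)
    v <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                    kind = character(0), stringsAsFactors = FALSE)
  new("TrabecularGraph", vertices = v, edges = e, paths = paths,
      pixelSizeUm = pixelSizeUm, imageDim = as.integer(imageDim))
}

#' Write a slice image to disk
#'
#' PNG slices are written 8-bit, TIFF 16-bit.
#'
#' @param img a [SliceImage-class].
#' @param path output path ending in .png, .tif or .tiff.
#' @export
writeSlice <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img@pixels, path),
         tif = , tiff = tiff::writeTIFF(img@pixels, path,
                                        bits.per.sample = 16L),
         stop("unsupported output format: ", path))
  invisible(path)
}

#' Write a QC overlay of a network on its source slice
#'
#' Grayscale slice with traced edges in red, junction vertices in yellow
#' and endpoints in green.
#'
#' @param img the source [SliceImage-class].
#' @param g the extracted [TrabecularGraph-class].
#' @param path output PNG path.
#' @export
writeOverlayPNG <- function(img, g, path) {
  d <- dim(img@pixels)
  arr <- array(rep(img@pixels, 3), dim = c(d, 3))
  setPx <- function(rc, rgb) {
    rc <- rc[rc[, 1] >= 1 & rc[, 1] <= d[1] &
             rc[, 2] >= 1 & rc[, 2] <= d[2], , drop = FALSE]
    for (ch in 1:3) arr[cbind(rc, ch)] <<- rgb[ch]
  }
  for (p in g@paths) setPx(p, c(1, 0, 0))
  v <- g@vertices
  for (i in seq_len(nrow(v))) {
    r <- round(v$row[i]); c <- round(v$col[i])
    block <- as.matrix(expand.grid(r + (-1:1), c + (-1:1)))
    setPx(block, if (v$kind[i] == "endpoint") c(0, 1, 0) else c(1, 1, 0))
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Write a phantom stack with its ground truth
#'
#' Writes one image per slice (`slice_0000.<ext>`), the ground-truth graph
#' of each slice as GraphML plus vertex/edge CSV tables, and returns the
#' written paths.
#'
#' @param stack output of [generateStack()].
#' @param dir output directory (created if missing).
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @export
writeStack <- function(stack, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "tif"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(stack)) {
    base <- file.path(dir, sprintf("slice_%04d", i - 1L))
    img <- stack[[i]]$image
    gt <- stack[[i]]$groundTruth
    writeSlice(img, paste0(base, ".", ext))
    write.csv(as.data.frame(gt@vertices),
              paste0(base, "_gt_vertices.csv"), row.names = FALSE)
    write.csv(gt@edges, paste0(base, "_gt_edges.csv"), row.names = FALSE)
    gg <- if (nrow(gt@vertices) == 0) {
      igraph::make_empty_graph(0, directed = FALSE)
    } else {
      igraph::graph_from_data_frame(
        d = data.frame(from = as.character(gt@edges$from),
                       to = as.character(gt@edges$to)),
        directed = FALSE,
        vertices = data.frame(
          name = as.character(seq_len(nrow(gt@vertices))),
          row = gt@vertices[, 1], col = gt@vertices[, 2]))
    }
    igraph::write_graph(gg, paste0(base, "_gt.graphml"), format = "graphml")
    paths <- c(paths, paste0(base, ".", ext))
  }
  invisible(paths)
}
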