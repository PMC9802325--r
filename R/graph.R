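#' @include AllClasses.R imageproc.R
NULL

# 8-neighbour offsets in fixed scan order (deterministic tracing)
NB_OFF <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Classify skeleton pixels into endpoints, ridges and junctions
#'
#' Each skeleton pixel is classified by its 8-neighbour skeleton count:
#' endpoint (<= 1 neighbour, including isolated pixels), ridge (2), junction
#' (>= 3).  8-connected clusters of junction pixels are merged into single
#' junction vertices at the cluster centroid — thinning produces multi-pixel
#' junction clusters, and without merging vertex counts would be inflated by
#' an algorithmic artifact.
#'
#' @param skel a [Skeleton-class].
#' @return list with `typeMap` (0 background, 1 endpoint, 2 ridge,
#'   3 junction), `clusterMap` (vertex id per node pixel, 0 elsewhere) and
#'   `nodes` (data.frame `id`, `row`, `col`, `kind`).
#' @export
detectNodes <- function(skel) {
  stopifnot(is(skel, "Skeleton"))
  m <- skel@pixels
  nb <- neighbor_count_cpp(m)
  typeMap <- matrix(0L, nrow(m), ncol(m))
  typeMap[m & nb <= 1] <- 1L
  typeMap[m & nb == 2] <- 2L
  typeMap[m & nb >= 3] <- 3L
  clusterMap <- matrix(0L, nrow(m), ncol(m))
  nodes <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE)
  nextId <- 0L
  jlab <- label_mask_cpp(typeMap == 3L, 8L)
  nj <- max(jlab)
  if (nj > 0) {
    for (j in seq_len(nj)) {
      idx <- which(jlab == j)
      nextId <- nextId + 1L
      clusterMap[idx] <- nextId
      rows <- (idx - 1L) %% nrow(m) + 1L
      cols <- (idx - 1L) %/% nrow(m) + 1L
      nodes <- rbind(nodes, data.frame(id = nextId, row = mean(rows),
                                       col = mean(cols), kind = "junction",
                                       stringsAsFactors = FALSE))
    }
  }
  eidx <- which(typeMap == 1L)
  for (i in eidx) {
    nextId <- nextId + 1L
    clusterMap[i] <- nextId
    nodes <- rbind(nodes, data.frame(
      id = nextId, row = (i - 1L) %% nrow(m) + 1L,
      col = (i - 1L) %/% nrow(m) + 1L, kind = "endpoint",
      stringsAsFactors = FALSE))
  }
  list(typeMap = typeMap, clusterMap = clusterMap, nodes = nodes)
}

# skeleton neighbours of (r, c) in fixed offset order, as n x 2 matrix
skelNeighbors <- function(m, r, c) {
  rr <- r + NB_OFF[, 1]; cc <- c + NB_OFF[, 2]
  ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  rr <- rr[ok]; cc <- cc[ok]
  on <- m[cbind(rr, cc)]
  cbind(rr[on], cc[on])
}

#' Trace individual ridges into a spatial multigraph
#'
#' Walks ridge pixels outward from every node pixel until another node is
#' reached, assigning each ridge pixel to exactly one edge; the ordered pixel
#' path is recorded and the physical length is the chamfer arc length (1 per
#' lateral step, sqrt(2) per diagonal step, times the pixel size) — the arc
#' length of a curved trabecula, not its endpoint distance.  Directly
#' adjacent node clusters yield an edge with no interior pixels.  Ridge
#' pixels unreachable from any node form isolated cycles; each is represented
#' as a self-loop on a synthetic degree-2 anchor vertex placed at the cycle's
#' first pixel in scan order.
#'
#' @param skel a [Skeleton-class].
#' @param nodes output of [detectNodes()] on the same skeleton.
#' @return a [TrabecularGraph-class].
#' @export
traceEdges <- function(skel, nodes) {
  m <- skel@pixels
  typeMap <- nodes$typeMap
  clusterMap <- nodes$clusterMap
  vdf <- nodes$nodes
  visited <- matrix(FALSE, nrow(m), ncol(m))
  edgesFrom <- integer(0); edgesTo <- integer(0); paths <- list()
  addEdge <- function(a, b, path) {
    edgesFrom[[length(edgesFrom) + 1L]] <<- a
    edgesTo[[length(edgesTo) + 1L]] <<- b
    paths[[length(paths) + 1L]] <<- path
  }
  walk <- function(startId, pr, pc, qr, qc) {
    path <- rbind(c(pr, pc), c(qr, qc))
    visited[qr, qc] <<- TRUE
    prevR <- pr; prevC <- pc; curR <- qr; curC <- qc
    repeat {
      nbrs <- skelNeighbors(m, curR, curC)
      keep <- !(nbrs[, 1] == prevR & nbrs[, 2] == prevC)
      nbrs <- nbrs[keep, , drop = FALSE]
      if (nrow(nbrs) == 0) {          # defensive: dangling ridge pixel
        addEdge(startId, clusterMap[path[1, 1], path[1, 2]], path)
        return(invisible())
      }
      nr <- nbrs[1, 1]; nc <- nbrs[1, 2]
      if (clusterMap[nr, nc] > 0L) {
        path <- rbind(path, c(nr, nc))
        addEdge(startId, clusterMap[nr, nc], path)
        return(invisible())
      }
      if (visited[nr, nc]) {          # defensive: should not occur
        addEdge(startId, clusterMap[path[1, 1], path[1, 2]], path)
        return(invisible())
      }
      visited[nr, nc] <<- TRUE
      path <- rbind(path, c(nr, nc))
      prevR <- curR; prevC <- curC; curR <- nr; curC <- nc
    }
  }
  # ridge walks from every node pixel, in id then scan order
  if (nrow(vdf) > 0) {
    for (vid in vdf$id) {
      idx <- which(clusterMap == vid)
      idx <- idx[order(idx)]
      for (i in idx) {
        pr <- (i - 1L) %% nrow(m) + 1L
        pc <- (i - 1L) %/% nrow(m) + 1L
        nbrs <- skelNeighbors(m, pr, pc)
        for (k in seq_len(nrow(nbrs))) {
          qr <- nbrs[k, 1]; qc <- nbrs[k, 2]
          if (typeMap[qr, qc] == 2L && !visited[qr, qc])
            walk(vid, pr, pc, qr, qc)
        }
      }
    }
    # direct adjacency between distinct clusters (no interior ridge pixels)
    nodeIdx <- which(clusterMap > 0L)
    seenPairs <- character(0)
    for (i in nodeIdx) {
      pr <- (i - 1L) %% nrow(m) + 1L
      pc <- (i - 1L) %/% nrow(m) + 1L
      a <- clusterMap[pr, pc]
      nbrs <- skelNeighbors(m, pr, pc)
      for (k in seq_len(nrow(nbrs))) {
        b <- clusterMap[nbrs[k, 1], nbrs[k, 2]]
        if (b > 0L && b != a) {
          key <- paste(min(a, b), max(a, b))
          if (!(key %in% seenPairs)) {
            seenPairs <- c(seenPairs, key)
            addEdge(a, b, rbind(c(pr, pc), c(nbrs[k, 1], nbrs[k, 2])))
          }
        }
      }
    }
  }
  # isolated cycles: all remaining unvisited ridge pixels
  repeat {
    left <- which(typeMap == 2L & !visited & clusterMap == 0L)
    if (length(left) == 0) break
    i <- left[1]
    ar <- (i - 1L) %% nrow(m) + 1L
    ac <- (i - 1L) %/% nrow(m) + 1L
    newId <- if (nrow(vdf) > 0) max(vdf$id) + 1L else 1L
    clusterMap[ar, ac] <- newId
    vdf <- rbind(vdf, data.frame(id = newId, row = ar, col = ac,
                                 kind = "anchor", stringsAsFactors = FALSE))
    nbrs <- skelNeighbors(m, ar, ac)
    walk(newId, ar, ac, nbrs[1, 1], nbrs[1, 2])
  }
  ne <- length(edgesFrom)
  paths <- lapply(paths, function(p) {
    storage.mode(p) <- "integer"
    dimnames(p) <- NULL
    p
  })
  lengths <- vapply(paths, chamferLength, numeric(1)) * skel@pixelSizeUm
  npix <- vapply(paths, nrow, integer(1))
  edges <- data.frame(id = seq_len(ne), from = edgesFrom, to = edgesTo,
                      lengthUm = lengths, nPathPixels = npix)
  new("TrabecularGraph", vertices = vdf, edges = edges, paths = paths,
      pixelSizeUm = skel@pixelSizeUm, imageDim = dim(m))
}

#' Extract the trabecular network from one slice
#'
#' Runs the full extraction chain: contrast adjustment, optional region of
#' interest, binarization, cleaning, thinning, node detection and ridge
#' tracing.  Deterministic for fixed parameters.
#'
#' @param img a [SliceImage-class].
#' @param params named list of settings: `lowPct`, `highPct` (contrast
#'   stretch percentiles), `roi` (see [segmentROI()]), `threshold` (NULL for
#'   Otsu), `minObjectPx`, `minHolePx` (see [cleanMask()]).  Missing entries
#'   take the defaults of [extractionParams()].
#' @return a [TrabecularGraph-class].
#' @export
extractNetwork <- function(img, params = extractionParams()) {
  p <- utils::modifyList(extractionParams(), params)
  adj <- adjustIntensity(img, p$lowPct, p$highPct)
  adj <- segmentROI(adj, p$roi)
  mask <- binarize(adj, p$threshold)
  mask <- cleanMask(mask, p$minObjectPx, p$minHolePx)
  skel <- skeletonize(mask)
  traceEdges(skel, detectNodes(skel))
}

#' @rdname extractNetwork
#' @export
extractionParams <- function() {
  list(lowPct = 1, highPct = 99, roi = NULL, threshold = NULL,
       minObjectPx = 20L, minHolePx = 20L)
}

#' Render a network graph back into a binary image
#'
#' Draws all edge pixel paths (value 1) and dilates each vertex centroid to a
#' 3x3 block (clipped at the frame), on a zero background — the input
#' encoding used when feeding extracted networks to the classifier.
#'
#' @param g a [TrabecularGraph-class].
#' @param imageDim integer length-2 output dimensions; defaults to the
#'   graph's source image dimensions.
#' @return a binary [SliceImage-class].
#' @export
renderNetwork <- function(g, imageDim = g@imageDim) {
  stopifnot(is(g, "TrabecularGraph"))
  out <- matrix(0, imageDim[1], imageDim[2])
  coords <- rbind(
    if (nrow(g@vertices)) cbind(g@vertices$row, g@vertices$col),
    do.call(rbind, g@paths))
  if (!is.null(coords) && nrow(coords) > 0) {
    if (min(coords) < 0.5 || max(coords[, 1]) > imageDim[1] + 0.49 ||
        max(coords[, 2]) > imageDim[2] + 0.49)
      stop("graph coordinates lie outside the image frame")
  }
  for (p in g@paths) out[p] <- 1
  if (nrow(g@vertices) > 0) {
    for (i in seq_len(nrow(g@vertices))) {
      r <- round(g@vertices$row[i]); c <- round(g@vertices$col[i])
      rr <- max(1, r - 1):min(imageDim[1], r + 1)
      cc <- max(1, c - 1):min(imageDim[2], c + 1)
      out[rr, cc] <- 1
    }
  }
  SliceImage(out, g@pixelSizeUm, 0L)
}
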