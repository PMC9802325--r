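#' @include AllClasses.R graph.R
NULL

asSimpleGraph <- function(g) {
  if (is(g, "SimpleGraph")) return(g)
  if (is(g, "TrabecularGraph")) return(simplifyGraph(g))
  stop("expected a TrabecularGraph or SimpleGraph")
}

#' Reduce a multigraph to a simple undirected graph
#'
#' Drops self-loops and collapses parallel edges; the vertex set is
#' unchanged.  The clustering and path-length formulas assume a simple
#' undirected graph, so metric computations operate on this reduction.
#'
#' @param g a [TrabecularGraph-class].
#' @return a [SimpleGraph-class].
#' @export
simplifyGraph <- function(g) {
  stopifnot(is(g, "TrabecularGraph"))
  nv <- nrow(g@vertices)
  e <- g@edges
  if (nrow(e) == 0) return(SimpleGraph(nv, matrix(integer(0), ncol = 2)))
  u <- pmin(e$from, e$to); v <- pmax(e$from, e$to)
  keep <- u != v
  pairs <- unique(cbind(u[keep], v[keep]))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  SimpleGraph(nv, pairs)
}

# adjacency list (sorted integer neighbour vectors) of a SimpleGraph
adjacencyList <- function(sg) {
  adj <- vector("list", sg@nVertices)
  for (i in seq_len(sg@nVertices)) adj[[i]] <- integer(0)
  e <- sg@edges
  if (nrow(e) > 0) {
    ends <- c(e[, 1], e[, 2])
    other <- c(e[, 2], e[, 1])
    sp <- split(other, factor(ends, levels = seq_len(sg@nVertices)))
    adj <- lapply(sp, function(x) sort(as.integer(x)))
  }
  adj
}

# per-vertex clustering coefficients by triangle counting:
# an edge (u, v) contributes one triangle to every common neighbour w,
# and E_w (edges among w's neighbours) equals the triangles through w.
localClustering <- function(sg) {
  adj <- adjacencyList(sg)
  k <- lengths(adj)
  tri <- numeric(sg@nVertices)
  e <- sg@edges
  for (i in seq_len(nrow(e))) {
    common <- intersect(adj[[e[i, 1]]], adj[[e[i, 2]]])
    if (length(common)) tri[common] <- tri[common] + 1
  }
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

#' Clustering coefficient of one vertex
#'
#' `C_i = 2 E_i / (k_i (k_i - 1))` where `k_i` is the degree of vertex `i`
#' and `E_i` the number of edges among its neighbours (out of the possible
#' `E_max = k_i (k_i - 1) / 2`).  Vertices with fewer than two neighbours
#' have `C_i = 0` by convention.
#'
#' @param g a [TrabecularGraph-class] or [SimpleGraph-class].
#' @param vertex vertex id.
#' @return clustering coefficient in \[0, 1\].
#' @export
clusteringCoefficient <- function(g, vertex) {
  sg <- asSimpleGraph(g)
  if (vertex < 1 || vertex > sg@nVertices) stop("no such vertex: ", vertex)
  unname(localClustering(sg)[vertex])
}

#' Mean clustering coefficient
#'
#' Arithmetic mean of the per-vertex clustering coefficients over all
#' vertices; vertices of degree < 2 contribute 0 (endpoint-heavy trabecular
#' graphs would otherwise leave the mean undefined).  Set
#' `excludeLowDegree = TRUE` to average only over vertices with `k_i >= 2`.
#'
#' @param g a [TrabecularGraph-class] or [SimpleGraph-class].
#' @param excludeLowDegree drop `k_i < 2` vertices from the mean.
#' @return mean clustering coefficient, or NA (with a warning) for an empty
#'   graph.
#' @export
meanClustering <- function(g, excludeLowDegree = FALSE) {
  sg <- asSimpleGraph(g)
  if (sg@nVertices == 0) {
    warning("mean clustering undefined for an empty graph")
    return(NA_real_)
  }
  ci <- localClustering(sg)
  if (excludeLowDegree) {
    k <- lengths(adjacencyList(sg))
    ci <- ci[k >= 2]
    if (length(ci) == 0) {
      warning("no vertices with degree >= 2")
      return(NA_real_)
    }
  }
  mean(ci)
}

# component membership of a SimpleGraph
sgComponents <- function(sg) {
  if (sg@nVertices == 0) return(integer(0))
  unionFindComponents(sg@nVertices, sg@edges[, 1], sg@edges[, 2])
}

#' Characteristic path length
#'
#' Mean shortest-path distance, in edges, over all pairs of distinct
#' vertices of the largest connected component (breadth-first search;
#' distances are unweighted edge counts).  Restricting to the largest
#' component keeps the mean finite on the disconnected graphs that
#' fragmented trabecular networks produce; `perComponent = TRUE` instead
#' returns the size-weighted average over all components with >= 2 vertices.
#'
#' @param g a [TrabecularGraph-class] or [SimpleGraph-class].
#' @param perComponent average over all components, weighted by pair count.
#' @return mean shortest-path length (>= 1), or NA (with a warning) when no
#'   two vertices are connected.
#' @export
charPathLength <- function(g, perComponent = FALSE) {
  sg <- asSimpleGraph(g)
  if (sg@nVertices < 2 || nrow(sg@edges) == 0) {
    warning("characteristic path length undefined: no connected pairs")
    return(NA_real_)
  }
  comp <- sgComponents(sg)
  pickStats <- function(vids) {
    idx <- match(seq_len(sg@nVertices), vids)
    e <- sg@edges
    keep <- e[, 1] %in% vids
    u <- idx[e[keep, 1]]; v <- idx[e[keep, 2]]
    n <- length(vids)
    deg <- tabulate(c(u, v), n)
    ptr <- c(0L, cumsum(deg))
    adj <- integer(2 * length(u))
    pos <- ptr[seq_len(n)]
    for (i in seq_along(u)) {
      pos[u[i]] <- pos[u[i]] + 1L; adj[pos[u[i]]] <- v[i] - 1L
      pos[v[i]] <- pos[v[i]] + 1L; adj[pos[v[i]]] <- u[i] - 1L
    }
    bfs_pair_stats_cpp(n, adj, ptr)
  }
  if (perComponent) {
    tot <- c(0, 0)
    for (cid in unique(comp)) {
      vids <- which(comp == cid)
      if (length(vids) >= 2) tot <- tot + pickStats(vids)
    }
    if (tot[2] == 0) {
      warning("characteristic path length undefined: no connected pairs")
      return(NA_real_)
    }
    return(tot[1] / tot[2])
  }
  sizes <- table(comp)
  cands <- as.integer(names(sizes)[sizes == max(sizes)])
  big <- comp[min(which(comp %in% cands))]   # tie: earliest-vertex component
  st <- pickStats(which(comp == big))
  if (st[2] == 0) {
    warning("characteristic path length undefined: no connected pairs")
    return(NA_real_)
  }
  st[1] / st[2]
}

#' Number of connected components
#'
#' Components of the vertex set under the (multi)edge list; isolated
#' vertices each count as one component; the empty graph has zero.
#'
#' @param g a [TrabecularGraph-class] or [SimpleGraph-class].
#' @return component count.
#' @export
countComponents <- function(g) {
  if (is(g, "TrabecularGraph")) {
    nv <- nrow(g@vertices)
    if (nv == 0) return(0L)
    comp <- unionFindComponents(nv, match(g@edges$from, g@vertices$id),
                                match(g@edges$to, g@vertices$id))
    return(length(unique(comp)))
  }
  sg <- asSimpleGraph(g)
  if (sg@nVertices == 0) return(0L)
  length(unique(sgComponents(sg)))
}

#' Edge-length statistics
#'
#' Mean, sample standard deviation and histogram of the physical edge
#' lengths (micrometers) over all multigraph edges, loops included.
#'
#' @param g a [TrabecularGraph-class].
#' @param breaks passed to [graphics::hist()].
#' @return list with `meanUm`, `sdUm`, `histogram` (a histogram object), or
#'   NA fields (with a warning) when the graph has no edges.
#' @export
edgeLengthStats <- function(g, breaks = "Sturges") {
  stopifnot(is(g, "TrabecularGraph"))
  len <- g@edges$lengthUm
  if (length(len) == 0) {
    warning("edge-length statistics undefined: no edges")
    return(list(meanUm = NA_real_, sdUm = NA_real_, histogram = NULL))
  }
  list(meanUm = mean(len), sdUm = if (length(len) > 1) sd(len) else 0,
       histogram = graphics::hist(len, breaks = breaks, plot = FALSE))
}

# uniformly random simple graph with exactly n vertices and m edges (G(N, E))
sampleGnm <- function(n, m) {
  total <- choose(n, 2)
  idx <- sort(sample(total, m))
  cum <- cumsum(seq(n - 1, 1))
  i <- findInterval(idx - 0.5, cum) + 1L
  j <- idx - c(0, cum)[i] + i
  SimpleGraph(n, cbind(i, j))
}

#' Metrics of an equivalent random network
#'
#' Samples uniform random simple graphs with matched vertex and edge counts
#' (the G(N, E) model) and returns the means of the mean clustering
#' coefficient and of the characteristic path length (largest component)
#' across samples.  Deterministic under `seed`.
#'
#' @param nVertices,nEdges counts of the graph to match;
#'   `nEdges <= nVertices (nVertices - 1) / 2`.
#' @param nSamples number of reference samples (>= 1).
#' @param seed integer seed.
#' @return named numeric vector `c(cRand, lRand)`.
#' @export
randomReference <- function(nVertices, nEdges, nSamples = 20L, seed = 1L) {
  if (nVertices < 2) stop("need at least 2 vertices")
  if (nSamples < 1) stop("nSamples must be >= 1")
  if (nEdges > choose(nVertices, 2))
    stop("infeasible edge count for a simple graph")
  withSeed(seed, {
    cs <- numeric(nSamples); ls <- numeric(nSamples)
    for (s in seq_len(nSamples)) {
      sg <- sampleGnm(nVertices, nEdges)
      cs[s] <- meanClustering(sg)
      ls[s] <- suppressWarnings(charPathLength(sg))
    }
    c(cRand = mean(cs), lRand = mean(ls, na.rm = TRUE))
  })
}

#' Small-worldness index
#'
#' `sigma = (C / C_r) / (L / L_r)`: the clustering coefficient and
#' characteristic path length of the graph relative to an equivalent random
#' network with matched vertex and edge counts (see [randomReference()]).
#' A small-world network has high clustering and short path length, giving
#' `sigma > 1`.
#'
#' @param g a [TrabecularGraph-class] or [SimpleGraph-class].
#' @param nSamples random reference samples.
#' @param seed integer seed for the reference ensemble.
#' @return sigma, or NA (with a warning) when any ingredient is undefined
#'   (e.g. `C_r = 0` or a disconnected, edgeless graph).
#' @export
smallWorldness <- function(g, nSamples = 20L, seed = 1L) {
  sw <- smallWorldStats(g, nSamples, seed)
  sw[["sigma"]]
}

smallWorldStats <- function(g, nSamples = 20L, seed = 1L) {
  sg <- asSimpleGraph(g)
  C <- suppressWarnings(meanClustering(sg))
  L <- suppressWarnings(charPathLength(sg))
  if (is.na(C) || is.na(L)) {
    warning("small-worldness undefined: C or L undefined")
    return(list(C = C, L = L, cRand = NA_real_, lRand = NA_real_,
                sigma = NA_real_))
  }
  ref <- randomReference(sg@nVertices, nrow(sg@edges), nSamples, seed)
  sigma <- if (ref[["cRand"]] <= 0 || !is.finite(ref[["lRand"]]) ||
               ref[["lRand"]] <= 0 || L <= 0) {
    warning("small-worldness undefined: degenerate random reference")
    NA_real_
  } else (C / ref[["cRand"]]) / (L / ref[["lRand"]])
  list(C = C, L = L, cRand = ref[["cRand"]], lRand = ref[["lRand"]],
       sigma = sigma)
}

#' Compute the full per-slice metrics record
#'
#' Populates every per-network statistic: vertex/junction/endpoint/edge/
#' component counts, mean clustering, characteristic path length, edge-length
#' mean and SD, and small-worldness with its random-reference ingredients.
#' Undefined quantities are NA, never silently zero.
#'
#' @param g a [TrabecularGraph-class].
#' @param depthIndex 0-based depth index recorded with the row.
#' @param seed seed for the random reference ensemble.
#' @param nSamples random reference samples.
#' @return a one-row data.frame.
#' @export
computeAllMetrics <- function(g, depthIndex = 0L, seed = 1L,
                              nSamples = 20L) {
  stopifnot(is(g, "TrabecularGraph"))
  nv <- nrow(g@vertices)
  base <- data.frame(
    depthIndex = as.integer(depthIndex),
    nVertices = nv,
    nJunctions = sum(g@vertices$kind == "junction"),
    nEndpoints = sum(g@vertices$kind == "endpoint"),
    nEdges = nrow(g@edges),
    nComponents = countComponents(g))
  if (nv == 0) {
    return(cbind(base, data.frame(
      meanClustering = NA_real_, charPathLength = NA_real_,
      meanEdgeLengthUm = NA_real_, sdEdgeLengthUm = NA_real_,
      cRand = NA_real_, lRand = NA_real_, sigma = NA_real_)))
  }
  els <- suppressWarnings(edgeLengthStats(g))
  sw <- suppressWarnings(smallWorldStats(g, nSamples, seed))
  cbind(base, data.frame(
    meanClustering = sw$C, charPathLength = sw$L,
    meanEdgeLengthUm = els$meanUm, sdEdgeLengthUm = els$sdUm,
    cRand = sw$cRand, lRand = sw$lRand, sigma = sw$sigma))
}
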