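# Independent brute-force oracles, deliberately written without reusing any
# package internals: Floyd-Warshall all-pairs distances, neighbour-pair
# clustering enumeration, and a tiny random-graph generator for
# property-style tests.

# adjacency matrix of a SimpleGraph-like edge list
oracleAdjMatrix <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges) > 0) {
    A[edges] <- TRUE
    A[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  A
}

# Floyd-Warshall shortest paths on an unweighted graph
oracleDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  D
}

# mean distance over finite pairs within the largest component
oracleCharPathLength <- function(n, edges) {
  A <- oracleAdjMatrix(n, edges)
  D <- oracleDistances(A)
  comp <- oracleComponents(A)
  sizes <- table(comp)
  # tie-break: the component containing the smallest vertex index (labels
  # are assigned in scan order, so that is the smallest label)
  big <- min(as.integer(names(sizes)[sizes == max(sizes)]))
  idx <- which(comp == big)
  if (length(idx) < 2) return(NA_real_)
  d <- D[idx, idx]
  vals <- d[upper.tri(d)]
  mean(vals)
}

# per-vertex clustering by exhaustive neighbour-pair enumeration
oracleClustering <- function(n, edges) {
  A <- oracleAdjMatrix(n, edges)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    cnt <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]]) cnt <- cnt + 1
    2 * cnt / (k * (k - 1))
  }, numeric(1))
}

# components by repeated matrix reachability
oracleComponents <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1L
    reach <- rep(FALSE, n)
    reach[s] <- TRUE
    repeat {
      new <- reach | apply(A[, reach, drop = FALSE], 1, any)
      if (all(new == reach)) break
      reach <- new
    }
    comp[reach & comp == 0] <- cur
  }
  comp
}

# random simple graph on n vertices with edge probability p
oracleRandomGraph <- function(n, p) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

# ring lattice: n vertices, each joined to k/2 neighbours on each side
ringLattice <- function(n, k) {
  edges <- NULL
  for (d in seq_len(k / 2))
    edges <- rbind(edges, cbind(seq_len(n),
                                ((seq_len(n) - 1 + d) %% n) + 1))
  edges <- t(apply(edges, 1, sort))
  SimpleGraph(n, unique(edges))
}
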