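# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# 8-connected Bresenham line between integer pixels (row, col), inclusive.
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  n <- max(dr, dc) + 1L
  rows <- integer(n); cols <- integer(n)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    rows[i] <- r; cols[i] <- c
    if (r == r1 && c == c1) { rows <- rows[seq_len(i)]; cols <- cols[seq_len(i)]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 <  dc) { err <- err + dc; r <- r + sr }
  }
  cbind(row = rows, col = cols)
}

# Liang-Barsky clipping of segment (p0, p1) (numeric xy pairs) to
# [lo, hi] x [lo, hi].  Returns NULL when fully outside, else 2x2 matrix.
clipSegment <- function(p0, p1, lo, hi) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    for (side in 1:2) {
      if (side == 1) { p <- -d[k]; q <- p0[k] - lo } else { p <- d[k]; q <- hi - p0[k] }
      if (p == 0) {
        if (q < 0) return(NULL)
      } else {
        r <- q / p
        if (p < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
        else       { if (r < t0) return(NULL); if (r < t1) t1 <- r }
      }
    }
  }
  rbind(p0 + t0 * d, p0 + t1 * d)
}

# chamfer path length in pixels: steps of 1 (lateral) and sqrt(2) (diagonal)
chamferLength <- function(path) {
  if (nrow(path) < 2) return(0)
  dr <- abs(diff(path[, 1])); dc <- abs(diff(path[, 2]))
  sum(ifelse(dr + dc == 2, sqrt(2), 1))
}

# union-find component membership for an edge list on vertices 1..n
unionFindComponents <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
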