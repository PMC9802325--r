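mkGraph <- function(n, edges) SimpleGraph(n, edges)
K3 <- mkGraph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
K4 <- mkGraph(4, t(combn(4, 2)))
P3 <- mkGraph(3, rbind(c(1, 2), c(2, 3)))
hub4 <- mkGraph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3)))

test_that("multigraph simplification drops loops and collapses parallels", {
  mkTrab <- function(edges) {
    ids <- sort(unique(as.vector(edges)))
    new("TrabecularGraph",
        vertices = data.frame(id = ids, row = ids, col = ids,
                              kind = "junction"),
        edges = data.frame(id = seq_len(nrow(edges)), from = edges[, 1],
                           to = edges[, 2], lengthUm = 10,
                           nPathPixels = 2L),
        paths = rep(list(cbind(1:2, 1:2)), nrow(edges)),
        pixelSizeUm = 20.5, imageDim = c(10L, 10L))
  }
  loop <- mkTrab(rbind(c(1, 1)))
  sg <- simplifyGraph(loop)
  expect_equal(nVertices(sg), 1L); expect_equal(nEdges(sg), 0L)
  par3 <- mkTrab(rbind(c(1, 2), c(2, 1), c(1, 2)))
  expect_equal(nEdges(simplifyGraph(par3)), 1L)
  mixed <- mkTrab(rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 3), c(4, 5),
                        c(1, 5)))
  expect_equal(nEdges(simplifyGraph(mixed)), 4L)  # distinct unordered pairs
})

test_that("clustering coefficients match the closed forms", {
  expect_equal(clusteringCoefficient(K3, 1), 1)
  expect_equal(clusteringCoefficient(P3, 2), 0)
  expect_equal(clusteringCoefficient(hub4, 1), 1 / 3)
  expect_error(clusteringCoefficient(K3, 9), "vertex")
  expect_equal(meanClustering(K3), 1)
  star <- mkGraph(5, cbind(1, 2:5))
  expect_equal(meanClustering(star), 0)
  expect_equal(meanClustering(hub4), (1 / 3 + 1 + 1 + 0) / 4)
  expect_warning(mc <- meanClustering(mkGraph(0, matrix(0, 0, 2))), "empty")
  expect_true(is.na(mc))
})

test_that("characteristic path length matches forced values and flags the undefined", {
  expect_equal(charPathLength(K3), 1)
  expect_equal(charPathLength(P3), 4 / 3)
  edgeless <- mkGraph(4, matrix(integer(0), ncol = 2))
  expect_warning(L <- charPathLength(edgeless), "undefined")
  expect_true(is.na(L))
})

test_that("metric implementations agree with brute-force and igraph oracles", {
  skip_if_not_installed("igraph")
  set.seed(101)
  maxErrC <- 0; maxErrL <- 0
  for (i in 1:60) {
    n <- sample(4:15, 1)
    edges <- oracleRandomGraph(n, runif(1, 0.15, 0.6))
    sg <- mkGraph(n, edges)
    cOracle <- mean(oracleClustering(n, edges))
    lOracle <- oracleCharPathLength(n, edges)
    cImpl <- meanClustering(sg)
    lImpl <- suppressWarnings(charPathLength(sg))
    maxErrC <- max(maxErrC, abs(cImpl - cOracle))
    if (!is.na(lOracle))
      maxErrL <- max(maxErrL, abs(lImpl - lOracle))
    # independent second oracle: igraph
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    ciIg <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    ciIg[igraph::degree(ig) < 2] <- 0
    expect_equal(cImpl, mean(ciIg), tolerance = 1e-12)
    expect_equal(countComponents(sg), igraph::count_components(ig))
  }
  expect_lt(maxErrC, 1e-12)
  expect_lt(maxErrL, 1e-12)
})

test_that("component counting handles empty, disjoint and random graphs", {
  expect_equal(countComponents(mkGraph(0, matrix(0, 0, 2))), 0L)
  twoTri <- mkGraph(6, rbind(c(1, 2), c(1, 3), c(2, 3),
                             c(4, 5), c(4, 6), c(5, 6)))
  expect_equal(countComponents(twoTri), 2L)
  set.seed(7)
  for (i in 1:10) {
    edges <- oracleRandomGraph(30, 0.04)
    sg <- mkGraph(30, edges)
    A <- oracleAdjMatrix(30, edges)
    expect_equal(countComponents(sg), max(oracleComponents(A)))
  }
})

test_that("edge-length statistics follow the hand formulas and scale linearly", {
  mk <- function(lens, px = 20.5) {
    ne <- length(lens)
    new("TrabecularGraph",
        vertices = data.frame(id = 1:2, row = 1:2, col = 1:2,
                              kind = "endpoint"),
        edges = data.frame(id = seq_len(ne), from = rep(1L, ne),
                           to = rep(2L, ne), lengthUm = lens,
                           nPathPixels = rep(2L, ne)),
        paths = rep(list(cbind(1:2, 1:2)), ne),
        pixelSizeUm = px, imageDim = c(5L, 5L))
  }
  s1 <- edgeLengthStats(mk(205))
  expect_equal(s1$meanUm, 205); expect_equal(s1$sdUm, 0)
  s2 <- edgeLengthStats(mk(c(100, 300)))
  expect_equal(s2$meanUm, 200)
  expect_equal(s2$sdUm, sd(c(100, 300)))
  expect_warning(s0 <- edgeLengthStats(mk(numeric(0))), "no edges")
  expect_true(is.na(s0$meanUm))
})

test_that("the G(N,E) reference is exact on forced graphs and deterministic", {
  r3 <- randomReference(3, 3, nSamples = 5, seed = 1)
  expect_equal(unname(r3), c(1, 1))            # only K3 exists
  r4 <- randomReference(4, 6, nSamples = 5, seed = 1)
  expect_equal(unname(r4), c(1, 1))            # only K4 exists
  expect_identical(randomReference(20, 40, 10, seed = 9),
                   randomReference(20, 40, 10, seed = 9))
  expect_error(randomReference(4, 7, 5, 1), "infeasible")
})

test_that("the sampled reference mean matches a large independent resample", {
  set.seed(33)
  ref <- randomReference(20, 40, nSamples = 200, seed = 5)
  # independent oracle: direct resampling with fresh RNG
  cs <- replicate(2000, {
    pairs <- t(combn(20, 2))
    pick <- pairs[sample(nrow(pairs), 40), , drop = FALSE]
    mean(oracleClustering(20, pick))
  })
  se <- sd(cs) / sqrt(200)
  expect_lt(abs(ref[["cRand"]] - mean(cs)), 3 * se + 1e-9)
})

test_that("small-worldness is 1 on complete graphs and exceeds 1 on ring lattices", {
  expect_equal(smallWorldness(K4, nSamples = 5, seed = 1), 1)
  ring <- ringLattice(20, 4)
  expect_gt(smallWorldness(ring, nSamples = 30, seed = 2), 1)
})

test_that("the full metrics record is consistent with individual metrics", {
  emptyG <- new("TrabecularGraph",
                vertices = data.frame(id = integer(0), row = numeric(0),
                                      col = numeric(0), kind = character(0)),
                edges = data.frame(id = integer(0), from = integer(0),
                                   to = integer(0), lengthUm = numeric(0),
                                   nPathPixels = integer(0)),
                paths = list(), pixelSizeUm = 20.5, imageDim = c(8L, 8L))
  m0 <- computeAllMetrics(emptyG)
  expect_equal(m0$nVertices, 0L)
  expect_true(is.na(m0$meanClustering) && is.na(m0$charPathLength))

  spec <- PhantomSpec(imageSize = 128L, seedPoints = 14L,
                      strutThicknessPx = 2L, fragmentationProb = 0.1,
                      noiseSigma = 0, rngSeed = 19L)
  g <- extractNetwork(generateSlice(spec, 0)$image,
                      list(minObjectPx = 0L, minHolePx = 0L))
  m <- computeAllMetrics(g, depthIndex = 3L, seed = 4L, nSamples = 10L)
  expect_equal(m$nVertices, nVertices(g))
  expect_equal(m$nEdges, nEdges(g))
  expect_equal(m$nComponents, countComponents(g))
  expect_equal(m$meanClustering, meanClustering(g))
  expect_equal(m$charPathLength, suppressWarnings(charPathLength(g)))
  expect_equal(m$meanEdgeLengthUm, edgeLengthStats(g)$meanUm)
  sw <- trabnet:::smallWorldStats(g, 10L, 4L)
  expect_equal(m$sigma, sw$sigma)
  expect_gte(m$meanClustering, 0); expect_lte(m$meanClustering, 1)
  expect_gte(m$charPathLength, 1)
})

test_that("HOA-like phantoms fragment more and have shorter edges than control-like", {
  # group means over 10 seeded samples per regime at the preset conditions
  ctrlM <- list(); hoaM <- list()
  for (i in 1:10) {
    gc <- extractNetwork(
      generateSlice(phantomPreset("control", rngSeed = 300L + i), 0)$image)
    gh <- extractNetwork(
      generateSlice(phantomPreset("hoa", rngSeed = 400L + i), 0)$image)
    ctrlM[[i]] <- c(countComponents(gc), edgeLengthStats(gc)$meanUm)
    hoaM[[i]] <- c(countComponents(gh), edgeLengthStats(gh)$meanUm)
  }
  ctrlM <- do.call(rbind, ctrlM); hoaM <- do.call(rbind, hoaM)
  expect_gt(mean(hoaM[, 1]), mean(ctrlM[, 1]))   # more graph components
  expect_lt(mean(hoaM[, 2]), mean(ctrlM[, 2]))   # shorter edges
})
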