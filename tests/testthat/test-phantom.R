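test_that("phantom spec validation rejects out-of-range parameters", {
  expect_error(PhantomSpec(fragmentationProb = 1.5), "fragmentationProb")
  expect_error(PhantomSpec(strutThicknessPx = 0L), "strutThicknessPx")
  expect_error(PhantomSpec(seedPoints = 3L), "seedPoints")
  expect_error(generateSlice(PhantomSpec(nSlices = 2L), 2), "sliceIndex")
})

test_that("identical specs regenerate bit-identical slices and ground truth", {
  spec <- PhantomSpec(imageSize = 96L, seedPoints = 12L, noiseSigma = 0.1,
                      rngSeed = 42L)
  a <- generateSlice(spec, 0)
  b <- generateSlice(spec, 0)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$groundTruth@edges, b$groundTruth@edges)
  expect_identical(a$groundTruth@vertices, b$groundTruth@vertices)
})

test_that("full fragmentation leaves pure noise and an empty ground truth", {
  spec <- PhantomSpec(imageSize = 64L, seedPoints = 10L,
                      fragmentationProb = 1, noiseSigma = 0.05, rngSeed = 5L)
  out <- generateSlice(spec, 0)
  expect_equal(nEdges(out$groundTruth), 0L)
  expect_equal(out$groundTruth@nComponents, 0L)
  # nothing but clipped Gaussian noise: no pixel reaches bone intensity
  expect_lt(max(pixels(out$image)), 0.5)
})

test_that("noiseless thin-strut slice equals the rasterized ridge set", {
  spec <- PhantomSpec(imageSize = 64L, seedPoints = 4L,
                      strutThicknessPx = 1L, anisotropy = 1,
                      fragmentationProb = 0, noiseSigma = 0, rngSeed = 1L)
  seeds <- cbind(c(16, 16, 48, 48), c(16, 48, 16, 48))
  out <- generateSlice(spec, 0, seedCoords = seeds)
  raster <- matrix(0, 64, 64)
  for (p in out$groundTruth@paths) raster[p] <- 1
  expect_identical(pixels(out$image), raster)
})

test_that("ground-truth edge count equals seeded Bernoulli survivors of the ridge set", {
  spec <- PhantomSpec(imageSize = 256L, seedPoints = 50L,
                      fragmentationProb = 0.2, noiseSigma = 0, rngSeed = 7L)
  out <- generateSlice(spec, 0)
  lat <- trabnet:::phantomLattice(spec, 0)
  # independent re-draw of the same seeded Bernoulli mask
  par <- trabnet:::sliceParams(spec, 0)
  redraw <- trabnet:::withSeed(7L, {
    runif(2 * par$seedPoints)               # seed coordinates come first
    runif(nrow(lat$ridges)) >= 0.2
  })
  expect_identical(lat$keep, redraw)
  nSurvivingInFrame <- sum(!vapply(lat$segments, is.null, logical(1)))
  # edges collapsing to one pixel after rounding are dropped on top
  expect_lte(nEdges(out$groundTruth), nSurvivingInFrame)
  expect_gte(nEdges(out$groundTruth), nSurvivingInFrame - 3)
})

test_that("ground-truth component count matches graph traversal on random specs", {
  skip_if_not_installed("igraph")
  for (seed in 1:15) {
    spec <- PhantomSpec(imageSize = 128L, seedPoints = 15L,
                        fragmentationProb = 0.35, noiseSigma = 0,
                        rngSeed = seed)
    gt <- generateSlice(spec, 0)$groundTruth
    if (nrow(gt@vertices) == 0) next
    ig <- igraph::graph_from_edgelist(
      as.matrix(gt@edges[, c("from", "to")]), directed = FALSE)
    ig <- igraph::add_vertices(ig,
                               max(0, nrow(gt@vertices) - igraph::vcount(ig)))
    expect_equal(gt@nComponents, igraph::count_components(ig),
                 info = paste("seed", seed))
  }
})

test_that("a stack equals its per-slice regenerations and honors the depth profile", {
  spec1 <- PhantomSpec(imageSize = 96L, seedPoints = 12L, nSlices = 1L,
                       noiseSigma = 0.05, rngSeed = 9L)
  st <- generateStack(spec1)
  expect_length(st, 1)
  expect_identical(pixels(st[[1]]$image),
                   pixels(generateSlice(spec1, 0)$image))

  thickening <- function(sliceIndex, nSlices)
    c(seedPoints = 1, strutThicknessPx = 1 + sliceIndex,
      fragmentationProb = 1)
  spec2 <- PhantomSpec(imageSize = 96L, seedPoints = 12L, nSlices = 2L,
                       strutThicknessPx = 2L, fragmentationProb = 0,
                       noiseSigma = 0, depthProfile = thickening,
                       rngSeed = 3L)
  st2 <- generateStack(spec2)
  expect_gt(sum(pixels(st2[[2]]$image)), sum(pixels(st2[[1]]$image)))

  expect_identical(lapply(generateStack(spec2), function(s) pixels(s$image)),
                   lapply(generateStack(spec2), function(s) pixels(s$image)))
})

test_that("bone pixel count is nondecreasing in strut thickness (noiseless)", {
  counts <- vapply(1:4, function(t) {
    spec <- PhantomSpec(imageSize = 96L, seedPoints = 12L,
                        strutThicknessPx = t, fragmentationProb = 0,
                        noiseSigma = 0, rngSeed = 21L)
    sum(pixels(generateSlice(spec, 0)$image))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("cohorts are balanced, reproducible, and show the intended contrast", {
  ctrl <- PhantomSpec(imageSize = 96L, seedPoints = 12L,
                      strutThicknessPx = 2L, fragmentationProb = 0,
                      noiseSigma = 0, rngSeed = 50L)
  hoa <- PhantomSpec(imageSize = 96L, seedPoints = 12L,
                     strutThicknessPx = 5L, fragmentationProb = 0.3,
                     noiseSigma = 0, rngSeed = 60L)
  co <- makeCohort(ctrl, hoa, 5L)
  expect_length(co$images, 10)
  expect_equal(as.vector(table(co$labels)), c(5, 5))
  frac <- vapply(co$images, function(im) mean(pixels(im)), numeric(1))
  expect_gt(mean(frac[co$labels == "HOA"]), mean(frac[co$labels == "CTRL"]))
  co2 <- makeCohort(ctrl, hoa, 5L)
  expect_identical(lapply(co$images, pixels), lapply(co2$images, pixels))
})
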