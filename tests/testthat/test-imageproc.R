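test_that("slices read back with bit-depth scaling and luminance conversion", {
  d <- withr_like_tempdir <- tempfile("slices"); dir.create(d)
  p8 <- file.path(d, "c255.png")
  png::writePNG(matrix(1, 8, 8), p8)                 # 8-bit constant 255
  img <- readSlice(p8, pixelSizeUm = 20.5)
  expect_true(all(pixels(img) == 1))
  expect_equal(pixelSize(img), 20.5)

  p16 <- file.path(d, "c0.tif")
  tiff::writeTIFF(matrix(0, 8, 8), p16, bits.per.sample = 16L)
  expect_true(all(pixels(readSlice(p16)) == 0))

  prgb <- file.path(d, "rgb.png")
  png::writePNG(array(128 / 255, dim = c(8, 8, 3)), prgb)
  expect_equal(pixels(readSlice(prgb)),
               matrix(128 / 255, 8, 8), tolerance = 1e-6)

  expect_error(readSlice(file.path(d, "missing.png")), "missing.png")
  bad <- file.path(d, "bad.tif")
  writeLines("not a tiff", bad)
  expect_error(readSlice(bad), "bad.tif")
})

test_that("contrast stretch maps extreme percentiles to 0/1 and is idempotent", {
  m <- matrix(c(0.2, 0.8), 4, 4)
  img <- SliceImage(m)
  out <- adjustIntensity(img, 0, 100)
  expect_setequal(unique(as.vector(pixels(out))), c(0, 1))
  twice <- adjustIntensity(out, 0, 100)
  expect_equal(pixels(twice), pixels(out))
  const <- SliceImage(matrix(0.4, 4, 4))
  expect_warning(res <- adjustIntensity(const), "constant")
  expect_equal(pixels(res), pixels(const))
  expect_error(adjustIntensity(img, 50, 10), "lowPct")
})

test_that("region-of-interest masking matches direct rasterization", {
  img <- SliceImage(matrix(1, 64, 64))
  expect_identical(pixels(segmentROI(img, NULL)), pixels(img))
  full <- list(type = "rect", rows = c(1, 64), cols = c(1, 64))
  expect_identical(pixels(segmentROI(img, full)), pixels(img))
  disc <- list(type = "disc", center = c(32, 32), radius = 10)
  out <- segmentROI(img, disc)
  # oracle: direct disc rasterization count
  cnt <- sum(outer(1:64, 1:64, function(r, c)
    (r - 32)^2 + (c - 32)^2 <= 100))
  expect_equal(sum(pixels(out)), cnt)
  expect_error(segmentROI(img, list(type = "disc", center = c(2, 2),
                                    radius = 10)), "outside")
})

test_that("automatic threshold lands between the modes of a bimodal image", {
  expect_warning(b <- binarize(SliceImage(matrix(0.3, 8, 8))), "constant")
  expect_false(any(pixels(b)))

  m <- matrix(c(0.2, 0.8), 6, 6)
  mask <- binarize(SliceImage(m), threshold = 0.5)
  expect_identical(pixels(mask), m > 0.5)

  set.seed(4)
  vals <- pmin(pmax(c(rnorm(2000, 0.2, 0.05), rnorm(2000, 0.8, 0.05)), 0), 1)
  img <- SliceImage(matrix(vals, 40, 100))
  auto <- binarize(img)
  # oracle: exhaustive search of the between-class variance criterion
  h <- tabulate(pmin(floor(as.vector(pixels(img)) * 256) + 1, 256), 256)
  mids <- (seq_len(256) - 0.5) / 256
  bcv <- vapply(1:255, function(t) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) return(NA_real_)
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):256] * mids[(t + 1):256]) / w1
    w0 * w1 * (mu0 - mu1)^2
  }, numeric(1))
  tOracle <- mids[which.max(bcv)]
  expect_gt(tOracle, 0.35); expect_lt(tOracle, 0.65)
  # the implementation's cut agrees with the oracle's mode separation
  nAuto <- sum(pixels(auto))
  nOracle <- sum(pixels(img) > tOracle)
  expect_equal(nAuto, nOracle, tolerance = 0.02)
})

test_that("cleaning removes small objects and fills small holes by size", {
  m <- matrix(FALSE, 32, 32)
  m[2:4, 2] <- TRUE                       # 3 px speck
  m[10:14, 10:11] <- TRUE                 # 10 px
  m[20:29, 20:24] <- TRUE                 # 50 px
  mask <- BinaryMask(m)
  expect_identical(pixels(cleanMask(mask, 0L, 0L)), m)
  out <- cleanMask(mask, 5L, 0L)
  lab <- trabnet:::label_mask_cpp(pixels(out), 8L)
  expect_setequal(as.vector(table(lab[lab > 0])), c(10, 50))
  # a hole strictly inside a solid block is filled when small enough
  blk <- matrix(TRUE, 9, 9); blk[5, 5] <- FALSE
  filled <- cleanMask(BinaryMask(blk), 0L, 2L)
  expect_true(all(pixels(filled)))
  kept <- cleanMask(BinaryMask(blk), 0L, 1L)
  expect_false(pixels(kept)[5, 5])
})

test_that("thinning reduces bars and crossings to one-pixel-wide lines", {
  bar <- matrix(FALSE, 20, 30); bar[8:12, 3:28] <- TRUE
  sk <- skeletonize(BinaryMask(bar))
  skm <- pixels(sk)
  expect_true(all(which(rowSums(skm) > 0) == 10))    # single medial row
  expect_gte(sum(skm[10, ]), 20)                     # most of the length
  expect_true(all(colSums(skm) <= 1))                # one pixel wide
  expect_equal(max(trabnet:::label_mask_cpp(skm, 8L)), 1L)

  plus <- matrix(FALSE, 21, 21)
  plus[10:12, 2:20] <- TRUE; plus[2:20, 10:12] <- TRUE
  skp <- pixels(skeletonize(BinaryMask(plus)))
  nb <- trabnet:::neighbor_count_cpp(skp)
  junction <- skp & nb >= 3
  expect_gte(sum(junction), 1)
  expect_equal(max(trabnet:::label_mask_cpp(junction, 8L)), 1L)  # one cluster
  expect_equal(sum(skp & nb == 1), 4L)               # four arm tips

  empty <- skeletonize(BinaryMask(matrix(FALSE, 5, 5)))
  expect_false(any(pixels(empty)))
})

test_that("thinning preserves topology, is idempotent, and stays within the mask", {
  for (seed in 1:10) {
    spec <- PhantomSpec(imageSize = 128L, seedPoints = 15L,
                        strutThicknessPx = 3L, fragmentationProb = 0.2,
                        noiseSigma = 0, rngSeed = seed)
    m <- pixels(generateSlice(spec, 0)$image) > 0.5
    sk <- pixels(skeletonize(BinaryMask(m)))
    expect_true(all(m[sk]), info = paste("subset, seed", seed))
    expect_equal(max(trabnet:::label_mask_cpp(sk, 8L)),
                 max(trabnet:::label_mask_cpp(m, 8L)),
                 info = paste("components, seed", seed))
    expect_identical(trabnet:::thin_cpp(sk), sk,
                     info = paste("idempotence, seed", seed))
    # residual 2x2 blocks are junction clusters only
    nb <- trabnet:::neighbor_count_cpp(sk)
    blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
      sk[-nrow(sk), -1] & sk[-1, -1]
    if (any(blocks)) {
      idx <- which(blocks, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        r <- idx[k, 1]; c <- idx[k, 2]
        expect_true(all(nb[r:(r + 1), c:(c + 1)] >= 3),
                    info = paste("2x2 block at junction, seed", seed))
      }
    }
  }
})
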