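## Build a flat slide from a solid colour, optionally with painted
## regions; colours given as 0-255 RGB triples.
solidSlide <- function(h, w, rgb = c(255, 255, 255)) {
  px <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  new("SlideImage", pixels = px, micronsPerPixel = 0.25,
      levelDownsamples = 1)
}

paintRect <- function(slide, rows, cols, rgb) {
  for (ch in 1:3) slide@pixels[rows, cols, ch] <- rgb[ch]
  slide
}

magenta <- c(255, 0, 255)

test_that("segmentation finds nothing on a pure white slide", {
  mask <- segmentTissue(solidSlide(512, 512))
  expect_true(all(mask@mask == 0))
})

test_that("segmentation recovers a saturated square up to closing effects", {
  slide <- paintRect(solidSlide(512, 512), 129:384, 129:384, magenta)
  mask <- segmentTissue(slide)@mask
  ## interior well inside the square is all tissue; far outside is empty
  expect_true(all(mask[140:373, 140:373] == 1))
  expect_true(all(mask[1:118, ] == 0))
  expect_true(all(mask[, 396:512] == 0))
  ## total area close to the true square (within a closing margin)
  expect_lt(abs(sum(mask) - 256^2) / 256^2, 0.1)
})

test_that("median filtering removes isolated salt noise", {
  clean <- paintRect(solidSlide(512, 512), 129:384, 129:384, magenta)
  noisy <- clean
  set.seed(41)
  ## ~1% isolated saturated pixels outside the square
  pts <- cbind(sample(1:120, 600, TRUE), sample(1:512, 600, TRUE))
  for (i in seq_len(nrow(pts)))
    noisy@pixels[pts[i, 1], pts[i, 2], ] <- magenta
  expect_equal(segmentTissue(noisy)@mask, segmentTissue(clean)@mask)
})

test_that("segmentation rejects malformed inputs", {
  grey <- new("SlideImage",
              pixels = array(255, dim = c(64, 64, 3L)),
              levelDownsamples = 1)
  grey@pixels <- array(255, dim = c(64, 64, 3L))
  bad <- grey; dim(bad@pixels) <- c(64, 64 * 3, 1)
  expect_error(segmentTissue(bad), "RGB")
  expect_error(segmentTissue(solidSlide(5, 5), segParams(medianKernel = 7)),
               "kernel larger")
  expect_error(segParams(medianKernel = 4), "medianKernel")
})

test_that("Otsu thresholding separates a bimodal saturation histogram", {
  slide <- paintRect(solidSlide(512, 512), 1:256, 1:512, magenta)
  mask <- segmentTissue(slide, segParams(useOtsu = TRUE))@mask
  expect_gt(mean(mask[1:250, ]), 0.95)
  expect_lt(mean(mask[263:512, ]), 0.05)
})

test_that("tile grid enumerates row-major and applies the four-point rule", {
  slide <- solidSlide(512, 512, magenta)
  fullMask <- new("TissueMask", mask = matrix(1, 512, 512), downsample = 1)
  grid <- extractTileGrid(slide, fullMask)
  expect_equal(grid, rbind(c(0, 0), c(256, 0), c(0, 256), c(256, 256)),
               ignore_attr = TRUE)
  emptyMask <- new("TissueMask", mask = matrix(0, 512, 512), downsample = 1)
  expect_equal(nrow(extractTileGrid(slide, emptyMask)), 0L)
  ## left-half mask: four_pt_all keeps only the left column of tiles
  half <- matrix(0, 512, 512); half[, 1:256] <- 1
  halfMask <- new("TissueMask", mask = half, downsample = 1)
  gAll <- extractTileGrid(slide, halfMask,
                          tileSpec(validityRule = "four_pt_all"))
  expect_equal(gAll, rbind(c(0, 0), c(0, 256)), ignore_attr = TRUE)
  ## four_pt_any keeps them too (plus nothing to the right: probes at
  ## x = 320 and 448 are both outside the mask)
  gAny <- extractTileGrid(slide, halfMask)
  expect_equal(gAny, rbind(c(0, 0), c(0, 256)), ignore_attr = TRUE)
  expect_error(extractTileGrid(slide, fullMask, tileSpec(level = 1)),
               "level")
})

test_that("kept tiles always satisfy their validity rule when re-checked", {
  slide <- solidSlide(512, 512, magenta)
  set.seed(42)
  prevCount <- 0
  base <- matrix(0, 64, 64)
  cells <- sample(64 * 64)
  for (fill in c(200, 800, 2000, 4096)) {
    mk <- base; mk[cells[seq_len(fill)]] <- 1
    tm <- new("TissueMask", mask = mk, downsample = 8)
    grid <- extractTileGrid(slide, tm)
    ## monotone in mask area under four_pt_any (nested masks)
    expect_gte(nrow(grid), prevCount)
    prevCount <- nrow(grid)
    if (nrow(grid)) {
      for (i in seq_len(nrow(grid))) {
        cx <- grid[i, "x"] + 128; cy <- grid[i, "y"] + 128
        hits <- vapply(list(c(-64, -64), c(64, -64), c(-64, 64), c(64, 64)),
                       function(o) {
                         mk[floor((cy + o[2]) / 8) + 1,
                            floor((cx + o[1]) / 8) + 1] == 1
                       }, logical(1))
        expect_true(any(hits))
      }
    }
  }
})

test_that("tile preprocessing resizes, rescales and standardises in order", {
  norm <- normParams(mean = c(0.5, 0.5, 0.5), std = c(0.5, 0.5, 0.5))
  white <- array(255, dim = c(256, 256, 3))
  out <- preprocessTile(white, norm)
  expect_equal(dim(out), c(224L, 224L, 3L))
  expect_equal(out, array(1, dim = c(224, 224, 3)), tolerance = 1e-12)
  black <- array(0, dim = c(256, 256, 3))
  expect_equal(preprocessTile(black, norm),
               array(-1, dim = c(224, 224, 3)), tolerance = 1e-12)
  expect_error(preprocessTile(array(0, dim = c(128, 128, 3)), norm),
               "256 x 256")
})

test_that("bicubic resampling reproduces linear ramps in the interior", {
  ## Catmull-Rom interpolation is exact on affine signals away from the
  ## clamped borders; the mapped output positions are known in closed
  ## form, which gives an independent oracle for the resize step.
  ramp <- array(0, dim = c(256, 256, 3))
  for (ch in 1:3) ramp[, , ch] <- matrix(rep(0:255, each = 256), 256, 256)
  out <- preprocessTile(ramp, normParams(mean = c(0, 0, 0),
                                         std = c(1, 1, 1)))
  scale <- 256 / 224
  expectCol <- ((seq_len(224) - 0.5) * scale - 0.5) / 255
  interior <- 3:222
  for (ch in 1:3)
    expect_equal(out[100, interior, ch], expectCol[interior],
                 tolerance = 1e-4)
  ## affine equivariance: shifting the channel mean by m moves the
  ## output by exactly -m/std
  tile <- array(runif(256 * 256 * 3, 0, 255), dim = c(256, 256, 3))
  n1 <- normParams(mean = c(0.2, 0.2, 0.2), std = c(0.5, 0.5, 0.5))
  n2 <- normParams(mean = c(0.45, 0.45, 0.45), std = c(0.5, 0.5, 0.5))
  expect_equal(preprocessTile(tile, n1) - preprocessTile(tile, n2),
               array(0.25 / 0.5, dim = c(224, 224, 3)), tolerance = 1e-12)
})

test_that("segmentation is nearly idempotent on a binary-rendered mask", {
  slide <- paintRect(solidSlide(512, 512), 100:350, 150:400, magenta)
  m1 <- segmentTissue(slide)
  rendered <- solidSlide(512, 512)
  for (ch in 1:3) {
    pl <- rendered@pixels[, , ch]
    pl[m1@mask == 1] <- magenta[ch]
    rendered@pixels[, , ch] <- pl
  }
  m2 <- segmentTissue(rendered)
  expect_gt(mean(m1@mask == m2@mask), 0.995)
})

test_that("synthetic tissue images drive the tiling stage end to end", {
  sim <- simulateTissueImage(768, 768, nBlobs = 2, seed = 3)
  expect_s4_class(sim$slide, "SlideImage")
  expect_gt(mean(sim$mask), 0)
  ## determinism
  sim2 <- simulateTissueImage(768, 768, nBlobs = 2, seed = 3)
  expect_identical(sim$slide@pixels, sim2$slide@pixels)
  ## segmentation approximates the ground-truth mask
  mask <- segmentTissue(sim$slide)
  expect_gt(mean((mask@mask == 1) == (sim$mask == 1)), 0.97)
  ## no tissue -> no tiles
  blank <- simulateTissueImage(512, 512, nBlobs = 0, seed = 1)
  g0 <- extractTileGrid(blank$slide, segmentTissue(blank$slide))
  expect_equal(nrow(g0), 0L)
  ## kept tiles intersect the true mask
  grid <- extractTileGrid(sim$slide, mask)
  expect_gt(nrow(grid), 0L)
  for (i in seq_len(nrow(grid))) {
    tile <- sim$mask[(grid[i, "y"] + 1):(grid[i, "y"] + 256),
                     (grid[i, "x"] + 1):(grid[i, "x"] + 256)]
    expect_gt(mean(tile), 0)
  }
  ## black artifact patches never contribute tissue pixels to the mask
  art <- simulateTissueImage(768, 768, nBlobs = 2, seed = 4,
                             blackPatches = 2)
  maskA <- segmentTissue(art$slide)
  black <- apply(art$slide@pixels, c(1, 2), sum) == 0
  expect_true(all(maskA@mask[black] == 0))
})

test_that("physical tile size follows resolution times tile size", {
  slide <- solidSlide(512, 512)
  expect_equal(tileMicrons(slide), 64)
  expect_equal(tileMicrons(slide, tileSpec(tileSize = 512)), 128)
})
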