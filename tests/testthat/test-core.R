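test_that("images load normalized to [0,1] and save/load round-trips", {
  d <- withr::local_tempdir()
  p8 <- file.path(d, "white.png")
  png::writePNG(matrix(1, 4, 4), p8)       # 8-bit all-255
  expect_equal(loadImage(p8), matrix(1, 4, 4))

  t16 <- file.path(d, "zeros.tif")
  tiff::writeTIFF(matrix(0, 3, 5), t16, bits.per.sample = 16L)
  expect_equal(loadImage(t16), matrix(0, 3, 5))

  pv <- file.path(d, "val51.png")
  png::writePNG(matrix(51 / 255, 2, 2), pv)  # 8-bit value 51 -> 0.2
  expect_equal(loadImage(pv)[1, 1], 0.2)

  rgb <- file.path(d, "rgb.png")
  arr <- array(c(0.2, 0.4, 0.9), c(1, 1, 3))
  png::writePNG(arr, rgb)
  expect_equal(loadImage(rgb)[1, 1], mean(c(0.2, 0.4, 0.9)),
               tolerance = 1 / 255)

  img <- matrix(runif(600), 20, 30)
  rt <- file.path(d, "rt.tif")
  saveImage(img, rt)
  expect_lt(max(abs(loadImage(rt) - img)), 2^-16)

  expect_error(loadImage(file.path(d, "absent.tif")), "absent")
})

test_that("tiling follows the stride geometry and discards partial tiles", {
  img <- matrix(0.5, 1440, 1920)
  expect_length(tileImage(img), 9 * 12)                   # 150-px tiling
  expect_length(tileImage(img, stridePx = 50L), 26 * 36)  # scanning stride

  one <- tileImage(matrix(0.5, 150, 150))
  expect_length(one, 1L)
  expect_identical(tileOrigin(one[[1]]), c(0L, 0L))

  expect_error(tileImage(matrix(0.5, 100, 200)), "larger than image")

  # partition property: stride = tile, tiles disjoint and cover the
  # tile-aligned sub-rectangle exactly once
  img2 <- matrix(runif(310 * 470), 310, 470)
  tiles <- tileImage(img2, tilePx = 100L)
  hits <- matrix(0L, 310, 470)
  for (tl in tiles) {
    o <- tileOrigin(tl)
    hits[o[1] + 1:100, o[2] + 1:100] <- hits[o[1] + 1:100, o[2] + 1:100] + 1L
    expect_identical(imagePixels(tl), img2[o[1] + 1:100, o[2] + 1:100])
  }
  expect_true(all(hits[1:300, 1:400] == 1L))
  expect_true(all(hits[301:310, ] == 0L) && all(hits[, 401:470] == 0L))
})

test_that("physical unit conversion is round-half-up and invertible", {
  g <- PixelGeometry()
  expect_identical(umToPx(50, g), 150L)
  expect_identical(umToPx(6, g), 18L)
  expect_identical(umToPx(0, g), 0L)
  expect_error(umToPx(-1, g), "non-negative")
  expect_error(PixelGeometry(0))

  d <- seq(0, 60, by = 0.07)
  px <- umToPx(d, g)
  expect_true(all(diff(px) >= 0))                       # monotone
  expect_true(all(abs(d - pxToUm(px, g)) <= umPerPx(g) / 2 + 1e-12))
})

test_that("area rates count true pixels over tile pixels and check shape", {
  tile <- RoiTile(matrix(0.5, 150, 150))
  empty <- BinaryMask(matrix(FALSE, 150, 150), "crack")
  full <- BinaryMask(matrix(TRUE, 150, 150), "crack")
  expect_identical(crackAreaRate(empty, tile), 0)
  expect_identical(crackAreaRate(full, tile), 1)

  m <- matrix(FALSE, 150, 150); m[21:120, 31:33] <- TRUE   # 100x3 line
  expect_equal(crackAreaRate(BinaryMask(m, "crack"), tile), 300 / 22500)

  bad <- BinaryMask(matrix(FALSE, 100, 100), "diff_nuclei")
  expect_error(diffNucleiAreaRate(bad, tile), "does not match")

  # mask area is invariant under image intensity rescaling
  tile2 <- RoiTile(imagePixels(tile) * 0.5)
  mm <- BinaryMask(m, "diff_nuclei")
  expect_identical(maskArea(mm), 300L)
  expect_equal(diffNucleiAreaRate(mm, tile2), diffNucleiAreaRate(mm, tile))
})

test_that("flat key-value config files parse with overrides", {
  d <- withr::local_tempdir()
  cf <- file.path(d, "morphoqc.toml")
  writeLines(c("# comment", "geometry.um_per_px = 0.5",
               "gabor.wavelengths_px = 3, 6, 9",
               'run.name = "demo"'), cf)
  cfg <- readConfig(cf, overrides = "nucleoli.k=3.5")
  expect_equal(cfg$`geometry.um_per_px`, 0.5)
  expect_equal(cfg$`gabor.wavelengths_px`, c(3, 6, 9))
  expect_identical(cfg$`run.name`, "demo")
  expect_equal(cfg$`nucleoli.k`, 3.5)

  expect_equal(umPerPx(configGeometry(cfg)), 0.5)
  expect_equal(configNucleoliDetector(cfg)@k, 3.5)
  expect_equal(configGaborBank(cfg)@wavelengthsPx, c(3, 6, 9))
  expect_equal(configNucleiDetector(list())@sourcePercentile, 2)
  expect_error(readConfig(cf, overrides = "broken line"), "no '='")
})

test_that("domain objects validate their invariants", {
  expect_error(RoiTile(matrix(c(0.5, 1.2), 1, 2)), "\\[0, 1\\]")
  expect_error(featureVector(-1, 0, 0))
  expect_error(featureVector(2, 1.4, 0))
  expect_error(qualityFactor("excellent"), "unknown quality label")
  fv <- featureVector(8, 0.01, 0)
  expect_identical(as.data.frame(fv)$n_nucleoli, 8L)
  lv <- qualityFactor(c("good", "poor", "mod"))
  expect_true(is.ordered(lv) && lv[2] < lv[3] && lv[3] < lv[1])
})
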