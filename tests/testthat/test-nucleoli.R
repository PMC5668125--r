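test_that("dark-blob extraction finds discs, gates sizes, ignores flats", {
  expect_identical(nrow(extractDarkBlobs(RoiTile(matrix(0.5, 150, 150)))), 0L)

  # one 12-px (4-um) disc with 0.3 contrast: exactly one round candidate
  cand <- extractDarkBlobs(discTile(12))
  expect_identical(nrow(cand), 1L)
  expect_gt(cand$roundness, 0.9)
  expect_equal(cand$equiv_diam_um, 4, tolerance = 0.15)
  expect_gt(cand$contrast, 0.25)
  expect_false(cand$border)

  # a 45-px (15-um) disc exceeds the 8-um slack bound
  expect_identical(nrow(extractDarkBlobs(discTile(45))), 0L)
})

test_that("extraction is pixel-identical to a global-threshold oracle on flat tiles", {
  for (seed in 101:105) {
    g <- generateTile(flatRecipe(), "good", seed = seed)
    cand <- extractDarkBlobs(g$tile)
    got <- lapply(attr(cand, "pixels"), sort)
    want <- oracleBlobPixels(g$tile, threshold = 0.45)
    expect_identical(length(got), length(want))
    ord <- order(vapply(got, min, integer(1)))
    ordW <- order(vapply(want, min, integer(1)))
    expect_identical(got[ord], want[ordW])
  }
})

test_that("candidate pixel sets are invariant to constant intensity shifts", {
  g <- generateTile(classRecipe(lambdaNucleoli = 6), "good", seed = 321)
  base <- lapply(attr(extractDarkBlobs(g$tile), "pixels"), sort)
  shifted <- RoiTile(pmin(imagePixels(g$tile) + 0.1, 1))
  # keep the shift exactly constant: the tile must not clip at 1
  expect_lt(max(imagePixels(g$tile)), 0.9)
  after <- lapply(attr(extractDarkBlobs(shifted), "pixels"), sort)
  expect_identical(base, after)
})

test_that("blob shape features separate discs from lines", {
  # digital disc: roundness near 1, within digitization loss
  disc <- extractDarkBlobs(discTile(14))
  expect_true(disc$roundness >= 0.85 && disc$roundness <= 1)

  # 1x20-px line, admitted through a widened gate: roundness < 0.3
  img <- matrix(0.6, 150, 150); img[70, 61:80] <- 0.2
  line <- extractDarkBlobs(RoiTile(img),
                           params = nucleoliDetectorConfig(diamRangeUm = c(0.5, 20)))
  expect_identical(nrow(line), 1L)
  expect_lt(line$roundness, 0.3)
  expect_gt(line$eccentricity, 0.9)

  # area 108 px at 1/3 um/px: equivalent diameter 2*sqrt(108/pi)/3
  fake <- data.frame(equiv_diam_um = 2 * sqrt(108 / pi) / 3, roundness = 0.9,
                     mean_intensity = 0.2, contrast = 0.3, eccentricity = 0.3)
  expect_equal(unname(blobFeatureVector(fake)[1, "equiv_diam_um"]),
               3.9088, tolerance = 1e-3)

  # 1-px blob: perimeter floor of 4, no error
  img1 <- matrix(0.6, 60, 60); img1[30, 30] <- 0.05
  one <- extractDarkBlobs(RoiTile(img1),
                          params = nucleoliDetectorConfig(diamRangeUm = c(0.1, 20)))
  expect_identical(one$perimeter_px, 4)
})

test_that("blob SVM training is deterministic and separates a toy set", {
  mkDisc <- function(seed) {
    withr::with_seed(seed, {
      img <- matrix(0.6 + rnorm(729, 0, 0.01), 27, 27)
      rr <- matrix(1:27, 27, 27); cc <- t(rr)
      img[(rr - 14)^2 + (cc - 14)^2 <= 25] <- 0.25
      pmin(pmax(img, 0), 1)
    })
  }
  mkLine <- function(seed) {
    withr::with_seed(seed, {
      img <- matrix(0.6 + rnorm(729, 0, 0.01), 27, 27)
      img[14, 4:24] <- 0.25
      pmin(pmax(img, 0), 1)
    })
  }
  patches <- c(lapply(1:8, mkDisc), lapply(1:8, mkLine))
  labels <- rep(c(TRUE, FALSE), each = 8)
  params <- nucleoliDetectorConfig(diamRangeUm = c(0.5, 20))
  m <- trainBlobSvm(patches, labels, folds = 2L, seed = 5, params = params)
  feats <- t(vapply(patches, morphoqc:::.patchFeatureRow, numeric(5),
                    geom = PixelGeometry(), params = params))
  colnames(feats) <- m@featureNames
  pred <- predict(m@fit, morphoqc:::.applyScaling(feats, m@scaling))
  expect_identical(unname(pred == "pos"), labels)   # training F = 1

  m2 <- trainBlobSvm(patches, labels, folds = 2L, seed = 5, params = params)
  expect_identical(m@selected, m2@selected)
  expect_identical(m@fit$coefs, m2@fit$coefs)

  m3 <- trainBlobSvm(patches, labels, grid = list(C = 2, gamma = 0.25),
                     folds = 2L, seed = 5, params = params)
  expect_identical(unname(m3@selected), c(2, 0.25))

  expect_error(trainBlobSvm(patches, rep(TRUE, 16)), "both classes")
})

test_that("nucleolus counting matches synthetic truth and ignores brights", {
  bm <- testBlobModel()
  expect_identical(countNucleoli(RoiTile(matrix(0.5, 150, 150)), bm), 0L)

  rec <- classRecipe(lambdaNucleoli = 7, distractorLambda = 0)
  hits <- 0L
  for (seed in 11:25) {
    g <- generateTile(rec, "good", seed = seed)
    err <- abs(countNucleoli(g$tile, bm) - nrow(g$truth@nucleoli))
    hits <- hits + (err <= 1L)
  }
  expect_gte(hits, 14L)

  recD <- classRecipe(lambdaNucleoli = 7, distractorLambda = 3,
                      distractorKinds = "dead_cell")
  ok <- 0L
  for (seed in 11:20) {
    g <- generateTile(recD, "good", seed = seed)
    ok <- ok + (abs(countNucleoli(g$tile, bm) - nrow(g$truth@nucleoli)) <= 1L)
  }
  expect_gte(ok, 9L)   # bright distractors never form dark candidates
})

test_that("adding a well-separated nucleolus never decreases the count", {
  bm <- testBlobModel()
  centres <- cbind(row = c(30, 30, 75, 75, 120, 120, 30, 75),
                   col = c(30, 100, 60, 130, 30, 100, 65, 95))
  counts <- integer(nrow(centres))
  for (n in seq_len(nrow(centres))) {
    img <- matrix(0.58, 150, 150)
    rr <- matrix(1:150, 150, 150); cc <- t(rr)
    for (i in seq_len(n))
      img[(rr - centres[i, 1])^2 + (cc - centres[i, 2])^2 <= 36] <- 0.22
    counts[n] <- countNucleoli(RoiTile(img), bm)
  }
  expect_true(all(diff(counts) >= 0))
})
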