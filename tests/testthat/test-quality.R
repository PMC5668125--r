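# simulated well-separated feature clusters (no images involved):
# good = many nucleoli, mod = cracked, poor = dark nuclei
simClusters <- function(n, seed) {
  withr::with_seed(seed, {
    per <- n %/% 3
    good <- data.frame(n_nucleoli = pmax(0, round(rnorm(per, 8, 1))),
                       crack_rate = 0, diff_nuclei_rate = 0)
    mod <- data.frame(n_nucleoli = pmax(0, round(rnorm(per, 4, 1))),
                      crack_rate = pmax(0, rnorm(per, 0.15, 0.03)),
                      diff_nuclei_rate = 0)
    poor <- data.frame(n_nucleoli = pmax(0, round(rnorm(per, 2, 1))),
                       crack_rate = 0,
                       diff_nuclei_rate = pmax(0, rnorm(per, 0.10, 0.02)))
    list(x = rbind(good, mod, poor),
         y = qualityFactor(rep(c("good", "mod", "poor"), each = per)))
  })
}

test_that("grid-searched quality SVM separates well-separated clusters", {
  d <- simClusters(600, seed = 42)
  tr <- withr::with_seed(7, sample(600, 400))
  fit <- trainQualitySvm(d$x[tr, ], d$y[tr], seed = 11)
  pred <- predictQuality(d$x[-tr, ], fit)
  cm <- confusionAndMetrics(d$y[-tr], pred)
  expect_true(all(cm$metrics$f_measure >= 0.95))

  # the selected point maximizes the stored per-point CV score
  expect_equal(max(fit@cvScores$meanScore),
               fit@cvScores$meanScore[
                 fit@cvScores$C == fit@selected["C"] &
                 fit@cvScores$gamma == fit@selected["gamma"]])

  # single-point grid is selected verbatim
  one <- trainQualitySvm(d$x[tr, ], d$y[tr],
                         grid = list(C = 1, gamma = 0.1), seed = 11)
  expect_identical(unname(one@selected), c(1, 0.1))

  # a class with fewer members than folds is refused by name
  bad <- d$x[c(1:2, 201:260, 401:460), ]
  badY <- d$y[c(1:2, 201:260, 401:460)]
  expect_error(trainQualitySvm(bad, badY, seed = 1), "good")
})

test_that("training and prediction are bit-identical under a fixed seed", {
  d <- simClusters(240, seed = 9)
  probe <- simClusters(60, seed = 10)
  f1 <- trainQualitySvm(d$x, d$y, seed = 33)
  f2 <- trainQualitySvm(d$x, d$y, seed = 33)
  expect_identical(f1@selected, f2@selected)
  expect_identical(f1@fit$coefs, f2@fit$coefs)
  expect_identical(predictQuality(probe$x, f1), predictQuality(probe$x, f2))
})

test_that("one-vs-one vote ties break toward the lowest quality", {
  lev <- qualityLevels()
  # cyclic vote: poor beats mod, mod beats good, good beats poor -> all
  # tie at one vote and the lowest grade wins
  dec <- matrix(c(1, -1, 1), 1, 3,
                dimnames = list(NULL, c("poor/mod", "poor/good", "mod/good")))
  expect_identical(morphoqc:::.voteFromDecision(dec, lev), "poor")
  # another cyclic tie under a different column order, plus a clear win
  dec2 <- matrix(c(-1, -1, 1, 1, -1, -1), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, c("mod/good", "poor/mod", "poor/good")))
  # row 1: good, mod, poor one vote each -> lowest grade; row 2: mod twice
  expect_identical(morphoqc:::.voteFromDecision(dec2, lev),
                   c("poor", "mod"))

  d <- simClusters(300, seed = 5)
  fit <- trainQualitySvm(d$x, d$y, seed = 5)
  centroid <- data.frame(n_nucleoli = 8, crack_rate = 0,
                         diff_nuclei_rate = 0)
  expect_identical(as.character(predictQuality(centroid, fit)), "good")
  expect_error(predictQuality(data.frame(n_nucleoli = NA, crack_rate = 0,
                                         diff_nuclei_rate = 0), fit),
               "finite")
})

test_that("predictions are invariant under consistent feature rescaling", {
  d <- simClusters(300, seed = 21)
  fit <- trainQualitySvm(d$x, d$y, seed = 21)
  probe <- simClusters(90, seed = 22)
  base <- predictQuality(probe$x, fit)
  scaled <- fit
  scaled@scaling$mean <- fit@scaling$mean * 10
  scaled@scaling$sd <- fit@scaling$sd * 10
  expect_identical(predictQuality(probe$x * 10, scaled), base)
})

test_that("degrading a tile's features never improves its grade", {
  d <- simClusters(600, seed = 3)
  fit <- trainQualitySvm(d$x, d$y, seed = 3)
  flips <- 0L; total <- 0L
  for (i in 1:40) {
    x0 <- withr::with_seed(100 + i, data.frame(
      n_nucleoli = sample(4:9, 1), crack_rate = 0, diff_nuclei_rate = 0))
    path <- seq(0, 0.10, length.out = 6)
    labs <- vapply(path, function(r) {
      x0$diff_nuclei_rate <- r
      as.character(predictQuality(x0, fit))
    }, character(1))
    ranks <- match(labs, rev(qualityLevels()))   # good=1 .. poor=3
    total <- total + 1L
    if (any(diff(ranks) < 0)) flips <- flips + 1L
  }
  expect_lte(flips / total, 0.05)
})

test_that("tile classification and frame scanning assemble correctly", {
  bm <- testBlobModel()
  d <- simClusters(300, seed = 13)
  qm <- trainQualitySvm(d$x, d$y, seed = 13)

  blank <- classifyTile(RoiTile(matrix(0.5, 150, 150)), bm, qm)
  expect_identical(blank$features@nNucleoli, 0L)
  expect_identical(blank$features@crackRate, 0)
  expect_identical(blank$features@diffNucleiRate, 0)
  expect_s4_class(blank$features, "FeatureVector")

  g <- generateTile(defaultRecipes()$good, "good", seed = 5150)
  res <- classifyTile(g$tile, bm, qm)
  expect_identical(as.character(res$label), "good")

  expect_error(scanImage(matrix(0.5, 100, 300), bm, qm), "smaller")

  one <- scanImage(imagePixels(g$tile), bm, qm, stridePx = 50L)
  expect_identical(dim(mapLabels(one)), c(1L, 1L))

  frame <- withr::with_seed(1, matrix(runif(250 * 300, 0.4, 0.6), 250, 300))
  qmap <- scanImage(frame, bm, qm, stridePx = 50L)
  expect_identical(dim(mapLabels(qmap)),
                   c((250L - 150L) %/% 50L + 1L, (300L - 150L) %/% 50L + 1L))

  png <- withr::local_tempfile(fileext = ".png")
  writeQualityPng(qmap, png)
  expect_true(file.exists(png))
  arr <- png::readPNG(png)
  expect_identical(dim(arr)[1:2], dim(mapLabels(qmap)) * 50L)
})

test_that("models survive a save/load round trip", {
  d <- simClusters(150, seed = 55)
  fit <- trainQualitySvm(d$x, d$y, seed = 55)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(fit, f)
  back <- loadModel(f)
  probe <- simClusters(30, seed = 56)
  expect_identical(predictQuality(probe$x, back),
                   predictQuality(probe$x, fit))
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), junk)
  expect_error(loadModel(junk), "not a serialized")
})
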