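test_that("scene generation is bit-reproducible and seed-sensitive", {
  a <- generateTile(defaultRecipes()$mod, "mod", seed = 12345)
  b <- generateTile(defaultRecipes()$mod, "mod", seed = 12345)
  expect_identical(imagePixels(a$tile), imagePixels(b$tile))
  expect_identical(a$truth@nucleoli, b$truth@nucleoli)
  expect_identical(maskPixels(a$truth@masks$crack),
                   maskPixels(b$truth@masks$crack))
  c <- generateTile(defaultRecipes()$mod, "mod", seed = 12346)
  expect_false(identical(imagePixels(a$tile), imagePixels(c$tile)))
  # generation must not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generateTile(defaultRecipes()$good, "good", seed = 9))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("empty recipes yield object-free textured tiles", {
  rec <- classRecipe(lambdaNucleoli = 0, crackProb = 0, nucleiLambda = 0,
                     distractorLambda = 0)
  g <- generateTile(rec, "good", seed = 4)
  expect_identical(nrow(g$truth@nucleoli), 0L)
  expect_length(g$truth@cracks, 0)
  expect_true(all(vapply(g$truth@masks, maskArea, integer(1)) == 0L))
  expect_gt(sd(imagePixels(g$tile)), 0)   # textured, not constant
})

test_that("stored truth masks equal a re-rasterization from object lists", {
  for (seed in c(21, 22, 23)) {
    for (cls in qualityLevels()) {
      g <- generateTile(defaultRecipes()[[cls]], cls, seed = seed)
      re <- rasterizeTruth(g$truth)
      expect_identical(maskPixels(g$truth@masks$nucleoli), re$nucleoli)
      expect_identical(maskPixels(g$truth@masks$crack), re$crack)
      expect_identical(maskPixels(g$truth@masks$diff_nuclei), re$diff_nuclei)
    }
  }
})

test_that("class-conditional feature distributions keep the biological ordering", {
  n <- 150
  stats <- sapply(qualityLevels(), function(cls) {
    fv <- vapply(seq_len(n), function(i) {
      g <- generateTile(defaultRecipes()[[cls]], cls, seed = 50000 + i)
      f <- truthFeatures(g$truth)
      c(f@nNucleoli, f@crackRate, f@diffNucleiRate)
    }, numeric(3))
    rowMeans(fv)
  })
  expect_true(stats[1, "good"] > stats[1, "mod"])   # nucleoli increase
  expect_true(stats[1, "mod"] > stats[1, "poor"])   # with quality
  expect_true(stats[2, "mod"] > max(stats[2, "poor"], stats[2, "good"]))
  expect_true(stats[3, "poor"] > max(stats[3, "mod"], stats[3, "good"]))

  # Poisson nucleolus count: empirical mean near the recipe rate
  expect_lt(abs(stats[1, "good"] - 8), 8 / sqrt(n) * 3 + 0.05)
})

test_that("patch datasets centre positives and honour requested counts", {
  pd <- generateNucleoliPatches(40, 40, seed = 7)
  expect_length(pd$patches, 80)
  expect_true(all(vapply(pd$patches, function(p) all(dim(p) == 27L),
                         logical(1))))
  # positives: centroid of the darkest connected region within 2 px of
  # the centre pixel (13, 13; 0-based)
  for (i in which(pd$labels)) {
    p <- pd$patches[[i]]
    dark <- p < 0.45   # objects render at <= 0.30, background near 0.55
    lab <- morphoqc:::.labelConnected8(dark)
    sizes <- tabulate(lab[lab > 0])
    main <- which(lab == which.max(sizes), arr.ind = TRUE)
    ctr <- colMeans(main) - 1
    expect_lt(sqrt(sum((ctr - c(13, 13))^2)), 2)
  }
  empty <- generateNucleoliPatches(0, 0, seed = 1)
  expect_length(empty$patches, 0)

  d <- withr::local_tempdir()
  generateNucleoliPatches(3, 2, seed = 8, dir = d)
  expect_length(list.files(d, pattern = "\\.tif$"), 5)
  lab <- read.csv(file.path(d, "labels.csv"))
  expect_identical(lab$label, c(1L, 1L, 1L, 0L, 0L))
})

test_that("labelled datasets have exact class counts and stable bytes", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  n <- c(poor = 3, mod = 2, good = 2)
  f1 <- generateLabeledDataset(d1, nPerClass = n, seed = 99)
  f2 <- generateLabeledDataset(d2, nPerClass = n, seed = 99)
  expect_identical(nrow(f1), 7L)
  labs <- read.csv(file.path(d1, "labels.csv"))
  expect_identical(as.vector(table(factor(labs$label, qualityLevels()))),
                   c(3L, 2L, 2L))
  tifs <- list.files(file.path(d1, "tiles"), full.names = TRUE)
  expect_length(tifs, 7)
  for (f in basename(tifs)) {
    expect_identical(readBin(file.path(d1, "tiles", f), "raw", 1e6),
                     readBin(file.path(d2, "tiles", f), "raw", 1e6))
  }
  expect_true(dir.exists(file.path(d1, "masks", "crack")))
  tf <- readFeatureTable(file.path(d1, "truth_features.csv"))
  expect_identical(nrow(tf), 7L)
})

test_that("rater simulation follows the confusion matrix", {
  y <- qualityFactor(rep(c("poor", "mod", "good"), each = 5))
  ident <- generateRaterLabels(y, nRaters = 4, seed = 3)
  expect_identical(nrow(ident), 60L)
  expect_true(all(as.character(ident$label) ==
                    as.character(y[ident$tile_id])))

  conf <- matrix(1 / 3, 3, 3)
  many <- generateRaterLabels(qualityFactor(rep("mod", 2500)), nRaters = 4,
                              confusion = conf, seed = 4)
  marg <- table(many$label) / nrow(many)
  expect_true(all(abs(marg - 1 / 3) < 0.02))

  again <- generateRaterLabels(qualityFactor(rep("mod", 2500)), nRaters = 4,
                               confusion = conf, seed = 4)
  expect_identical(many, again)

  expect_error(generateRaterLabels(y, confusion = matrix(1, 3, 3)),
               "row-stochastic")
})

test_that("impossible placement densities fail loudly", {
  rec <- classRecipe(nucleiLambda = 80)
  expect_error(generateTile(rec, "poor", seed = 1), "place")
})
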