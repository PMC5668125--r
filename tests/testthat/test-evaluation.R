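test_that("vote aggregation is plurality with ties to the lowest grade", {
  expect_identical(as.character(aggregateLabels(c("good", "good", "mod",
                                                  "poor"))), "good")
  expect_identical(as.character(aggregateLabels(c("good", "good", "mod",
                                                  "mod"))), "mod")
  expect_identical(as.character(aggregateLabels(c("good", "mod", "poor"))),
                   "poor")
  expect_error(aggregateLabels(character(0)), "at least one")

  # exhaustive: all 3- and 4-rater vote vectors agree with the oracle
  lev <- qualityLevels()
  for (n in 3:4) {
    votes <- do.call(expand.grid, rep(list(lev), n))
    for (i in seq_len(nrow(votes))) {
      v <- as.character(unlist(votes[i, ]))
      expect_identical(as.character(aggregateLabels(v)), bruteAggregate(v))
    }
  }

  # permutation invariance
  withr::with_seed(8, {
    for (i in 1:20) {
      v <- sample(lev, 5, replace = TRUE)
      expect_identical(aggregateLabels(v), aggregateLabels(rev(sample(v))))
    }
  })
})

test_that("aggregating simulated identity raters recovers the truth", {
  y <- qualityFactor(rep(qualityLevels(), times = c(5, 3, 4)))
  tab <- generateRaterLabels(y, nRaters = 4, seed = 2)
  agg <- aggregateLabelTable(tab)
  expect_identical(as.character(agg$label), as.character(y))
})

test_that("confusion matrix and per-class metrics match closed forms", {
  y <- qualityFactor(c(rep("poor", 8), rep("mod", 5), rep("good", 4)))
  expect_identical(unname(confusionAndMetrics(y, y)$confusion),
                   diag(c(8L, 5L, 4L)))
  expect_true(all(confusionAndMetrics(y, y)$metrics[, 3:6] == 1))

  # poor class with TP=4, FP=1, FN=4 in a 20-item problem
  truth <- qualityFactor(c(rep("poor", 8), rep("mod", 6), rep("good", 6)))
  pred <- qualityFactor(c(rep("poor", 4), rep("mod", 4),       # 4 TP, 4 FN
                          "poor", rep("mod", 5),               # 1 FP
                          rep("good", 6)))
  m <- confusionAndMetrics(truth, pred)$metrics
  poor <- m[m$class == "poor", ]
  expect_equal(poor$precision, 0.8)
  expect_equal(poor$recall, 0.5)
  expect_equal(poor$f_measure, 2 * 0.4 / 1.3)
  expect_equal(poor$accuracy, (4 + 11) / 20)
  expect_identical(poor$support, 8L)

  # degenerate: everything misclassified into one class
  allG <- qualityFactor(rep("good", 5))
  allP <- qualityFactor(rep("poor", 5))
  suppressWarnings(mm <- confusionAndMetrics(allG, allP)$metrics)
  expect_identical(mm$recall[mm$class == "good"], 0)
  expect_identical(mm$precision[mm$class == "poor"], 0)
  w <- capture_warnings(confusionAndMetrics(allG, allP))
  expect_true(any(grepl("zero denominator", w)))

  expect_error(confusionAndMetrics(allG, qualityFactor("poor")),
               "equal length")
})

test_that("metric invariants hold on randomized label sets", {
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- sample(10:60, 1)
      truth <- qualityFactor(sample(qualityLevels(), n, replace = TRUE))
      pred <- qualityFactor(sample(qualityLevels(), n, replace = TRUE))
      r <- suppressWarnings(confusionAndMetrics(truth, pred))
      expect_identical(sum(r$confusion), n)
      expect_equal(unname(rowSums(r$confusion)),
                   as.vector(table(truth)[qualityLevels()]))
      expect_equal(r$metrics$support, unname(rowSums(r$confusion)),
                   ignore_attr = TRUE)
      with(r$metrics, for (j in 1:3) {
        if (precision[j] + recall[j] > 0) {
          expect_gte(f_measure[j], min(precision[j], recall[j]) - 1e-12)
          expect_lte(f_measure[j], max(precision[j], recall[j]) + 1e-12)
        }
      })
    }
  })
})

test_that("stratified metrics split and recombine consistently", {
  withr::with_seed(17, {
    truth <- qualityFactor(sample(qualityLevels(), 90, replace = TRUE))
    pred <- qualityFactor(sample(qualityLevels(), 90, replace = TRUE))
  })
  one <- stratifiedMetrics(truth, pred, rep("lineA", 90))
  pooled <- suppressWarnings(confusionAndMetrics(truth, pred))
  expect_identical(suppressWarnings(one$lineA$confusion), pooled$confusion)

  strata <- rep(c("MRC5", "Edom", "201B7"), each = 30)
  per <- suppressWarnings(stratifiedMetrics(truth, pred, strata))
  expect_identical(Reduce(`+`, lapply(per, `[[`, "confusion")),
                   pooled$confusion)

  perfect <- stratifiedMetrics(
    qualityFactor(c("poor", "mod", "good", "poor", "mod", "good")),
    qualityFactor(c("poor", "mod", "good", "good", "poor", "mod")),
    rep(c("a", "b"), each = 3))
  expect_true(all(perfect$a$metrics$f_measure == 1))
  expect_true(all(perfect$b$metrics$f_measure == 0))

  expect_error(stratifiedMetrics(truth, pred, strata[1:10]), "align")
  expect_error(stratifiedMetrics(truth, pred,
                                 c(NA, strata[-1])), "NA")
})

test_that("detector agreement is the regression R^2 with affine invariance", {
  x <- c(0.1, 0.4, 0.2, 0.8, 0.5)
  expect_equal(detectorAgreement(x, x), 1)
  expect_equal(detectorAgreement(2 * x + 5, x), 1)
  withr::with_seed(12, {
    a <- rnorm(10000); b <- rnorm(10000)
  })
  expect_lt(detectorAgreement(a, b), 0.01)
  expect_warning(r <- detectorAgreement(x, rep(1, 5)), "zero variance")
  expect_true(is.na(r))
  expect_error(detectorAgreement(x[1:2], x[1:2]), "at least 3")
  expect_error(detectorAgreement(x, x[1:3]), "lengths")
})

test_that("evaluation reports serialize to JSON and read back", {
  withr::with_seed(2, {
    truth <- qualityFactor(sample(qualityLevels(), 60, replace = TRUE))
    pred <- truth
    pred[1:6] <- qualityFactor("poor")
  })
  f <- withr::local_tempfile(fileext = ".json")
  suppressWarnings(writeEvaluationReport(truth, pred, f,
                                         strata = rep(c("x", "y"), 30)))
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(sum(unlist(rep$pooled$confusion)), 60L)
  expect_setequal(names(rep$strata), c("x", "y"))
  expect_setequal(rep$pooled$metrics$class, qualityLevels())
})
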