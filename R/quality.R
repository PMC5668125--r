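# Tile-level quality grading: RBF-SVM over the three morphological
# features, one-vs-one voting with conservative (lowest-grade) ties,
# grid-searched under stratified cross-validation; sliding-window quality
# maps over full frames.

.featureNames3 <- c("n_nucleoli", "crack_rate", "diff_nuclei_rate")

.featureMatrix <- function(features) {
  if (is(features, "FeatureVector")) features <- as.data.frame(features)
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, is, logical(1), "FeatureVector")))
    features <- do.call(rbind, lapply(features, as.data.frame))
  x <- as.matrix(as.data.frame(features)[, .featureNames3])
  if (any(!is.finite(x))) stop("features must be finite")
  x
}

# One-vs-one vote from a libsvm pairwise decision-value matrix. Columns are
# named "a/b"; a positive value favours a. Ties in the vote count resolve
# to the lowest grade among the tied labels.
.voteFromDecision <- function(dec, lev) {
  pairs <- strsplit(colnames(dec), "/", fixed = TRUE)
  apply(dec, 1L, function(z) {
    votes <- setNames(integer(length(lev)), lev)
    for (j in seq_along(z)) {
      w <- if (z[j] > 0) pairs[[j]][1] else pairs[[j]][2]
      votes[w] <- votes[w] + 1L
    }
    tied <- names(votes)[votes == max(votes)]
    tied[which.min(match(tied, lev))]   # lev is ordered worst..best
  })
}

.predictVote <- function(fit, x, lev) {
  pr <- predict(fit, x, decision.values = TRUE)
  dec <- attr(pr, "decision.values")
  factor(.voteFromDecision(dec, lev), levels = lev, ordered = TRUE)
}

#' Train the tile quality classifier
#'
#' Fits a one-vs-one RBF-kernel SVM on z-scored feature vectors.
#' `(C, gamma)` is chosen by grid search maximizing the mean
#' macro-averaged F-measure over seeded stratified k-fold
#' cross-validation (macro averaging keeps the minority classes from
#' being swamped by the class imbalance), then the model is refit on all
#' data. Training is deterministic given `seed`.
#'
#' @param features data.frame (columns `n_nucleoli`, `crack_rate`,
#'   `diff_nuclei_rate`), matrix, or list of [FeatureVector-class].
#' @param labels quality labels, coercible via [qualityFactor()].
#' @param grid list with numeric vectors `C` and `gamma`
#'   (default [defaultSvmGrid()]).
#' @param folds cross-validation folds (default 3).
#' @param seed integer seed for the fold assignment.
#' @return A [QualitySvmModel-class]. Its `cvScores` slot holds the mean
#'   and per-fold macro-F of every grid point; `cvDetail` the per-class
#'   precision/recall/F per fold at the selected point.
#' @export
trainQualitySvm <- function(features, labels, grid = defaultSvmGrid(),
                            folds = 3L, seed = 1L) {
  x <- .featureMatrix(features)
  y <- qualityFactor(labels)
  if (anyNA(y)) stop("labels must not contain NA")
  if (nrow(x) != length(y)) stop("features and labels must align")
  lev <- qualityLevels()
  yf <- factor(as.character(y), levels = lev)   # plain factor for libsvm

  fit <- .gridSearchSvm(x, yf, grid, folds, seed, score = .macroF,
                        predictFun = function(m, newx)
                          factor(.voteFromDecision(
                            attr(predict(m, newx, decision.values = TRUE),
                                 "decision.values"), lev), levels = lev))

  # per-class CV detail at the selected grid point
  xs <- .applyScaling(x, fit$scaling)
  detail <- list()
  for (f in seq_len(folds)) {
    tr <- fit$fold != f
    m <- e1071::svm(xs[tr, , drop = FALSE], yf[tr],
                    type = "C-classification", kernel = "radial",
                    cost = fit$selected["C"], gamma = fit$selected["gamma"],
                    scale = FALSE)
    pred <- .predictVote(m, xs[!tr, , drop = FALSE], lev)
    cm <- confusionAndMetrics(qualityFactor(yf[!tr]), pred)
    detail[[f]] <- cbind(fold = f, cm$metrics)
  }
  new("QualitySvmModel", fit = fit$model, scaling = fit$scaling,
      featureNames = .featureNames3, grid = grid, cvScores = fit$cvScores,
      selected = fit$selected, folds = as.integer(folds),
      seed = as.integer(seed), levels = lev,
      cvDetail = do.call(rbind, detail))
}

#' Predict quality labels for feature vectors
#'
#' Applies the model's stored z-scoring, evaluates the three pairwise
#' decision functions, and votes one-vs-one; vote ties are broken toward
#' the lowest quality label, the conservative rule used for expert-vote
#' aggregation.
#'
#' @param features a [FeatureVector-class], a list of them, or a
#'   data.frame/matrix with the three feature columns.
#' @param model a [QualitySvmModel-class].
#' @return ordered factor of quality labels.
#' @export
predictQuality <- function(features, model) {
  stopifnot(is(model, "QualitySvmModel"))
  x <- .applyScaling(.featureMatrix(features), model@scaling)
  .predictVote(model@fit, x, model@levels)
}

#' Grade one tile end to end
#'
#' Runs the three feature detectors, assembles the [FeatureVector-class],
#' and predicts the quality label. Both are returned for auditability.
#'
#' @param tile a [RoiTile-class].
#' @param blobModel a [BlobSvmModel-class].
#' @param model a [QualitySvmModel-class].
#' @param gaborCfg a [GaborBankConfig-class].
#' @param nucleiCfg a [NucleiDetectorConfig-class].
#' @param nucleoliCfg a [NucleoliDetectorConfig-class].
#' @param geom a [PixelGeometry-class].
#' @return list with elements `features` ([FeatureVector-class]) and
#'   `label` (ordered factor of length 1).
#' @export
classifyTile <- function(tile, blobModel, model,
                         gaborCfg = gaborBankConfig(),
                         nucleiCfg = nucleiDetectorConfig(),
                         nucleoliCfg = nucleoliDetectorConfig(),
                         geom = PixelGeometry()) {
  fv <- tileFeatures(tile, blobModel, gaborCfg, nucleiCfg, nucleoliCfg, geom)
  list(features = fv, label = predictQuality(fv, model))
}

#' Measure the three morphological features of a tile
#'
#' @inheritParams classifyTile
#' @return a [FeatureVector-class].
#' @export
tileFeatures <- function(tile, blobModel,
                         gaborCfg = gaborBankConfig(),
                         nucleiCfg = nucleiDetectorConfig(),
                         nucleoliCfg = nucleoliDetectorConfig(),
                         geom = PixelGeometry()) {
  n <- countNucleoli(tile, blobModel, geom, nucleoliCfg)
  crack <- crackAreaRate(detectCracks(tile, gaborCfg), tile)
  nuc <- diffNucleiAreaRate(detectNuclei(tile, nucleiCfg, geom), tile)
  featureVector(n, crack, nuc)
}

#' Scan a full frame into a quality map
#'
#' Classifies every stride-aligned 150-px window of a frame (the
#' acquisition-scale scanning procedure uses a 50-px stride, i.e. a
#' two-thirds window overlap) and assembles the labels into a
#' [QualityMap-class] of dimensions `floor((H - tile)/stride) + 1` by
#' `floor((W - tile)/stride) + 1`.
#'
#' @param img numeric intensity matrix in [0, 1], at least `tilePx` wide
#'   and tall.
#' @param blobModel a [BlobSvmModel-class].
#' @param model a [QualitySvmModel-class].
#' @param stridePx scan stride (default 50).
#' @param tilePx window side (default 150).
#' @inheritParams classifyTile
#' @return a [QualityMap-class].
#' @export
scanImage <- function(img, blobModel, model, stridePx = 50L, tilePx = 150L,
                      gaborCfg = gaborBankConfig(),
                      nucleiCfg = nucleiDetectorConfig(),
                      nucleoliCfg = nucleoliDetectorConfig(),
                      geom = PixelGeometry()) {
  stopifnot(is.matrix(img))
  if (min(dim(img)) < tilePx)
    stop(sprintf("image (%d x %d) smaller than the %d-px scan window",
                 nrow(img), ncol(img), tilePx))
  tiles <- tileImage(img, tilePx = tilePx, stridePx = stridePx)
  nRows <- (nrow(img) - tilePx) %/% stridePx + 1L
  nCols <- (ncol(img) - tilePx) %/% stridePx + 1L
  labs <- vapply(tiles, function(tl) {
    as.character(classifyTile(tl, blobModel, model, gaborCfg, nucleiCfg,
                              nucleoliCfg, geom)$label)
  }, character(1))
  new("QualityMap", labels = matrix(labs, nRows, nCols, byrow = TRUE),
      stridePx = as.integer(stridePx), tilePx = as.integer(tilePx))
}

#' Quality map accessors and rendering
#'
#' `mapLabels` returns the label grid as an ordered factor matrix-alike
#' (character matrix plus levels); `writeQualityPng` renders the map as a
#' colour overlay PNG (poor = red, mod = yellow, good = green), one
#' stride-sized block per window.
#'
#' @param x a [QualityMap-class].
#' @return `mapLabels`: character matrix of labels.
#' @export
setGeneric("mapLabels", function(x) standardGeneric("mapLabels"))

#' @rdname mapLabels
#' @export
setMethod("mapLabels", "QualityMap", function(x) x@labels)

#' @rdname mapLabels
#' @param path output PNG path.
#' @param blockPx rendered block size per window (default the stride).
#' @export
writeQualityPng <- function(x, path, blockPx = x@stridePx) {
  stopifnot(is(x, "QualityMap"))
  cols <- rbind(poor = c(0.85, 0.1, 0.1), mod = c(0.95, 0.85, 0.1),
                good = c(0.1, 0.7, 0.2))
  d <- dim(x@labels)
  arr <- array(0, c(d[1] * blockPx, d[2] * blockPx, 3))
  big <- x@labels[rep(seq_len(d[1]), each = blockPx),
                  rep(seq_len(d[2]), each = blockPx), drop = FALSE]
  for (ch in 1:3) {
    m <- matrix(cols[big, ch], nrow(big), ncol(big))
    arr[, , ch] <- m
  }
  png::writePNG(arr, path)
  invisible(path)
}

setMethod("show", "QualityMap", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels, levels = qualityLevels()))
  cat(sprintf("QualityMap %d x %d windows (tile %d px, stride %d px): %s\n",
              d[1], d[2], object@tilePx, object@stridePx,
              paste(names(tab), tab, sep = "=", collapse = " ")))
})

setMethod("show", "QualitySvmModel", function(object) {
  cat(sprintf(
    "QualitySvmModel (RBF, one-vs-one %s): C=%.4g gamma=%.4g, %d SVs\n",
    paste(object@levels, collapse = "/"), object@selected["C"],
    object@selected["gamma"], object@fit$tot.nSV))
  cat(sprintf("  grid %d x %d, %d-fold CV, best mean macro-F %.3f\n",
              length(object@grid$C), length(object@grid$gamma),
              object@folds, max(object@cvScores$meanScore)))
})

#' Save or load a fitted model
#'
#' Serializes the full model object (fit, scaling, grid, CV scores,
#' selected point, seed) to an RDS file.
#'
#' @param model a [BlobSvmModel-class] or [QualitySvmModel-class].
#' @param path file path.
#' @return `loadModel`: the model object; `saveModel`: `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "RbfSvmModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "RbfSvmModel")) stop("not a serialized morphoqc model: ", path)
  m
}
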