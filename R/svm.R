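#' @importFrom e1071 svm
NULL

# Shared RBF-SVM machinery: z-scoring, stratified folds, grid search.
# Both detectors' classifiers and the quality grader go through this path,
# so selection (max mean CV score, ties to the first grid point in C-then-
# gamma order) and determinism are identical everywhere.

#' Default hyperparameter grid for the RBF-SVM grid search
#'
#' Log-spaced soft-margin constants C over 10^-1..10^2 (7 steps) and
#' kernel widths gamma over 10^-3..10 (9 steps). The span covers the
#' order of magnitude of optima reported for this problem class
#' (C near 0.6-8, gamma near 0.05-0.13).
#'
#' @return list with numeric vectors `C` and `gamma`.
#' @export
#' @examples defaultSvmGrid()
defaultSvmGrid <- function() {
  list(C = 10^seq(-1, 2, length.out = 7),
       gamma = 10^seq(-3, 1, length.out = 9))
}

.fitScaling <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2L, sd)
  sg[!is.finite(sg) | sg == 0] <- 1   # constant feature: leave centred
  list(mean = mu, sd = sg)
}

.applyScaling <- function(x, scaling) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, scaling$mean, "-"), 2L, scaling$sd, "/")
}

# Stratified fold assignment, deterministic given seed: within each class
# the (seeded) shuffled members are dealt round-robin into folds, so every
# class appears in every fold whenever it has >= folds members.
.stratifiedFolds <- function(y, folds, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(factor(y))) {
      i <- which(y == cl)
      i <- i[sample.int(length(i))]
      fold[i] <- rep_len(seq_len(folds), length(i))
    }
  })
  fold
}

.binaryF <- function(truth, pred) {
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

.macroF <- function(truth, pred) {
  lv <- levels(truth)
  mean(vapply(lv, function(cl) .binaryF(truth == cl, pred == cl), numeric(1)))
}

# Grid search with stratified k-fold CV. `score(truth, pred)` maps held-out
# factors to a scalar; the grid point maximizing the mean fold score wins,
# ties resolved to the earliest point in row-major (C ascending, then gamma
# ascending) order. Refits on all data at the selected point.
.gridSearchSvm <- function(x, y, grid, folds, seed, score,
                           predictFun = NULL) {
  stopifnot(is.list(grid), !is.null(grid$C), !is.null(grid$gamma))
  folds <- as.integer(folds)
  tab <- table(y)
  if (any(tab < folds))
    stop("class '", names(tab)[which.min(tab)], "' has fewer samples (",
         min(tab), ") than folds (", folds, ")")
  scaling <- .fitScaling(x)
  xs <- .applyScaling(x, scaling)
  fold <- .stratifiedFolds(y, folds, seed)

  pts <- expand.grid(gamma = grid$gamma, C = grid$C)[, c("C", "gamma")]
  meanScore <- numeric(nrow(pts))
  foldScore <- matrix(NA_real_, nrow(pts), folds)
  for (i in seq_len(nrow(pts))) {
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- e1071::svm(xs[tr, , drop = FALSE], y[tr], type = "C-classification",
                      kernel = "radial", cost = pts$C[i],
                      gamma = pts$gamma[i], scale = FALSE)
      pred <- if (is.null(predictFun)) {
        predict(m, xs[!tr, , drop = FALSE])
      } else {
        predictFun(m, xs[!tr, , drop = FALSE])
      }
      foldScore[i, f] <- score(y[!tr], pred)
    }
    meanScore[i] <- mean(foldScore[i, ])
  }
  best <- which.max(meanScore)   # first maximum: deterministic tie-break
  model <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                      cost = pts$C[best], gamma = pts$gamma[best],
                      scale = FALSE)
  cvScores <- cbind(pts, meanScore = meanScore,
                    as.data.frame(foldScore) |>
                      setNames(paste0("fold", seq_len(folds))))
  list(model = model, scaling = scaling, cvScores = cvScores,
       selected = c(C = pts$C[best], gamma = pts$gamma[best]),
       fold = fold, best = best)
}
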