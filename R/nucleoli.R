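# Nucleolus detection: dark near-oval blobs 3-6 um in diameter, counted per
# tile after an SVM accept/reject step on shape and intensity features.

#' Extract dark blob candidates from a tile
#'
#' Candidate nucleoli are connected components (8-connectivity) of pixels
#' darker than a background-refined adaptive threshold, gated to an
#' equivalent-diameter window slightly wider than the biological 3-6
#' micrometre range (default 2-8) so the SVM decides borderline sizes.
#'
#' Thresholding is two-pass. A robust preliminary dark set
#' (`intensity < median - k * MAD`, global) flags pixels likely to belong
#' to objects; local mean and standard deviation are then computed over
#' the remaining background pixels in a square window spanning
#' `windowFactor` times the largest admissible diameter, and the final
#' dark set is `intensity < mean - k * sd`. The refinement keeps the local
#' statistics from being dragged down by the object itself, which matters
#' when the object fills much of the field (27-px training patches). Both
#' passes are exactly invariant under a constant intensity shift.
#'
#' @param tile a [RoiTile-class] (any size; 27-px patches work too).
#' @param geom a [PixelGeometry-class].
#' @param params a [NucleoliDetectorConfig-class].
#' @return data.frame with one row per candidate: `row`, `col` (centroid,
#'   0-based), `area_px`, `perimeter_px`, `roundness`, `equiv_diam_um`,
#'   `mean_intensity`, `contrast` (surround minus blob mean),
#'   `eccentricity`, `border` (logical, touches the tile border). The
#'   pixel set of each candidate (linear indices into the tile) is
#'   attached as the `pixels` attribute, a list parallel to the rows.
#' @export
extractDarkBlobs <- function(tile, geom = PixelGeometry(),
                             params = nucleoliDetectorConfig()) {
  stopifnot(is(tile, "RoiTile"), is(params, "NucleoliDetectorConfig"))
  img <- tile@pixels
  nr <- nrow(img); nc <- ncol(img)

  k <- params@k
  med <- median(img)
  madv <- mad(img)                      # scaled MAD, consistent with sd
  prelim <- img < med - k * madv
  win <- 2L * (umToPx(params@windowFactor * params@diamRangeUm[2], geom) %/%
                 2L) + 1L
  st <- boxStats(img, win, exclude = prelim)
  # the 1e-9 guard absorbs integral-image rounding dust, which otherwise
  # flips the strict comparison on exactly-constant backgrounds
  dark <- img < st$mean - k * st$sd - 1e-9

  empty <- data.frame(row = numeric(0), col = numeric(0),
                      area_px = integer(0), perimeter_px = numeric(0),
                      roundness = numeric(0), equiv_diam_um = numeric(0),
                      mean_intensity = numeric(0), contrast = numeric(0),
                      eccentricity = numeric(0), border = logical(0))
  attr(empty, "pixels") <- list()
  if (!any(dark)) return(empty)

  lab <- .labelConnected8(dark)
  nlab <- max(lab)
  idx <- which(dark)
  comp <- split(idx, lab[idx])

  areaRange <- pi * (umToPx(params@diamRangeUm, geom) / 2)^2
  rows <- vector("list", nlab)
  pix <- vector("list", nlab)
  kept <- 0L
  for (ci in seq_along(comp)) {
    p <- comp[[ci]]
    area <- length(p)
    equivDiamUm <- 2 * sqrt(area / pi) * geom@umPerPx
    if (equivDiamUm < params@diamRangeUm[1] ||
        equivDiamUm > params@diamRangeUm[2]) next
    pr <- (p - 1L) %% nr + 1L
    pc <- (p - 1L) %/% nr + 1L
    sh <- componentShape(pr, pc)
    surround <- .surroundMean(img, dark, pr, pc, sh$bbox)
    blobMean <- mean(img[p])
    kept <- kept + 1L
    rows[[kept]] <- data.frame(
      row = sh$centroid[1] - 1, col = sh$centroid[2] - 1,
      area_px = area, perimeter_px = sh$perimeter,
      roundness = sh$roundness, equiv_diam_um = equivDiamUm,
      mean_intensity = blobMean, contrast = surround - blobMean,
      eccentricity = sh$eccentricity,
      border = sh$bbox[1] == 1L || sh$bbox[3] == 1L ||
        sh$bbox[2] == nr || sh$bbox[4] == nc)
    pix[[kept]] <- p
  }
  if (kept == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(kept)])
  rownames(out) <- NULL
  attr(out, "pixels") <- pix[seq_len(kept)]
  out
}

# Mean intensity of the non-dark ring (width 3 px) around a component.
.surroundMean <- function(img, dark, pr, pc, bbox) {
  nr <- nrow(img); nc <- ncol(img)
  m <- 3L
  r0 <- max(bbox[1] - m, 1L); r1 <- min(bbox[2] + m, nr)
  c0 <- max(bbox[3] - m, 1L); c1 <- min(bbox[4] + m, nc)
  sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(pr - r0 + 1L, pc - c0 + 1L)] <- TRUE
  ring <- EBImage::dilate(sub * 1, EBImage::makeBrush(2L * m + 1L, "disc")) > 0
  ring <- ring & !sub & !dark[r0:r1, c0:c1]
  if (!any(ring)) return(mean(img[r0:r1, c0:c1]))
  mean(img[r0:r1, c0:c1][ring])
}

#' Feature matrix of blob candidates
#'
#' Fixed feature order consumed by the blob SVM:
#' `equiv_diam_um`, `roundness`, `mean_intensity`, `contrast`,
#' `eccentricity`. Size and roundness are the primary discriminative
#' cues; mean intensity and contrast encode "appears black", eccentricity
#' "nearly oval".
#'
#' @param candidates data.frame from [extractDarkBlobs()].
#' @return numeric matrix, one row per candidate.
#' @export
blobFeatureVector <- function(candidates) {
  cols <- c("equiv_diam_um", "roundness", "mean_intensity", "contrast",
            "eccentricity")
  as.matrix(candidates[, cols, drop = FALSE])
}

.blobFeatureNames <- c("equiv_diam_um", "roundness", "mean_intensity",
                       "contrast", "eccentricity")

# Feature row for one training patch: the candidate closest to the patch
# centre, or background statistics when no candidate was extracted.
.patchFeatureRow <- function(patch, geom, params) {
  tile <- RoiTile(patch)
  cand <- extractDarkBlobs(tile, geom, params)
  if (nrow(cand) == 0L)
    return(c(0, 0, mean(patch), 0, 0))
  ctr <- (dim(patch) - 1) / 2
  d2 <- (cand$row - ctr[1])^2 + (cand$col - ctr[2])^2
  blobFeatureVector(cand)[which.min(d2), ]
}

#' Train the nucleolus accept/reject SVM
#'
#' Fits an RBF-kernel SVM on shape/intensity features of 27 x 27 training
#' patches (positives: a nucleolus centred in the patch; negatives:
#' background, fragments, off-centre objects). For each patch the most
#' central dark-blob candidate supplies the feature row; positive patches
#' with no extractable candidate are dropped with a warning, negatives
#' fall back to background statistics. `(C, gamma)` is selected by grid
#' search maximizing the mean cross-validated F-measure of the positive
#' class over stratified folds, then the model is refit on all data.
#' Deterministic given `seed`.
#'
#' @param patches list of 27 x 27 numeric matrices in [0, 1].
#' @param labels logical vector (TRUE = nucleolus), parallel to `patches`.
#' @param grid list with numeric vectors `C` and `gamma`
#'   (default [defaultSvmGrid()]).
#' @param folds cross-validation folds (default 3).
#' @param seed integer seed for the fold assignment.
#' @param geom a [PixelGeometry-class].
#' @param params a [NucleoliDetectorConfig-class].
#' @return A [BlobSvmModel-class].
#' @export
trainBlobSvm <- function(patches, labels, grid = defaultSvmGrid(),
                         folds = 3L, seed = 1L, geom = PixelGeometry(),
                         params = nucleoliDetectorConfig()) {
  stopifnot(length(patches) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || !any(!labels))
    stop("both classes (nucleolus / not) must be present")
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 patches per class")

  feats <- t(vapply(patches, .patchFeatureRow, numeric(5),
                    geom = geom, params = params))
  colnames(feats) <- .blobFeatureNames
  # positives whose nucleolus could not be extracted carry no signal
  noCand <- labels & feats[, "equiv_diam_um"] == 0
  if (any(noCand)) {
    warning(sum(noCand), " positive patch(es) had no extractable candidate",
            " and were dropped", call. = FALSE)
    feats <- feats[!noCand, , drop = FALSE]
    labels <- labels[!noCand]
  }
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))

  fit <- .gridSearchSvm(feats, y, grid, folds, seed,
                        score = function(truth, pred) {
                          .binaryF(truth == "pos", pred == "pos")
                        })
  new("BlobSvmModel", fit = fit$model, scaling = fit$scaling,
      featureNames = .blobFeatureNames, grid = grid,
      cvScores = fit$cvScores, selected = fit$selected,
      folds = as.integer(folds), seed = as.integer(seed))
}

#' Count nucleoli in a tile
#'
#' Runs candidate extraction, scores each candidate with the blob SVM,
#' and returns the number of accepted candidates. Candidates flagged as
#' touching the tile border are counted once like any other. Merged
#' (touching) nucleoli form a single candidate and count as one; no
#' watershed splitting is attempted.
#'
#' @param tile a [RoiTile-class].
#' @param model a [BlobSvmModel-class].
#' @param geom a [PixelGeometry-class].
#' @param params a [NucleoliDetectorConfig-class].
#' @return non-negative integer count.
#' @export
countNucleoli <- function(tile, model, geom = PixelGeometry(),
                          params = nucleoliDetectorConfig()) {
  stopifnot(is(model, "BlobSvmModel"))
  cand <- extractDarkBlobs(tile, geom, params)
  if (nrow(cand) == 0L) return(0L)
  x <- .applyScaling(blobFeatureVector(cand), model@scaling)
  pred <- predict(model@fit, x)
  sum(pred == "pos")
}

setMethod("show", "BlobSvmModel", function(object) {
  cat(sprintf(
    "BlobSvmModel (RBF): C=%.4g gamma=%.4g, %d SVs, grid %dx%d, %d-fold CV\n",
    object@selected["C"], object@selected["gamma"], object@fit$tot.nSV,
    length(object@grid$C), length(object@grid$gamma), object@folds))
})
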