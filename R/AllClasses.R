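#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib morphoqc, .registration = TRUE
NULL

#' Ordered quality classes
#'
#' The three expert grades of a culture region, ordered from worst to best:
#' `poor < mod < good`. Tie-breaking throughout the package resolves toward
#' the lowest grade, the conservative convention used when aggregating
#' expert votes.
#'
#' @return Character vector `c("poor", "mod", "good")`.
#' @export
#' @examples qualityLevels()
qualityLevels <- function() c("poor", "mod", "good")

#' Coerce to an ordered quality factor
#'
#' @param x character vector (or factor) with values among
#'   `qualityLevels()`.
#' @return An ordered factor with levels `poor < mod < good`.
#' @export
#' @examples
#' qualityFactor(c("good", "poor"))
qualityFactor <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% qualityLevels())
  if (any(bad))
    stop("unknown quality label(s): ", paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = qualityLevels(), ordered = TRUE)
}

#' PixelGeometry: physical pixel pitch
#'
#' Ties all size thresholds (nucleolus diameter gates, nucleus diameter
#' window) to physical units. The default pitch of 1/3 micrometre per pixel
#' reproduces the acquisition geometry in which a 150-pixel region of
#' interest spans 50 micrometres (10x phase-contrast objective).
#'
#' @slot umPerPx micrometres per pixel (positive scalar).
#' @export
setClass("PixelGeometry", representation(umPerPx = "numeric"))

setValidity("PixelGeometry", function(object) {
  if (length(object@umPerPx) != 1L || !is.finite(object@umPerPx) ||
      object@umPerPx <= 0)
    return("umPerPx must be a single positive finite number")
  TRUE
})

#' @describeIn PixelGeometry-class Constructor.
#' @param umPerPx micrometres per pixel; default `1/3`.
#' @return A `PixelGeometry` object.
#' @export
#' @examples PixelGeometry()
PixelGeometry <- function(umPerPx = 1 / 3) {
  new("PixelGeometry", umPerPx = as.numeric(umPerPx))
}

#' RoiTile: one region of interest
#'
#' A square window cut from a phase-contrast frame (150 x 150 px = 50 x 50
#' micrometres at the default pitch), the unit on which features are
#' measured and quality is graded. Intensities are normalized to [0, 1];
#' `origin` is the 0-based (row, col) of the top-left corner in the parent
#' frame, so the tile covers the half-open ranges
#' `[origin, origin + dim)`.
#'
#' @slot pixels numeric matrix of intensities in [0, 1].
#' @slot origin integer (row, col), 0-based.
#' @export
setClass("RoiTile", representation(pixels = "matrix", origin = "integer"))

setValidity("RoiTile", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(p) == 0L)
    return("pixels must be a non-empty numeric matrix")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    return("pixel intensities must lie in [0, 1]")
  if (length(object@origin) != 2L || any(object@origin < 0L))
    return("origin must be two non-negative integers (row, col)")
  TRUE
})

#' @describeIn RoiTile-class Constructor.
#' @param pixels numeric matrix with values in [0, 1].
#' @param origin 0-based (row, col) of the tile's top-left corner.
#' @return A `RoiTile`.
#' @export
RoiTile <- function(pixels, origin = c(0L, 0L)) {
  new("RoiTile", pixels = pixels, origin = as.integer(origin))
}

#' BinaryMask: per-pixel feature annotation
#'
#' A logical matrix the same shape as the image it annotates, with a role
#' identifying which morphological feature it marks.
#'
#' @slot pixels logical matrix.
#' @slot role one of `"nucleoli"`, `"crack"`, `"diff_nuclei"`.
#' @export
setClass("BinaryMask", representation(pixels = "matrix", role = "character"))

.maskRoles <- c("nucleoli", "crack", "diff_nuclei")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("mask pixels must be logical")
  if (anyNA(object@pixels)) return("mask pixels must not contain NA")
  if (length(object@role) != 1L || !(object@role %in% .maskRoles))
    return(paste("role must be one of:", paste(.maskRoles, collapse = ", ")))
  TRUE
})

#' @describeIn BinaryMask-class Constructor.
#' @param pixels logical matrix (numeric input is coerced, nonzero = TRUE).
#' @param role mask role.
#' @return A `BinaryMask`.
#' @export
BinaryMask <- function(pixels, role = c("nucleoli", "crack", "diff_nuclei")) {
  role <- match.arg(role)
  if (!is.logical(pixels)) {
    p <- pixels != 0
    dim(p) <- dim(pixels)
    pixels <- p
  }
  new("BinaryMask", pixels = pixels, role = role)
}

#' FeatureVector: the three morphological features of one tile
#'
#' @slot nNucleoli non-negative integer count of accepted nucleoli.
#' @slot crackRate fraction of tile pixels covered by cracks, in [0, 1].
#' @slot diffNucleiRate fraction covered by differentiating nuclei, in [0, 1].
#' @export
setClass("FeatureVector",
         representation(nNucleoli = "integer", crackRate = "numeric",
                        diffNucleiRate = "numeric"))

setValidity("FeatureVector", function(object) {
  if (length(object@nNucleoli) != 1L || is.na(object@nNucleoli) ||
      object@nNucleoli < 0L)
    return("nNucleoli must be a single non-negative integer")
  for (s in c("crackRate", "diffNucleiRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      return(paste(s, "must be a single value in [0, 1]"))
  }
  TRUE
})

#' @describeIn FeatureVector-class Constructor.
#' @param nNucleoli nucleolus count.
#' @param crackRate crack area rate in [0, 1].
#' @param diffNucleiRate differentiating-nuclei area rate in [0, 1].
#' @return A `FeatureVector`.
#' @export
#' @examples featureVector(8, 0, 0)
featureVector <- function(nNucleoli = 0L, crackRate = 0, diffNucleiRate = 0) {
  new("FeatureVector", nNucleoli = as.integer(nNucleoli),
      crackRate = as.numeric(crackRate),
      diffNucleiRate = as.numeric(diffNucleiRate))
}

#' NucleoliDetectorConfig: dark-blob candidate extraction parameters
#'
#' Candidates are connected dark components below a background-refined
#' adaptive threshold (local mean minus `k` local standard deviations,
#' window spanning `windowFactor` times the largest admissible nucleolus
#' diameter), gated to an equivalent-diameter window slightly wider than
#' the biological 3-6 micrometre range so the SVM, not a hard gate,
#' decides borderline sizes.
#'
#' @slot k threshold depth in local standard deviations (default 2.5: a
#'   shallower depth marks several percent of pure background as dark,
#'   and the resulting clutter bridges neighbouring blobs into oversized
#'   components that the size gate then discards).
#' @slot diamRangeUm admissible equivalent-diameter window in micrometres
#'   (default `c(2, 8)`).
#' @slot windowFactor local-statistics window as a multiple of the largest
#'   admissible diameter (default 3).
#' @export
setClass("NucleoliDetectorConfig",
         representation(k = "numeric", diamRangeUm = "numeric",
                        windowFactor = "numeric"))

setValidity("NucleoliDetectorConfig", function(object) {
  if (object@k <= 0) return("k must be positive")
  if (length(object@diamRangeUm) != 2L ||
      object@diamRangeUm[1] <= 0 ||
      object@diamRangeUm[1] >= object@diamRangeUm[2])
    return("diamRangeUm must be an increasing positive pair")
  if (object@windowFactor <= 0) return("windowFactor must be positive")
  TRUE
})

#' @describeIn NucleoliDetectorConfig-class Constructor.
#' @param k threshold depth.
#' @param diamRangeUm admissible diameter window (micrometres).
#' @param windowFactor window multiple.
#' @return A `NucleoliDetectorConfig`.
#' @export
nucleoliDetectorConfig <- function(k = 2.5, diamRangeUm = c(2, 8),
                                   windowFactor = 3) {
  new("NucleoliDetectorConfig", k = as.numeric(k),
      diamRangeUm = as.numeric(diamRangeUm),
      windowFactor = as.numeric(windowFactor))
}

#' GaborBankConfig: crack-detector filter bank parameters
#'
#' Cracks are bright ridges a few pixels wide. The bank pairs
#' even-symmetric (cosine-phase, zero-mean) kernels, which peak on
#' ridges, with their odd-phase quadrature partners, which peak on
#' edges; the detector response is the positive even part minus
#' `edgeSuppression` times the odd magnitude, so the flanks and rims of
#' bright blobs are suppressed while genuine ridges stand. Orientations
#' are uniformly spaced over [0, pi). Constant regions respond exactly
#' zero.
#'
#' @slot nOrientations number of orientations (default 8).
#' @slot wavelengthsPx sinusoid wavelengths in pixels (default 4, 8, 12,
#'   spanning plausible crack widths at 1/3 micrometre per pixel).
#' @slot sigmaFactor Gaussian envelope width as a fraction of the
#'   wavelength (default 0.5).
#' @slot aspect envelope aspect ratio (default 1, isotropic: elongated
#'   envelopes make compact bright blobs bleed tangential streak
#'   responses).
#' @slot edgeSuppression weight of the odd-phase magnitude subtracted
#'   from the even-phase response (default 0.5).
#' @slot responseThreshold threshold on the per-tile-normalized response
#'   map, in (0, 1) (default 0.3).
#' @slot responseFloor floor of the per-tile normalizing maximum, as a
#'   fraction of the bank's response to a unit-contrast 3-px reference
#'   ridge (default 0.25, the faintest contrast still read as a crack);
#'   keeps crack-free tiles from having noise amplified to full scale.
#' @slot minElongation minimum linearity of an accepted component:
#'   either second-moment major/minor axis ratio or curvature-invariant
#'   thinness `perimeter^2/(4 pi area)` must reach this bound
#'   (default 3).
#' @slot minAreaPx minimum accepted component area in pixels
#'   (default 20).
#' @slot minRidgeContrast minimum excess of component mean intensity
#'   over its local non-candidate surround (default 0.15; a genuine
#'   crack is brighter than the cells flanking it).
#' @export
setClass("GaborBankConfig",
         representation(nOrientations = "integer", wavelengthsPx = "numeric",
                        sigmaFactor = "numeric", aspect = "numeric",
                        edgeSuppression = "numeric",
                        responseThreshold = "numeric",
                        responseFloor = "numeric",
                        minElongation = "numeric",
                        minAreaPx = "integer",
                        minRidgeContrast = "numeric"))

setValidity("GaborBankConfig", function(object) {
  if (object@nOrientations < 1L) return("need at least one orientation")
  if (any(object@wavelengthsPx <= 1)) return("wavelengths must exceed 1 px")
  if (object@sigmaFactor <= 0 || object@aspect <= 0)
    return("sigmaFactor and aspect must be positive")
  if (object@edgeSuppression < 0)
    return("edgeSuppression must be non-negative")
  if (object@responseThreshold <= 0 || object@responseThreshold >= 1)
    return("responseThreshold must lie in (0, 1)")
  if (object@responseFloor < 0) return("responseFloor must be non-negative")
  if (object@minElongation <= 0) return("minElongation must be positive")
  if (object@minAreaPx < 1L) return("minAreaPx must be positive")
  if (object@minRidgeContrast < 0)
    return("minRidgeContrast must be non-negative")
  TRUE
})

#' @describeIn GaborBankConfig-class Constructor.
#' @param nOrientations,wavelengthsPx,sigmaFactor,aspect,edgeSuppression,responseThreshold,responseFloor,minElongation,minAreaPx,minRidgeContrast
#'   see slots.
#' @return A `GaborBankConfig`.
#' @export
gaborBankConfig <- function(nOrientations = 8L, wavelengthsPx = c(4, 8, 12),
                            sigmaFactor = 0.5, aspect = 1,
                            edgeSuppression = 0.5,
                            responseThreshold = 0.3, responseFloor = 0.25,
                            minElongation = 3, minAreaPx = 20L,
                            minRidgeContrast = 0.15) {
  new("GaborBankConfig", nOrientations = as.integer(nOrientations),
      wavelengthsPx = as.numeric(wavelengthsPx),
      sigmaFactor = as.numeric(sigmaFactor), aspect = as.numeric(aspect),
      edgeSuppression = as.numeric(edgeSuppression),
      responseThreshold = as.numeric(responseThreshold),
      responseFloor = as.numeric(responseFloor),
      minElongation = as.numeric(minElongation),
      minAreaPx = as.integer(minAreaPx),
      minRidgeContrast = as.numeric(minRidgeContrast))
}

#' NucleiDetectorConfig: differentiating-nuclei segmenter parameters
#'
#' The segmenter seeds a graph cut with the darkest pixels as sure
#' foreground (source) and the brightest as sure background (sink);
#' percentile seeds keep the rule illumination-relative. Surviving
#' components must look like nuclei: equivalent diameter inside
#' `diamRangeUm` (bracketing the ~10 micrometre biology with slack, and
#' deliberately disjoint from the nucleolus size class) and roundness at
#' least `minRoundness`.
#'
#' @slot sourcePercentile dark seed cutoff percentile (default 2; hard
#'   seeds are irreversible, so the cutoff must undershoot the dark-object
#'   area fraction and claim only object cores).
#' @slot sinkPercentile bright seed cutoff percentile (default 60).
#' @slot diamRangeUm accepted equivalent-diameter window (default
#'   `c(7, 15)` micrometres).
#' @slot minRoundness minimum `4*pi*area/perimeter^2` (default 0.6).
#' @slot iterations graph-cut model re-estimation iterations (default 5).
#' @slot minSpread minimum intensity spread (between the 0.5th and
#'   99.5th percentiles) for a segmentable tile (default 0.05); flatter
#'   tiles return an empty mask.
#' @slot smoothness weight of the contrast-modulated pairwise term
#'   (default 2).
#' @export
setClass("NucleiDetectorConfig",
         representation(sourcePercentile = "numeric",
                        sinkPercentile = "numeric",
                        diamRangeUm = "numeric", minRoundness = "numeric",
                        iterations = "integer", minSpread = "numeric",
                        smoothness = "numeric"))

setValidity("NucleiDetectorConfig", function(object) {
  if (object@sourcePercentile <= 0 || object@sourcePercentile >= 100 ||
      object@sinkPercentile <= 0 || object@sinkPercentile >= 100)
    return("percentiles must lie in (0, 100)")
  if (object@sourcePercentile >= object@sinkPercentile)
    return("sourcePercentile must be below sinkPercentile")
  if (length(object@diamRangeUm) != 2L ||
      object@diamRangeUm[1] >= object@diamRangeUm[2])
    return("diamRangeUm must be an increasing pair")
  if (object@minRoundness <= 0 || object@minRoundness > 1)
    return("minRoundness must lie in (0, 1]")
  if (object@iterations < 1L) return("need at least one iteration")
  if (object@minSpread < 0) return("minSpread must be non-negative")
  if (object@smoothness < 0) return("smoothness must be non-negative")
  TRUE
})

#' @describeIn NucleiDetectorConfig-class Constructor.
#' @param sourcePercentile,sinkPercentile,diamRangeUm,minRoundness,iterations,minSpread,smoothness
#'   see slots.
#' @return A `NucleiDetectorConfig`.
#' @export
nucleiDetectorConfig <- function(sourcePercentile = 2, sinkPercentile = 60,
                                 diamRangeUm = c(7, 15), minRoundness = 0.6,
                                 iterations = 5L, minSpread = 0.05,
                                 smoothness = 2) {
  new("NucleiDetectorConfig",
      sourcePercentile = as.numeric(sourcePercentile),
      sinkPercentile = as.numeric(sinkPercentile),
      diamRangeUm = as.numeric(diamRangeUm),
      minRoundness = as.numeric(minRoundness),
      iterations = as.integer(iterations),
      minSpread = as.numeric(minSpread),
      smoothness = as.numeric(smoothness))
}

#' RbfSvmModel: a fitted RBF-kernel SVM with its preprocessing frozen in
#'
#' Wraps a fitted support vector machine together with the per-feature
#' z-scoring statistics estimated on its training data (applied
#' identically at prediction time), the hyperparameter grid searched, the
#' cross-validation score of every grid point, and the selected
#' `(C, gamma)`. `BlobSvmModel` accepts/rejects nucleolus candidates;
#' `QualitySvmModel` grades tiles into poor/mod/good by one-vs-one voting
#' with ties broken toward the lowest grade.
#'
#' @slot fit fitted `e1071::svm` object.
#' @slot scaling list with numeric vectors `mean` and `sd`.
#' @slot featureNames feature order the model expects.
#' @slot grid list with numeric vectors `C` and `gamma`.
#' @slot cvScores data.frame of per-grid-point CV scores.
#' @slot selected named numeric `(C, gamma)` chosen by grid search.
#' @slot folds number of cross-validation folds.
#' @slot seed RNG seed the fold assignment was derived from.
#' @aliases BlobSvmModel-class QualitySvmModel-class
#' @export
setClass("RbfSvmModel",
         representation(fit = "ANY", scaling = "list",
                        featureNames = "character", grid = "list",
                        cvScores = "data.frame", selected = "numeric",
                        folds = "integer", seed = "integer", "VIRTUAL"))

#' @export
setClass("BlobSvmModel", contains = "RbfSvmModel")

#' @export
setClass("QualitySvmModel", contains = "RbfSvmModel",
         representation(levels = "character", cvDetail = "data.frame"))

#' QualityMap: sliding-window grading of a full frame
#'
#' One quality label per stride-aligned 150-px window of a frame, in the
#' window grid's raster layout (`floor((H - tile)/stride) + 1` rows by
#' `floor((W - tile)/stride) + 1` columns).
#'
#' @slot labels character matrix of `qualityLevels()` values.
#' @slot stridePx scan stride in pixels.
#' @slot tilePx window side in pixels.
#' @export
setClass("QualityMap",
         representation(labels = "matrix", stridePx = "integer",
                        tilePx = "integer"))

setValidity("QualityMap", function(object) {
  if (!all(object@labels %in% qualityLevels()))
    return("labels must be quality levels")
  if (object@stridePx < 1L || object@tilePx < 1L)
    return("stridePx and tilePx must be positive")
  TRUE
})

#' ClassRecipe: generating distributions for one quality class
#'
#' Defines the class-conditional scene statistics the synthetic generator
#' draws from: nucleolus count ~ Poisson(`lambdaNucleoli`), crack presence
#' with probability `crackProb` (then `crackCountRange` strokes of the
#' given length/width), differentiating-nucleus count ~
#' Poisson(`nucleiLambda`), bright distractor count ~
#' Poisson(`distractorLambda`), on a smoothed-noise background. The
#' default per-class recipes (see [defaultRecipes()]) reproduce the
#' qualitative class ordering of the real data: nucleolus abundance
#' increases with quality, cracks concentrate in the moderate class, dark
#' differentiating nuclei in the poor class.
#'
#' @slot lambdaNucleoli Poisson mean of the nucleolus count.
#' @slot crackProb probability the tile contains any crack.
#' @slot crackCountRange integer range of crack strokes when present.
#' @slot crackLengthRangePx crack path length range (pixels).
#' @slot crackWidthRangePx crack stroke width range (pixels).
#' @slot nucleiLambda Poisson mean of the differentiating-nucleus count.
#' @slot distractorLambda Poisson mean of the bright distractor count.
#' @slot distractorKinds distractor kinds to draw from, a subset of
#'   `c("dead_cell", "stacked_region")`.
#' @slot nucleolusDiamRangeUm nucleolus diameter range (micrometres).
#' @slot nucleolusIntensityRange nucleolus intensity range.
#' @slot crackIntensityRange crack intensity range (bright).
#' @slot nucleusDiamRangeUm nucleus major-diameter range (micrometres).
#' @slot nucleusIntensityRange nucleus intensity range (dark).
#' @slot backgroundMean mean background intensity.
#' @slot textureSd amplitude of the smoothed cell-texture field.
#' @slot noiseSd per-pixel Gaussian noise standard deviation.
#' @slot edgeSoftness anti-aliasing width of object edges in pixels
#'   (0 renders hard edges).
#' @export
setClass("ClassRecipe",
         representation(lambdaNucleoli = "numeric", crackProb = "numeric",
                        crackCountRange = "integer",
                        crackLengthRangePx = "numeric",
                        crackWidthRangePx = "numeric",
                        nucleiLambda = "numeric",
                        distractorLambda = "numeric",
                        distractorKinds = "character",
                        nucleolusDiamRangeUm = "numeric",
                        nucleolusIntensityRange = "numeric",
                        crackIntensityRange = "numeric",
                        nucleusDiamRangeUm = "numeric",
                        nucleusIntensityRange = "numeric",
                        backgroundMean = "numeric", textureSd = "numeric",
                        noiseSd = "numeric", edgeSoftness = "numeric"))

setValidity("ClassRecipe", function(object) {
  if (object@lambdaNucleoli < 0 || object@nucleiLambda < 0 ||
      object@distractorLambda < 0)
    return("Poisson means must be non-negative")
  if (object@crackProb < 0 || object@crackProb > 1)
    return("crackProb must lie in [0, 1]")
  if (object@backgroundMean <= 0 || object@backgroundMean >= 1)
    return("backgroundMean must lie in (0, 1)")
  if (length(object@distractorKinds) < 1L ||
      !all(object@distractorKinds %in% c("dead_cell", "stacked_region")))
    return("distractorKinds must be among dead_cell, stacked_region")
  TRUE
})

#' @describeIn ClassRecipe-class Constructor.
#' @param lambdaNucleoli,crackProb,crackCountRange,crackLengthRangePx,crackWidthRangePx,nucleiLambda,distractorLambda,distractorKinds,nucleolusDiamRangeUm,nucleolusIntensityRange,crackIntensityRange,nucleusDiamRangeUm,nucleusIntensityRange,backgroundMean,textureSd,noiseSd,edgeSoftness
#'   see slots.
#' @return A `ClassRecipe`.
#' @export
classRecipe <- function(lambdaNucleoli = 4, crackProb = 0,
                        crackCountRange = c(1L, 2L),
                        crackLengthRangePx = c(60, 140),
                        crackWidthRangePx = c(2, 5),
                        nucleiLambda = 0, distractorLambda = 0,
                        distractorKinds = c("dead_cell", "stacked_region"),
                        nucleolusDiamRangeUm = c(3, 6),
                        nucleolusIntensityRange = c(0.15, 0.30),
                        crackIntensityRange = c(0.85, 0.95),
                        nucleusDiamRangeUm = c(8.5, 11.5),
                        nucleusIntensityRange = c(0.22, 0.35),
                        backgroundMean = 0.55, textureSd = 0.03,
                        noiseSd = 0.02, edgeSoftness = 1) {
  new("ClassRecipe", lambdaNucleoli = as.numeric(lambdaNucleoli),
      crackProb = as.numeric(crackProb),
      crackCountRange = as.integer(crackCountRange),
      crackLengthRangePx = as.numeric(crackLengthRangePx),
      crackWidthRangePx = as.numeric(crackWidthRangePx),
      nucleiLambda = as.numeric(nucleiLambda),
      distractorLambda = as.numeric(distractorLambda),
      distractorKinds = as.character(distractorKinds),
      nucleolusDiamRangeUm = as.numeric(nucleolusDiamRangeUm),
      nucleolusIntensityRange = as.numeric(nucleolusIntensityRange),
      crackIntensityRange = as.numeric(crackIntensityRange),
      nucleusDiamRangeUm = as.numeric(nucleusDiamRangeUm),
      nucleusIntensityRange = as.numeric(nucleusIntensityRange),
      backgroundMean = as.numeric(backgroundMean),
      textureSd = as.numeric(textureSd), noiseSd = as.numeric(noiseSd),
      edgeSoftness = as.numeric(edgeSoftness))
}

#' SceneTruth: exact ground truth of one synthetic tile
#'
#' Object lists (one data.frame per object kind), the rasterized truth
#' mask for each feature role, the latent class label the scene was drawn
#' from, and the seed that makes the scene bit-reproducible.
#'
#' @slot nucleoli data.frame (row, col, diamUm, intensity).
#' @slot cracks list of stroke specifications (path, widthPx, intensity).
#' @slot nuclei data.frame (row, col, diamAUm, diamBUm, angle, intensity).
#' @slot distractors data.frame (kind, row, col, sizePx, intensity).
#' @slot masks named list of [BinaryMask-class] objects
#'   (nucleoli, crack, diff_nuclei).
#' @slot label quality class the recipe belonged to.
#' @slot seed integer seed.
#' @export
setClass("SceneTruth",
         representation(nucleoli = "data.frame", cracks = "list",
                        nuclei = "data.frame", distractors = "data.frame",
                        masks = "list", label = "character",
                        seed = "integer"))
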