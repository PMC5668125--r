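# Synthetic phase-contrast scene generator with exact ground truth.
# Emulates the statistical structure of the labelled / masked / nucleoli
# patch datasets: dark oval nucleoli (3-6 um), bright curvilinear cracks,
# dark ~10 um differentiating nuclei and bright compact distractors on a
# textured feeder background, with class-conditional frequencies that
# reproduce the qualitative ordering of the real data (nucleoli increase
# with quality, cracks concentrate in mod, dark nuclei in poor).

#' Default per-class scene recipes
#'
#' Poor: few nucleoli (Poisson mean 2), differentiating nuclei common
#' (Poisson mean 3), cracks occasional (p = 0.2). Mod: intermediate
#' nucleolus abundance (mean 4), cracks nearly always present (p = 0.9),
#' few nuclei (mean 0.3). Good: abundant nucleoli (mean 8), cracks rare
#' (p = 0.05), few nuclei (mean 0.3). All classes carry occasional bright
#' distractors (dead cells / stacked regions, Poisson mean 0.5).
#'
#' @return named list of [ClassRecipe-class] objects
#'   (`poor`, `mod`, `good`).
#' @export
#' @examples names(defaultRecipes())
defaultRecipes <- function() {
  list(
    poor = classRecipe(lambdaNucleoli = 2, crackProb = 0.2,
                       nucleiLambda = 3, distractorLambda = 0.5),
    mod = classRecipe(lambdaNucleoli = 4, crackProb = 0.9,
                      nucleiLambda = 0.3, distractorLambda = 0.5),
    good = classRecipe(lambdaNucleoli = 8, crackProb = 0.05,
                       nucleiLambda = 0.3, distractorLambda = 0.5))
}

# normalized ellipse coordinate q (q <= 1 inside) over a bounding window
.ellipseQ <- function(dims, row1, col1, aPx, bPx, angle) {
  half <- ceiling(max(aPx, bPx)) + 2L
  r0 <- max(1L, floor(row1 - half)); r1 <- min(dims[1], ceiling(row1 + half))
  c0 <- max(1L, floor(col1 - half)); c1 <- min(dims[2], ceiling(col1 + half))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- (r0:r1) - row1
  cc <- (c0:c1) - col1
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  xr <- C * cos(angle) + R * sin(angle)
  yr <- -C * sin(angle) + R * cos(angle)
  list(q = sqrt((xr / aPx)^2 + (yr / bPx)^2), r0 = r0, r1 = r1,
       c0 = c0, c1 = c1)
}

# composite an ellipse of the given intensity onto img; returns img
.renderEllipse <- function(img, row1, col1, aPx, bPx, angle, intensity,
                           soft) {
  e <- .ellipseQ(dim(img), row1, col1, aPx, bPx, angle)
  if (is.null(e)) return(img)
  alpha <- if (soft > 0) {
    pmin(1, pmax(0, 0.5 + (1 - e$q) * min(aPx, bPx) / soft))
  } else (e$q <= 1) * 1
  win <- img[e$r0:e$r1, e$c0:e$c1]
  img[e$r0:e$r1, e$c0:e$c1] <- (1 - alpha) * win + alpha * intensity
  img
}

.rasterEllipseMask <- function(dims, row0, col0, aPx, bPx, angle) {
  m <- matrix(FALSE, dims[1], dims[2])
  e <- .ellipseQ(dims, row0 + 1, col0 + 1, aPx, bPx, angle)
  if (!is.null(e)) m[e$r0:e$r1, e$c0:e$c1] <- e$q <= 1
  m
}

# pixels within widthPx/2 of any point of a polyline path (1-px steps)
.rasterStrokeMask <- function(dims, path, widthPx) {
  m <- matrix(FALSE, dims[1], dims[2])
  rad <- widthPx / 2
  ir <- ceiling(rad)
  off <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
  pr <- round(path[, 1] + 1)   # path is 0-based
  pc <- round(path[, 2] + 1)
  rr <- outer(pr, off$dr, "+")
  cc <- outer(pc, off$dc, "+")
  ok <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
  m[cbind(rr[ok], cc[ok])] <- TRUE
  m
}

# meandering crack path: unit steps with slowly drifting heading, 0-based
.crackPath <- function(dims, lengthPx) {
  margin <- 3
  p <- c(runif(1, margin, dims[1] - margin),
         runif(1, margin, dims[2] - margin))
  heading <- runif(1, 0, 2 * pi)
  path <- matrix(NA_real_, ceiling(lengthPx), 2)
  for (i in seq_len(nrow(path))) {
    path[i, ] <- p
    heading <- heading + rnorm(1, 0, 0.06)
    p <- p + c(sin(heading), cos(heading))
    if (p[1] < margin || p[1] > dims[1] - margin ||
        p[2] < margin || p[2] > dims[2] - margin) {
      path <- path[seq_len(i), , drop = FALSE]
      break
    }
  }
  path[complete.cases(path), , drop = FALSE] - 1
}

.sceneBackground <- function(dims, recipe) {
  bg <- matrix(recipe@backgroundMean, dims[1], dims[2])
  if (recipe@textureSd > 0) {
    # scale smoothed white noise by its theoretical standard deviation
    # 1/(2*sigma*sqrt(pi)), so the texture amplitude means the same thing
    # on a 27-px patch as on a 150-px tile (a sample-sd normalization
    # would amplify correlated dips on small fields)
    smoothField <- function(sigma, amp) {
      z <- matrix(rnorm(prod(dims)), dims[1], dims[2])
      as.matrix(EBImage::gblur(z, sigma = sigma)) * 2 * sigma * sqrt(pi) * amp
    }
    bg <- bg + smoothField(4, recipe@textureSd) +
      smoothField(1, recipe@textureSd * 0.7)
  }
  bg
}

# rejection-sample a centre at least `clearance(row, col)`-clear of the
# previously placed keep-out discs (matrix with columns row, col, radius)
.placeCentre <- function(dims, margin, keepOut, radius, maxTries = 1000L) {
  for (i in seq_len(maxTries)) {
    p <- c(runif(1, margin, dims[1] - 1 - margin),
           runif(1, margin, dims[2] - 1 - margin))
    if (is.null(keepOut) || nrow(keepOut) == 0L) return(p)
    d <- sqrt((keepOut[, 1] - p[1])^2 + (keepOut[, 2] - p[2])^2)
    if (all(d > keepOut[, 3] + radius)) return(p)
  }
  stop("could not place object after ", maxTries,
       " rejections; scene density too high")
}

#' Generate one synthetic scene with exact ground truth
#'
#' Draws object counts and parameters from the class recipe, renders the
#' scene (background texture, dark nucleoli, bright cracks, dark nuclei,
#' bright distractors, Gaussian pixel noise), and returns the tile
#' together with a [SceneTruth-class] carrying object lists and exact
#' rasterized masks. Nucleoli are rejection-sampled so they never overlap
#' each other, a nucleus, or a distractor. Bit-reproducible for a given
#' seed.
#'
#' @param recipe a [ClassRecipe-class].
#' @param label quality class the recipe represents.
#' @param geom a [PixelGeometry-class].
#' @param seed integer seed.
#' @param dims tile dimensions in pixels (default `c(150, 150)`).
#' @return list with elements `tile` ([RoiTile-class]) and `truth`
#'   ([SceneTruth-class]).
#' @export
generateTile <- function(recipe, label = "good", geom = PixelGeometry(),
                         seed = 1L, dims = c(150L, 150L)) {
  stopifnot(is(recipe, "ClassRecipe"))
  label <- match.arg(label, qualityLevels())
  # recipe rates are per 150x150 tile; larger scenes scale counts by area
  # (Poisson additivity keeps the per-tile statistics exact)
  areaFactor <- prod(dims) / 22500
  withSeed(seed, {
    img <- .sceneBackground(dims, recipe)
    soft <- recipe@edgeSoftness
    keepOut <- matrix(numeric(0), 0, 3)

    # differentiating nuclei: dark ellipses ~10 um
    nNuc <- rpois(1, recipe@nucleiLambda * areaFactor)
    nuclei <- data.frame(row = numeric(0), col = numeric(0),
                         diamAUm = numeric(0), diamBUm = numeric(0),
                         angle = numeric(0), intensity = numeric(0))
    nucMask <- matrix(FALSE, dims[1], dims[2])
    for (i in seq_len(nNuc)) {
      dA <- runif(1, recipe@nucleusDiamRangeUm[1], recipe@nucleusDiamRangeUm[2])
      dB <- dA * runif(1, 0.7, 1)
      aPx <- umToPx(dA, geom) / 2; bPx <- umToPx(dB, geom) / 2
      ang <- runif(1, 0, pi)
      ctr <- .placeCentre(dims, aPx + 2, keepOut, aPx)
      int <- runif(1, recipe@nucleusIntensityRange[1],
                   recipe@nucleusIntensityRange[2])
      img <- .renderEllipse(img, ctr[1] + 1, ctr[2] + 1, aPx, bPx, ang, int,
                            soft)
      nucMask <- nucMask |
        .rasterEllipseMask(dims, ctr[1], ctr[2], aPx, bPx, ang)
      nuclei[i, ] <- list(ctr[1], ctr[2], dA, dB, ang, int)
      keepOut <- rbind(keepOut, c(ctr, aPx + 2))
    }

    # bright distractors: dead cells (single discs) and stacked regions
    nDis <- rpois(1, recipe@distractorLambda * areaFactor)
    distractors <- data.frame(kind = character(0), row = numeric(0),
                              col = numeric(0), sizePx = numeric(0),
                              intensity = numeric(0))
    for (i in seq_len(nDis)) {
      kind <- if (length(recipe@distractorKinds) == 1L) {
        recipe@distractorKinds
      } else sample(recipe@distractorKinds, 1)
      int <- runif(1, 0.78, 0.95)
      if (kind == "dead_cell") {
        rad <- runif(1, 7, 12)
        ctr <- .placeCentre(dims, rad + 2, keepOut, rad)
        img <- .renderEllipse(img, ctr[1] + 1, ctr[2] + 1, rad, rad,
                              0, int, soft)
        keepOut <- rbind(keepOut, c(ctr, rad + 2))
      } else {
        rad <- runif(1, 10, 16)
        ctr <- .placeCentre(dims, rad + 6, keepOut, rad + 4)
        for (j in 1:4) {
          sub <- ctr + rnorm(2, 0, rad / 2)
          subRad <- runif(1, rad * 0.4, rad * 0.7)
          img <- .renderEllipse(img, sub[1] + 1, sub[2] + 1, subRad,
                                subRad * runif(1, 0.8, 1), runif(1, 0, pi),
                                int, soft)
        }
        keepOut <- rbind(keepOut, c(ctr, rad + 6))
      }
      distractors[i, ] <- list(kind, ctr[1], ctr[2], rad, int)
    }

    # nucleoli: dark non-overlapping ellipses 3-6 um
    nNucleoli <- rpois(1, recipe@lambdaNucleoli * areaFactor)
    nucleoli <- data.frame(row = numeric(0), col = numeric(0),
                           diamUm = numeric(0), aspect = numeric(0),
                           angle = numeric(0), intensity = numeric(0))
    nucleoliMask <- matrix(FALSE, dims[1], dims[2])
    for (i in seq_len(nNucleoli)) {
      dUm <- runif(1, recipe@nucleolusDiamRangeUm[1],
                   recipe@nucleolusDiamRangeUm[2])
      aPx <- umToPx(dUm, geom) / 2
      asp <- runif(1, 0.75, 1)
      ang <- runif(1, 0, pi)
      int <- runif(1, recipe@nucleolusIntensityRange[1],
                   recipe@nucleolusIntensityRange[2])
      ctr <- .placeCentre(dims, aPx + 2, keepOut, aPx + 3)
      img <- .renderEllipse(img, ctr[1] + 1, ctr[2] + 1, aPx, aPx * asp,
                            ang, int, soft)
      nucleoliMask <- nucleoliMask |
        .rasterEllipseMask(dims, ctr[1], ctr[2], aPx, aPx * asp, ang)
      nucleoli[i, ] <- list(ctr[1], ctr[2], dUm, asp, ang, int)
      keepOut <- rbind(keepOut, c(ctr, aPx + 3))
    }

    # cracks: bright meandering strokes avoiding nucleoli; each
    # tile-equivalent of area carries an independent crack event
    cracks <- list()
    crackMask <- matrix(FALSE, dims[1], dims[2])
    nCracks <- sum(vapply(seq_len(max(1L, round(areaFactor))), function(re) {
      if (runif(1) < recipe@crackProb)
        sample(seq(recipe@crackCountRange[1], recipe@crackCountRange[2]), 1)
      else 0L
    }, numeric(1)))
    if (nCracks > 0) {
      for (i in seq_len(nCracks)) {
        for (attempt in 1:1000) {
          len <- runif(1, recipe@crackLengthRangePx[1],
                       recipe@crackLengthRangePx[2])
          path <- .crackPath(dims, len)
          if (nrow(path) < 30) next
          w <- runif(1, recipe@crackWidthRangePx[1],
                     recipe@crackWidthRangePx[2])
          clear <- TRUE
          if (nrow(keepOut) > 0) {
            for (kk in seq_len(nrow(keepOut))) {
              d <- sqrt((path[, 1] - keepOut[kk, 1])^2 +
                          (path[, 2] - keepOut[kk, 2])^2)
              if (any(d < keepOut[kk, 3] + w / 2)) { clear <- FALSE; break }
            }
          }
          if (!clear) next
          int <- runif(1, recipe@crackIntensityRange[1],
                       recipe@crackIntensityRange[2])
          sm <- .rasterStrokeMask(dims, path, w)
          img[sm] <- int
          crackMask <- crackMask | sm
          cracks[[length(cracks) + 1L]] <-
            list(path = path, widthPx = w, intensity = int)
          break
        }
      }
    }

    if (recipe@noiseSd > 0)
      img <- img + matrix(rnorm(prod(dims), 0, recipe@noiseSd),
                          dims[1], dims[2])
    img[img < 0] <- 0
    img[img > 1] <- 1

    truth <- new("SceneTruth", nucleoli = nucleoli, cracks = cracks,
                 nuclei = nuclei, distractors = distractors,
                 masks = list(nucleoli = BinaryMask(nucleoliMask, "nucleoli"),
                              crack = BinaryMask(crackMask, "crack"),
                              diff_nuclei = BinaryMask(nucMask,
                                                       "diff_nuclei")),
                 label = label, seed = as.integer(seed))
    list(tile = RoiTile(img), truth = truth)
  })
}

#' Re-rasterize the truth masks of a scene from its object lists
#'
#' Recomputes the three role masks purely from the object parameter lists
#' stored in a [SceneTruth-class]; by construction these must equal the
#' masks rasterized at generation time.
#'
#' @param truth a [SceneTruth-class].
#' @param dims scene dimensions in pixels.
#' @param geom a [PixelGeometry-class].
#' @return named list of logical matrices
#'   (`nucleoli`, `crack`, `diff_nuclei`).
#' @export
rasterizeTruth <- function(truth, dims = c(150L, 150L),
                           geom = PixelGeometry()) {
  stopifnot(is(truth, "SceneTruth"))
  nm <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(nrow(truth@nucleoli))) {
    o <- truth@nucleoli[i, ]
    aPx <- umToPx(o$diamUm, geom) / 2
    nm <- nm | .rasterEllipseMask(dims, o$row, o$col, aPx, aPx * o$aspect,
                                  o$angle)
  }
  cm <- matrix(FALSE, dims[1], dims[2])
  for (cr in truth@cracks)
    cm <- cm | .rasterStrokeMask(dims, cr$path, cr$widthPx)
  dm <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(nrow(truth@nuclei))) {
    o <- truth@nuclei[i, ]
    dm <- dm | .rasterEllipseMask(dims, o$row, o$col,
                                  umToPx(o$diamAUm, geom) / 2,
                                  umToPx(o$diamBUm, geom) / 2, o$angle)
  }
  list(nucleoli = nm, crack = cm, diff_nuclei = dm)
}

#' True feature values of a synthetic scene
#'
#' @param truth a [SceneTruth-class].
#' @return a [FeatureVector-class] computed from the truth masks
#'   (nucleolus count from the object list).
#' @export
truthFeatures <- function(truth) {
  stopifnot(is(truth, "SceneTruth"))
  n <- prod(dim(truth@masks$crack@pixels))
  featureVector(nrow(truth@nucleoli),
                sum(truth@masks$crack@pixels) / n,
                sum(truth@masks$diff_nuclei@pixels) / n)
}

#' Generate a labelled synthetic dataset in memory
#'
#' Draws `nPerClass` tiles per class from the per-class recipes with
#' deterministic per-tile child seeds.
#'
#' @param recipes named list of [ClassRecipe-class]
#'   (default [defaultRecipes()]).
#' @param nPerClass named integer vector, counts for poor/mod/good
#'   (default `c(poor = 401, mod = 259, good = 240)`, the class balance
#'   of the 900-image labelled dataset).
#' @param geom a [PixelGeometry-class].
#' @param seed integer seed.
#' @return list with `tiles` (list of [RoiTile-class]), `truths` (list of
#'   [SceneTruth-class]), and `labels` (ordered factor).
#' @export
generateLabeledTiles <- function(recipes = defaultRecipes(),
                                 nPerClass = c(poor = 401, mod = 259,
                                               good = 240),
                                 geom = PixelGeometry(), seed = 1L) {
  stopifnot(all(qualityLevels() %in% names(recipes)),
            all(names(nPerClass) %in% qualityLevels()), all(nPerClass >= 1))
  labels <- rep(names(nPerClass), nPerClass)
  seeds <- childSeeds(seed, length(labels))
  tiles <- vector("list", length(labels))
  truths <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    g <- generateTile(recipes[[labels[i]]], labels[i], geom, seeds[i])
    tiles[[i]] <- g$tile
    truths[[i]] <- g$truth
  }
  list(tiles = tiles, truths = truths, labels = qualityFactor(labels))
}

#' Write a labelled synthetic dataset to disk
#'
#' Layout: `tiles/tile_0001.tif` (16-bit), per-role masks under
#' `masks/{nucleoli,crack,diff_nuclei}/` (8-bit PNG, 255 = true),
#' `truth_features.csv` (`tile_id,row,col,n_nucleoli,crack_rate,`
#' `diff_nuclei_rate`, truth values), and `labels.csv` (`tile_id,label`).
#'
#' @inheritParams generateLabeledTiles
#' @param dir output directory (created if needed).
#' @param writeMasks write per-role truth masks (default TRUE).
#' @return the truth feature data.frame, invisibly.
#' @export
generateLabeledDataset <- function(dir, recipes = defaultRecipes(),
                                   nPerClass = c(poor = 401, mod = 259,
                                                 good = 240),
                                   geom = PixelGeometry(), seed = 1L,
                                   writeMasks = TRUE) {
  ds <- generateLabeledTiles(recipes, nPerClass, geom, seed)
  dir.create(file.path(dir, "tiles"), recursive = TRUE, showWarnings = FALSE)
  if (writeMasks)
    for (role in .maskRoles)
      dir.create(file.path(dir, "masks", role), recursive = TRUE,
                 showWarnings = FALSE)
  n <- length(ds$tiles)
  ids <- sprintf("tile_%04d", seq_len(n))
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    saveImage(ds$tiles[[i]]@pixels,
              file.path(dir, "tiles", paste0(ids[i], ".tif")))
    if (writeMasks) {
      for (role in .maskRoles) {
        mrole <- if (role == "crack") "crack" else role
        m <- ds$truths[[i]]@masks[[mrole]]@pixels
        png::writePNG(m * 1, file.path(dir, "masks", role,
                                       paste0(ids[i], ".png")))
      }
    }
    fv <- truthFeatures(ds$truths[[i]])
    feats[[i]] <- cbind(tile_id = ids[i], row = 0L, col = 0L,
                        as.data.frame(fv))
  }
  feats <- do.call(rbind, feats)
  writeFeatureTable(feats, file.path(dir, "truth_features.csv"))
  write.csv(data.frame(tile_id = ids, label = as.character(ds$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(feats)
}

#' Generate a nucleolus patch training set
#'
#' Positives: one nucleolus rendered with its centroid at the centre
#' pixel (13, 13; 0-based) of a 27 x 27 patch of background texture.
#' Negatives cycle through background-only patches, crack fragments,
#' nucleus fragments (dark blobs too large to be nucleoli) and off-centre
#' nucleoli.
#'
#' @param nPos,nNeg number of positive/negative patches.
#' @param seed integer seed.
#' @param geom a [PixelGeometry-class].
#' @param recipe a [ClassRecipe-class] supplying background and object
#'   statistics.
#' @param dir optional output directory; when given, patches are written
#'   as `patch_0001.tif`, ... plus `labels.csv` (`patch_id,label`).
#' @return list with `patches` (list of 27 x 27 matrices) and `labels`
#'   (logical vector).
#' @export
generateNucleoliPatches <- function(nPos, nNeg, seed = 1L,
                                    geom = PixelGeometry(),
                                    recipe = classRecipe(), dir = NULL) {
  stopifnot(nPos >= 0, nNeg >= 0)
  side <- 27L
  ctr <- (side - 1) / 2     # 0-based centre = 13
  patches <- vector("list", nPos + nNeg)
  labels <- rep(c(TRUE, FALSE), c(nPos, nNeg))
  negKinds <- c("background", "crack_fragment", "nucleus_fragment",
                "offcentre_nucleolus")
  withSeed(seed, {
    for (i in seq_len(nPos + nNeg)) {
      img <- .sceneBackground(c(side, side), recipe)
      if (labels[i]) {
        dUm <- runif(1, recipe@nucleolusDiamRangeUm[1],
                     recipe@nucleolusDiamRangeUm[2])
        aPx <- umToPx(dUm, geom) / 2
        img <- .renderEllipse(img, ctr + 1, ctr + 1, aPx,
                              aPx * runif(1, 0.75, 1), runif(1, 0, pi),
                              runif(1, recipe@nucleolusIntensityRange[1],
                                    recipe@nucleolusIntensityRange[2]),
                              recipe@edgeSoftness)
      } else {
        kind <- negKinds[(i - nPos - 1L) %% length(negKinds) + 1L]
        if (kind == "crack_fragment") {
          path <- cbind(seq(0, side - 1, by = 0.5),
                        ctr + rnorm(2 * side - 1, 0, 1))
          sm <- .rasterStrokeMask(c(side, side), path, runif(1, 2, 4))
          img[sm] <- runif(1, recipe@crackIntensityRange[1],
                           recipe@crackIntensityRange[2])
        } else if (kind == "nucleus_fragment") {
          aPx <- umToPx(runif(1, 8.5, 11.5), geom) / 2
          img <- .renderEllipse(img, ctr + 1 + rnorm(1, 0, 3),
                                ctr + 1 + rnorm(1, 0, 3), aPx,
                                aPx * runif(1, 0.7, 1), runif(1, 0, pi),
                                runif(1, recipe@nucleusIntensityRange[1],
                                      recipe@nucleusIntensityRange[2]),
                                recipe@edgeSoftness)
        } else if (kind == "offcentre_nucleolus") {
          dUm <- runif(1, recipe@nucleolusDiamRangeUm[1],
                       recipe@nucleolusDiamRangeUm[2])
          aPx <- umToPx(dUm, geom) / 2
          ang <- runif(1, 0, 2 * pi)
          off <- runif(1, 7, 10)
          img <- .renderEllipse(img, ctr + 1 + off * sin(ang),
                                ctr + 1 + off * cos(ang), aPx,
                                aPx * runif(1, 0.75, 1), runif(1, 0, pi),
                                runif(1, recipe@nucleolusIntensityRange[1],
                                      recipe@nucleolusIntensityRange[2]),
                                recipe@edgeSoftness)
        }
      }
      if (recipe@noiseSd > 0)
        img <- img + matrix(rnorm(side * side, 0, recipe@noiseSd), side, side)
      img[img < 0] <- 0
      img[img > 1] <- 1
      patches[[i]] <- img
    }
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ids <- sprintf("patch_%04d", seq_along(patches))
    for (i in seq_along(patches))
      saveImage(patches[[i]], file.path(dir, paste0(ids[i], ".tif")))
    write.csv(data.frame(patch_id = ids, label = as.integer(labels)),
              file.path(dir, "labels.csv"), row.names = FALSE)
  }
  list(patches = patches, labels = labels)
}

#' Simulate multi-rater labels from a confusion matrix
#'
#' Each rater's label is drawn independently from the row of the
#' (row-stochastic) confusion matrix corresponding to the item's true
#' label, emulating inter-expert scoring variation.
#'
#' @param trueLabels true quality labels.
#' @param nRaters number of raters (default 4).
#' @param confusion 3 x 3 row-stochastic matrix, rows/cols in
#'   `qualityLevels()` order (default identity).
#' @param seed integer seed.
#' @return data.frame `tile_id,rater,label`.
#' @export
generateRaterLabels <- function(trueLabels, nRaters = 4L,
                                confusion = diag(3), seed = 1L) {
  y <- qualityFactor(trueLabels)
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(3L, 3L)) ||
      any(abs(rowSums(confusion) - 1) > 1e-8) || any(confusion < 0))
    stop("confusion must be a 3 x 3 row-stochastic matrix")
  lev <- qualityLevels()
  n <- length(y)
  withSeed(seed, {
    out <- data.frame(
      tile_id = rep(seq_len(n), each = nRaters),
      rater = rep(seq_len(nRaters), n),
      label = unlist(lapply(seq_len(n), function(i) {
        sample(lev, nRaters, replace = TRUE,
               prob = confusion[match(y[i], lev), ])
      })))
  })
  out$label <- qualityFactor(out$label)
  out
}

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth (%s, seed %d): %d nucleoli, %d crack(s), %d nuclei, %d distractor(s)\n",
    object@label, object@seed, nrow(object@nucleoli), length(object@cracks),
    nrow(object@nuclei), nrow(object@distractors)))
})

setMethod("show", "ClassRecipe", function(object) {
  cat(sprintf(
    "ClassRecipe: nucleoli ~ Pois(%.2g), crack p=%.2g, nuclei ~ Pois(%.2g), distractors ~ Pois(%.2g)\n",
    object@lambdaNucleoli, object@crackProb, object@nucleiLambda,
    object@distractorLambda))
})
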