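#' @importFrom stats fft quantile rnorm rpois runif sd var median mad
#'   complete.cases setNames lm predict
#' @importFrom utils read.csv write.csv head
NULL

# ---- accessors ------------------------------------------------------------

#' Pixel pitch accessor
#' @param x a [PixelGeometry-class].
#' @return micrometres per pixel.
#' @export
setGeneric("umPerPx", function(x) standardGeneric("umPerPx"))

#' @rdname umPerPx
#' @export
setMethod("umPerPx", "PixelGeometry", function(x) x@umPerPx)

#' Pixel data accessors
#'
#' `imagePixels` returns the intensity matrix of a tile, `maskPixels` the
#' logical matrix of a mask, `maskRole` its role, `tileOrigin` the 0-based
#' (row, col) of a tile in its parent frame, and `maskArea` the number of
#' TRUE pixels.
#'
#' @param x a [RoiTile-class] or [BinaryMask-class].
#' @return See description.
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname imagePixels
#' @export
setMethod("imagePixels", "RoiTile", function(x) x@pixels)

#' @rdname imagePixels
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' @rdname imagePixels
#' @export
setMethod("maskPixels", "BinaryMask", function(x) x@pixels)

#' @rdname imagePixels
#' @export
setGeneric("maskRole", function(x) standardGeneric("maskRole"))

#' @rdname imagePixels
#' @export
setMethod("maskRole", "BinaryMask", function(x) x@role)

#' @rdname imagePixels
#' @export
setGeneric("tileOrigin", function(x) standardGeneric("tileOrigin"))

#' @rdname imagePixels
#' @export
setMethod("tileOrigin", "RoiTile", function(x) x@origin)

#' @rdname imagePixels
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))

#' @rdname imagePixels
#' @export
setMethod("maskArea", "BinaryMask", function(x) sum(x@pixels))

#' @describeIn FeatureVector-class Coerce to a one-row data.frame with
#'   columns `n_nucleoli`, `crack_rate`, `diff_nuclei_rate`.
#' @param x a `FeatureVector`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "FeatureVector", function(x, ...) {
  data.frame(n_nucleoli = x@nNucleoli, crack_rate = x@crackRate,
             diff_nuclei_rate = x@diffNucleiRate)
})

setMethod("show", "PixelGeometry", function(object) {
  cat(sprintf("PixelGeometry: %.6g um/px (150 px = %.4g um)\n",
              object@umPerPx, 150 * object@umPerPx))
})

setMethod("show", "RoiTile", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RoiTile %dx%d px at origin (%d, %d), intensity [%.3f, %.3f]\n",
              d[1], d[2], object@origin[1], object@origin[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask (%s) %dx%d px, area %d px\n", object@role,
              d[1], d[2], sum(object@pixels)))
})

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf(
    "FeatureVector: n_nucleoli=%d crack_rate=%.4f diff_nuclei_rate=%.4f\n",
    object@nNucleoli, object@crackRate, object@diffNucleiRate))
})

# ---- physical units -------------------------------------------------------

#' Convert physical lengths to pixels and back
#'
#' `umToPx` converts micrometres to integer pixels (round half up);
#' `pxToUm` converts pixels back to micrometres. At the default pitch of
#' 1/3 micrometre per pixel, 50 micrometres is 150 pixels.
#'
#' @param dUm lengths in micrometres (non-negative).
#' @param px lengths in pixels.
#' @param geom a [PixelGeometry-class].
#' @return `umToPx`: integer pixels; `pxToUm`: micrometres.
#' @export
#' @examples
#' umToPx(50, PixelGeometry())   # 150
#' umToPx(6, PixelGeometry())    # 18
umToPx <- function(dUm, geom = PixelGeometry()) {
  stopifnot(is(geom, "PixelGeometry"))
  if (any(!is.finite(dUm)) || any(dUm < 0))
    stop("lengths in micrometres must be finite and non-negative")
  as.integer(floor(dUm / geom@umPerPx + 0.5))
}

#' @rdname umToPx
#' @export
pxToUm <- function(px, geom = PixelGeometry()) {
  stopifnot(is(geom, "PixelGeometry"))
  as.numeric(px) * geom@umPerPx
}

# ---- image I/O ------------------------------------------------------------

#' Load a phase-contrast image
#'
#' Reads a single-channel TIFF or PNG and returns an intensity matrix
#' normalized to [0, 1] (8/16-bit sources are rescaled by the maximum
#' representable value). Multi-channel input is collapsed by the unweighted
#' channel mean: phase contrast is intrinsically single-channel, so colour
#' planes are display artifacts.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return numeric matrix with values in [0, 1].
#' @seealso [saveImage()]
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "': ", path))
  if (is.list(img)) img <- img[[1]]   # multi-page TIFF: first page
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  if (!is.matrix(img)) img <- as.matrix(img)
  if (length(img) == 0L || any(dim(img) == 0L))
    stop("zero-sized image: ", path)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Save an intensity matrix as a 16-bit TIFF or PNG
#'
#' @param img numeric matrix in [0, 1].
#' @param path output path; format chosen by extension.
#' @param bitsPerSample TIFF bit depth (8 or 16; default 16).
#' @return `path`, invisibly.
#' @export
saveImage <- function(img, path, bitsPerSample = 16L) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path,
                                   bits.per.sample = as.integer(bitsPerSample)),
    png = png::writePNG(img, path),
    stop("unsupported image format '", ext, "'"))
  invisible(path)
}

# ---- tiling ---------------------------------------------------------------

#' Cut a frame into regions of interest
#'
#' Windows of `tilePx` x `tilePx` pixels at origins that are multiples of
#' `stridePx`, in raster order. Only windows fully inside the frame are
#' returned; partial edge windows are discarded, never padded.
#'
#' @param img numeric intensity matrix in [0, 1].
#' @param tilePx window side in pixels (default 150).
#' @param stridePx origin spacing in pixels (default `tilePx`,
#'   i.e. non-overlapping tiling; 50 reproduces the scanning stride).
#' @return list of [RoiTile-class] objects.
#' @export
#' @examples
#' img <- matrix(runif(300 * 450), 300, 450)
#' length(tileImage(img))  # 2 x 3 = 6 tiles
tileImage <- function(img, tilePx = 150L, stridePx = tilePx) {
  stopifnot(is.matrix(img))
  tilePx <- as.integer(tilePx)
  stridePx <- as.integer(stridePx)
  if (stridePx < 1L) stop("stridePx must be >= 1")
  if (tilePx > min(dim(img)))
    stop(sprintf("tile (%d px) larger than image (%d x %d)",
                 tilePx, nrow(img), ncol(img)))
  rows <- seq(0L, nrow(img) - tilePx, by = stridePx)
  cols <- seq(0L, ncol(img) - tilePx, by = stridePx)
  out <- vector("list", length(rows) * length(cols))
  i <- 1L
  for (r in rows) {      # raster order: sweep columns within each row band
    for (cc in cols) {
      out[[i]] <- RoiTile(img[(r + 1L):(r + tilePx), (cc + 1L):(cc + tilePx)],
                          origin = c(r, cc))
      i <- i + 1L
    }
  }
  out
}

# ---- area rates -----------------------------------------------------------

.maskAreaRate <- function(mask, tile) {
  stopifnot(is(mask, "BinaryMask"), is(tile, "RoiTile"))
  if (!identical(dim(mask@pixels), dim(tile@pixels)))
    stop("mask shape ", paste(dim(mask@pixels), collapse = "x"),
         " does not match tile shape ",
         paste(dim(tile@pixels), collapse = "x"))
  sum(mask@pixels) / length(tile@pixels)
}

#' Crack area rate of a tile
#'
#' Fraction of tile pixels covered by the crack mask (for a 150 x 150
#' tile, true pixels / 22500).
#'
#' @param mask a [BinaryMask-class] with role `"crack"`.
#' @param tile the [RoiTile-class] the mask annotates.
#' @return value in [0, 1].
#' @export
crackAreaRate <- function(mask, tile) .maskAreaRate(mask, tile)

#' Differentiating-nuclei area rate of a tile
#'
#' @param mask a [BinaryMask-class] with role `"diff_nuclei"`.
#' @param tile the [RoiTile-class] the mask annotates.
#' @return value in [0, 1].
#' @export
diffNucleiAreaRate <- function(mask, tile) .maskAreaRate(mask, tile)

# ---- tables ---------------------------------------------------------------

#' Read and write feature tables
#'
#' CSV with header `tile_id,row,col,n_nucleoli,crack_rate,diff_nuclei_rate`.
#'
#' @param x data.frame with those columns.
#' @param path CSV path.
#' @return `readFeatureTable`: the data.frame; `writeFeatureTable`:
#'   `path`, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  need <- c("tile_id", "row", "col", "n_nucleoli", "crack_rate",
            "diff_nuclei_rate")
  stopifnot(all(need %in% names(x)))
  write.csv(x[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tile_id", "n_nucleoli", "crack_rate", "diff_nuclei_rate")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("feature table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  x
}

#' Read a multi-rater label table
#'
#' CSV with header `tile_id,rater,label`, label among `qualityLevels()`.
#'
#' @param path CSV path.
#' @return data.frame with `label` as an ordered quality factor.
#' @export
readLabelTable <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("tile_id", "label"), names(x))
  if (length(miss))
    stop("label table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  x$label <- qualityFactor(x$label)
  x
}

# ---- flat key-value configuration ----------------------------------------

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line (TOML-style scalars); `#` starts a
#' comment. Values that parse as numbers become numeric, comma-separated
#' numbers become numeric vectors, everything else stays character. Keys
#' use dotted names, e.g. `geometry.um_per_px`, `gabor.response_threshold`.
#'
#' @param path file path.
#' @param overrides optional character vector of `key=value` strings
#'   applied after the file (CLI `--set` semantics).
#' @return named list.
#' @export
readConfig <- function(path = NULL, overrides = character()) {
  lines <- character()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    lines <- readLines(path, warn = FALSE)
  }
  lines <- c(lines, overrides)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    val <- gsub('^"|"$', "", val)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

.cfgGet <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Build configuration objects from a flat config list
#'
#' Maps dotted keys from [readConfig()] onto the package's configuration
#' classes, falling back to the documented defaults for absent keys.
#'
#' @param cfg named list from [readConfig()] (may be empty).
#' @return `configGeometry`: [PixelGeometry-class];
#'   `configGaborBank`: [GaborBankConfig-class];
#'   `configNucleiDetector`: [NucleiDetectorConfig-class];
#'   `configNucleoliDetector`: [NucleoliDetectorConfig-class].
#' @export
configGeometry <- function(cfg = list()) {
  PixelGeometry(.cfgGet(cfg, "geometry.um_per_px", 1 / 3))
}

#' @rdname configGeometry
#' @export
configGaborBank <- function(cfg = list()) {
  gaborBankConfig(
    nOrientations = .cfgGet(cfg, "gabor.n_orientations", 8L),
    wavelengthsPx = .cfgGet(cfg, "gabor.wavelengths_px", c(4, 8, 12)),
    sigmaFactor = .cfgGet(cfg, "gabor.sigma_factor", 0.5),
    aspect = .cfgGet(cfg, "gabor.aspect", 1),
    edgeSuppression = .cfgGet(cfg, "gabor.edge_suppression", 0.5),
    responseThreshold = .cfgGet(cfg, "gabor.response_threshold", 0.3),
    responseFloor = .cfgGet(cfg, "gabor.response_floor", 0.25),
    minElongation = .cfgGet(cfg, "gabor.min_elongation", 3),
    minAreaPx = .cfgGet(cfg, "gabor.min_area_px", 20L),
    minRidgeContrast = .cfgGet(cfg, "gabor.min_ridge_contrast", 0.15))
}

#' @rdname configGeometry
#' @export
configNucleiDetector <- function(cfg = list()) {
  nucleiDetectorConfig(
    sourcePercentile = .cfgGet(cfg, "nuclei.source_percentile", 2),
    sinkPercentile = .cfgGet(cfg, "nuclei.sink_percentile", 60),
    diamRangeUm = .cfgGet(cfg, "nuclei.diam_range_um", c(7, 15)),
    minRoundness = .cfgGet(cfg, "nuclei.min_roundness", 0.6),
    iterations = .cfgGet(cfg, "nuclei.iterations", 5L),
    minSpread = .cfgGet(cfg, "nuclei.min_spread", 0.05),
    smoothness = .cfgGet(cfg, "nuclei.smoothness", 2))
}

#' @rdname configGeometry
#' @export
configNucleoliDetector <- function(cfg = list()) {
  nucleoliDetectorConfig(
    k = .cfgGet(cfg, "nucleoli.k", 2.5),
    diamRangeUm = .cfgGet(cfg, "nucleoli.diam_range_um", c(2, 8)),
    windowFactor = .cfgGet(cfg, "nucleoli.window_factor", 3))
}

# ---- internal helpers -----------------------------------------------------

# Run code with a local, restored RNG state so generators are pure
# functions of their seed argument.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds below 2^31 derived from one parent seed.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

# Windowed mean and standard deviation via integral images, with optional
# per-pixel exclusion mask. Windows are clipped at the image border; the
# divisor is the number of included pixels actually inside each window.
boxStats <- function(img, win, exclude = NULL) {
  stopifnot(win %% 2L == 1L)
  h <- (win - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  inc <- if (is.null(exclude)) matrix(1, nr, nc) else (!exclude) * 1
  s1 <- img * inc
  s2 <- img * img * inc
  intImg <- function(m) {
    p <- matrix(0, nr + 1L, nc + 1L)
    p[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
    p
  }
  I1 <- intImg(s1); I2 <- intImg(s2); In <- intImg(inc)
  r0 <- pmax(seq_len(nr) - h, 1L); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h, 1L); c1 <- pmin(seq_len(nc) + h, nc)
  boxSum <- function(P) {
    P[r1 + 1L, c1 + 1L] - P[r0, c1 + 1L] - P[r1 + 1L, c0] + P[r0, c0]
  }
  n <- boxSum(In)
  sum1 <- boxSum(I1)
  sum2 <- boxSum(I2)
  ok <- n > 0
  mu <- matrix(NA_real_, nr, nc)
  sg <- matrix(NA_real_, nr, nc)
  mu[ok] <- sum1[ok] / n[ok]
  sg[ok] <- sqrt(pmax(0, sum2[ok] / n[ok] - mu[ok]^2))
  # windows with no usable pixels fall back to the global included stats
  if (any(!ok)) {
    gi <- if (is.null(exclude)) img else img[!exclude]
    gmu <- if (length(gi)) mean(gi) else mean(img)
    gsd <- if (length(gi) > 1L) sd(gi) else 0
    mu[!ok] <- gmu
    sg[!ok] <- gsd
  }
  list(mean = mu, sd = sg)
}

# Shape statistics of one connected component given its pixel indices.
# Perimeter follows the boundary chain (EBImage::ocontour): unit steps
# count 1, diagonal steps sqrt(2); isolated/line-degenerate contours get
# the 1-px perimeter floor of 4. Second moments are regularized by the
# 1/12 pixel-extent term so 1-px-wide shapes have finite elongation.
componentShape <- function(rows, cols) {
  area <- length(rows)
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  sub <- matrix(0L, r1 - r0 + 3L, c1 - c0 + 3L)
  sub[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1L
  ct <- EBImage::ocontour(sub)
  perim <- 4
  if (length(ct) >= 1L && nrow(ct[[1L]]) >= 2L) {
    p <- ct[[1L]]
    d <- sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2))
    perim <- max(sum(d), 4)
  }
  vr <- var(rows) * (area - 1) / area + 1 / 12
  vc <- var(cols) * (area - 1) / area + 1 / 12
  if (area == 1L) vr <- vc <- 1 / 12
  cv <- if (area > 1L) {
    sum((rows - mean(rows)) * (cols - mean(cols))) / area
  } else 0
  tr <- vr + vc
  det <- vr * vc - cv * cv
  disc <- sqrt(max(0, tr * tr / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-9)
  list(area = area, perimeter = perim,
       roundness = min(1, 4 * pi * area / perim^2),
       eccentricity = sqrt(max(0, 1 - l2 / l1)),
       elongation = sqrt(l1 / l2),
       centroid = c(mean(rows), mean(cols)),
       bbox = c(r0, r1, c0, c1))
}
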