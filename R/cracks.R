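# Crack detection: bright curvilinear intercellular gaps found with a
# quadrature Gabor filter bank (even/ridge phase minus a fraction of the
# odd/edge-phase magnitude), followed by component gates that keep thin,
# high-luminance, locally contrasted ridges and reject bright but compact
# or edge-generated structures (dead cells, stacked regions, their rims).

# One Gabor kernel. Even (cosine) phase is made exactly zero-mean so
# constant regions respond zero; the odd (sine) phase is zero-mean by
# symmetry. Both are L2-normalized so responses are comparable across
# wavelengths.
.gaborKernel <- function(lambda, theta, sigma, aspect, phase = c("even", "odd")) {
  phase <- match.arg(phase)
  half <- max(3L, ceiling(3 * sigma))
  g <- expand.grid(y = -half:half, x = -half:half)
  xr <- g$x * cos(theta) + g$y * sin(theta)    # across-ridge coordinate
  yr <- -g$x * sin(theta) + g$y * cos(theta)   # along-ridge coordinate
  env <- exp(-(xr^2 + (aspect * yr)^2) / (2 * sigma^2))
  k <- if (phase == "even") env * cos(2 * pi * xr / lambda)
       else env * sin(2 * pi * xr / lambda)
  if (phase == "even") k <- k - env * sum(k) / sum(env)
  k <- k / sqrt(sum(k^2))
  matrix(k, nrow = 2L * half + 1L)
}

# FFT plans are cached per (image size, bank parameters): complex kernel
# FFTs (even + i*odd) are precomputed once at the padded size and reused
# for every tile. `calib` is the bank's response to a unit-contrast 3-px
# ridge, the reference scale for the normalization floor.
.gaborCache <- new.env(parent = emptyenv())

.gaborBank <- function(cfg, dims) {
  key <- paste(c(dims, cfg@nOrientations, cfg@wavelengthsPx,
                 cfg@sigmaFactor, cfg@aspect), collapse = "_")
  hit <- .gaborCache[[key]]
  if (!is.null(hit)) return(hit)
  nOr <- cfg@nOrientations
  thetas <- seq(0, pi, length.out = nOr + 1L)[-(nOr + 1L)]
  kernels <- list()
  calib <- 0
  maxHalf <- 0L
  for (lam in cfg@wavelengthsPx) {
    sigma <- cfg@sigmaFactor * lam
    E0 <- .gaborKernel(lam, 0, sigma, cfg@aspect, "even")
    h0 <- (nrow(E0) - 1L) %/% 2L
    xr0 <- matrix(rep(-h0:h0, each = nrow(E0)), nrow(E0))
    calib <- max(calib, sum(E0[abs(xr0) <= 1.5]))
    for (th in thetas) {
      E <- .gaborKernel(lam, th, sigma, cfg@aspect, "even")
      O <- .gaborKernel(lam, th, sigma, cfg@aspect, "odd")
      kernels[[length(kernels) + 1L]] <- matrix(complex(real = E,
                                                        imaginary = O),
                                                nrow(E))
      maxHalf <- max(maxHalf, (nrow(E) - 1L) %/% 2L)
    }
  }
  pad <- maxHalf
  goodSize <- function(n) {
    while (TRUE) {
      m <- n
      for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
      if (m == 1L) return(n)
      n <- n + 1L
    }
  }
  P <- c(goodSize(dims[1] + 2L * pad), goodSize(dims[2] + 2L * pad))
  kernelFfts <- lapply(kernels, function(k) {
    half <- (nrow(k) - 1L) %/% 2L
    km <- matrix(complex(real = 0, imaginary = 0), P[1], P[2])
    ri <- ((-half:half) %% P[1]) + 1L     # centre kernel at (1,1), wrapped
    ci <- ((-half:half) %% P[2]) + 1L
    km[ri, ci] <- k
    fft(km)
  })
  bank <- list(P = P, pad = pad, dims = dims, kernelFfts = kernelFfts,
               calib = calib)
  .gaborCache[[key]] <- bank
  bank
}

#' Gabor ridge response of a tile
#'
#' Per-pixel maximum, over the bank's orientations and wavelengths, of
#' the quadrature ridge measure: the positive part of the even-symmetric
#' (cosine-phase, zero-mean) Gabor response minus `edgeSuppression` times
#' the magnitude of the odd-phase response. The even phase peaks on
#' ridges, the odd phase on edges, so the difference responds to bright
#' lines while suppressing the flanks of bright blobs. The map is
#' normalized to [0, 1] per tile; the normalizing maximum is floored at
#' `responseFloor` times the bank's response to a unit-contrast 3-px
#' reference ridge, so a tile containing no ridge-like structure does not
#' have its noise amplified to full scale. The tile is replicate-padded
#' before the FFT-domain convolution, and constant tiles return an
#' all-zero map.
#'
#' @param tile a [RoiTile-class].
#' @param cfg a [GaborBankConfig-class].
#' @return numeric matrix, same shape as the tile, values in [0, 1].
#' @export
gaborResponse <- function(tile, cfg = gaborBankConfig()) {
  stopifnot(is(tile, "RoiTile"), is(cfg, "GaborBankConfig"))
  img <- tile@pixels
  dims <- dim(img)
  bank <- .gaborBank(cfg, dims)
  pad <- bank$pad; P <- bank$P
  ri <- c(rep(1L, pad), seq_len(dims[1]), rep(dims[1], P[1] - dims[1] - pad))
  ci <- c(rep(1L, pad), seq_len(dims[2]), rep(dims[2], P[2] - dims[2] - pad))
  Fimg <- fft(img[ri, ci])
  resp <- matrix(0, dims[1], dims[2])
  sel1 <- pad + seq_len(dims[1])
  sel2 <- pad + seq_len(dims[2])
  for (K in bank$kernelFfts) {
    r <- fft(Fimg * K, inverse = TRUE) / prod(P)
    e <- Re(r)[sel1, sel2]
    o <- Im(r)[sel1, sel2]
    resp <- pmax(resp, pmax(e, 0) - cfg@edgeSuppression * abs(o))
  }
  resp <- pmax(resp, 0)
  top <- max(max(resp), cfg@responseFloor * bank$calib)
  if (max(resp) < 1e-9) return(matrix(0, dims[1], dims[2]))
  resp / top
}

#' Detect crack regions in a tile
#'
#' Thresholds the normalized ridge response at `cfg@responseThreshold`,
#' then keeps connected components that pass all of:
#' \itemize{
#'   \item area at least `cfg@minAreaPx` (specks are noise);
#'   \item high luminance: component mean intensity above the tile's
#'     75th percentile;
#'   \item linear shape: second-moment elongation (major/minor axis
#'     ratio) at least `cfg@minElongation`, or curvature-invariant
#'     thinness `perimeter^2 / (4 pi area)` at least the same bound
#'     (strongly curved cracks have low moment elongation but stay thin);
#'   \item not a closed contour: filled-hull area at most 1.5x the
#'     component area (bright blob rims form rings; cracks do not
#'     enclose anything);
#'   \item locally contrasted: component mean minus the mean of its
#'     non-candidate surround at least `cfg@minRidgeContrast` (a crack
#'     is brighter than the cells flanking it, whereas an arc hugging a
#'     bright dead cell is not brighter than its surround).
#' }
#'
#' @param tile a [RoiTile-class].
#' @param cfg a [GaborBankConfig-class].
#' @return a [BinaryMask-class] with role `"crack"`.
#' @export
detectCracks <- function(tile, cfg = gaborBankConfig()) {
  resp <- gaborResponse(tile, cfg)
  img <- tile@pixels
  nr <- nrow(img); nc <- ncol(img)
  cand <- resp >= cfg@responseThreshold
  out <- matrix(FALSE, nr, nc)
  if (any(cand)) {
    lab <- .labelConnected8(cand)
    idx <- which(cand)
    lumGate <- quantile(img, 0.75)
    for (p in split(idx, lab[idx])) {
      if (length(p) < cfg@minAreaPx) next
      compMean <- mean(img[p])
      if (compMean <= lumGate) next
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      sh <- componentShape(pr, pc)
      thinness <- 1 / max(sh$roundness, 1e-9)
      if (sh$elongation < cfg@minElongation &&
          thinness < cfg@minElongation) next
      m <- 4L
      r0 <- max(sh$bbox[1] - m, 1L); r1 <- min(sh$bbox[2] + m, nr)
      c0 <- max(sh$bbox[3] - m, 1L); c1 <- min(sh$bbox[4] + m, nc)
      sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      sub[cbind(pr - r0 + 1L, pc - c0 + 1L)] <- TRUE
      if (sum(EBImage::fillHull(sub * 1) > 0) / length(p) > 1.5) next
      ring <- (EBImage::dilate(sub * 1, EBImage::makeBrush(9L, "disc")) > 0) &
        !sub & !cand[r0:r1, c0:c1]
      if (any(ring) &&
          compMean - mean(img[r0:r1, c0:c1][ring]) < cfg@minRidgeContrast)
        next
      out[p] <- TRUE
    }
  }
  BinaryMask(out, role = "crack")
}
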