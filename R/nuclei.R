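# Differentiating-nuclei detection: dark, round-to-oval regions around
# 10 um segmented by a seeded iterative graph cut, then shape/size
# selection and the area-rate feature.

#' Segment dark regions of a tile by seeded iterative graph cut
#'
#' Pixels below the `sourcePercentile` intensity quantile are sure
#' foreground (hard-linked to the source), pixels above the
#' `sinkPercentile` quantile sure background (hard-linked to the sink);
#' the remainder is decided by a minimum cut. Because hard source seeds
#' can never be relabelled, the source percentile deliberately
#' undershoots the area fraction dark objects typically occupy, claiming
#' only object cores; the cut then grows them outward. Unary terms are
#' negative Gaussian log-likelihoods under foreground/background
#' intensity models estimated robustly (median/MAD) from the current
#' segmentation; pairwise terms are contrast-modulated
#' (`smoothness * exp(-(dI)^2 / (2 * sigma^2))`, `sigma^2` the mean
#' squared neighbour difference) on the 4-neighbour grid. Models and cut
#' are iterated `iterations` rounds, and the final mask is opened with a
#' 1-px-radius disc to strip specks and thin tendrils. Tiles with an
#' intensity spread (p90 - p10) below `minSpread` have no contrast to
#' segment and return an empty mask.
#'
#' @param tile a [RoiTile-class].
#' @param cfg a [NucleiDetectorConfig-class].
#' @return a [BinaryMask-class] with role `"diff_nuclei"` marking dark
#'   foreground.
#' @export
segmentDarkRegions <- function(tile, cfg = nucleiDetectorConfig()) {
  stopifnot(is(tile, "RoiTile"), is(cfg, "NucleiDetectorConfig"))
  img <- tile@pixels
  nr <- nrow(img); nc <- ncol(img)
  # spread measured between extreme quantiles: a single dark nucleus
  # covers only a few percent of the tile, so bulk quantiles like
  # p10/p90 would miss it and wrongly declare the tile contrast-free
  q <- quantile(img, c(0.005, 0.995, cfg@sourcePercentile / 100,
                       cfg@sinkPercentile / 100), names = FALSE)
  if (q[2] - q[1] < cfg@minSpread)
    return(BinaryMask(matrix(FALSE, nr, nc), role = "diff_nuclei"))

  sureFg <- img <= q[3]
  sureBg <- img >= q[4]
  BIG <- 1e6
  sdFloor <- 0.01

  dH <- img[, -1L, drop = FALSE] - img[, -nc, drop = FALSE]
  dV <- img[-1L, , drop = FALSE] - img[-nr, , drop = FALSE]
  sig2 <- mean(c(dH^2, dV^2))
  if (sig2 <= 0) sig2 <- 1e-6
  wRight <- cfg@smoothness * exp(-dH^2 / (2 * sig2))
  wDown <- cfg@smoothness * exp(-dV^2 / (2 * sig2))

  fg <- sureFg
  for (it in seq_len(cfg@iterations)) {
    # robust location/scale: keeps the foreground model peaked on truly
    # dark pixels instead of letting the background's dark tail broaden
    # it (the snowball that drags texture into the cut)
    fgPix <- img[fg | sureFg]
    bgPix <- img[(!fg & !sureFg) | sureBg]
    muF <- median(fgPix); sdF <- max(mad(fgPix), sdFloor)
    muB <- median(bgPix); sdB <- max(mad(bgPix), sdFloor)
    if (!is.finite(muF) || !is.finite(sdF)) { muF <- q[3]; sdF <- sdFloor }
    if (!is.finite(muB) || !is.finite(sdB)) { muB <- q[4]; sdB <- sdFloor }
    dataFg <- (img - muF)^2 / (2 * sdF^2) + log(sdF)
    dataBg <- (img - muB)^2 / (2 * sdB^2) + log(sdB)
    capSrc <- pmin(dataBg, BIG / 2)   # cost of being background
    capSnk <- pmin(dataFg, BIG / 2)   # cost of being foreground
    capSrc[sureFg] <- BIG; capSnk[sureFg] <- 0
    capSnk[sureBg] <- BIG; capSrc[sureBg] <- 0
    # only the net terminal capacity matters for the cut (equal parts on
    # both terminals cancel up to a constant); halving the terminal arcs
    # speeds the max-flow up considerably
    net <- capSrc - capSnk
    newFg <- .gridMinCut(pmax(net, 0), pmax(-net, 0), wRight, wDown)
    changed <- sum(newFg != fg)
    fg <- newFg
    if (changed <= length(fg) * 0.001) break  # converged
  }
  # 1-px-radius opening: strips isolated specks and thin texture tendrils
  # off object boundaries without meaningfully eroding ~30-px nuclei
  fg <- EBImage::opening(fg * 1, EBImage::makeBrush(3L, "disc")) > 0
  BinaryMask(fg, role = "diff_nuclei")
}

#' Select nucleus-like components from a dark-region mask
#'
#' Keeps connected components whose equivalent diameter falls inside
#' `cfg@diamRangeUm` (default 7-15 micrometres, bracketing the ~10
#' micrometre biology while excluding the 3-6 micrometre nucleolus size
#' class) and whose roundness `4*pi*area/perimeter^2` is at least
#' `cfg@minRoundness`.
#'
#' @param mask a [BinaryMask-class] from [segmentDarkRegions()].
#' @param cfg a [NucleiDetectorConfig-class].
#' @param geom a [PixelGeometry-class].
#' @return a [BinaryMask-class] with role `"diff_nuclei"`.
#' @export
selectNuclei <- function(mask, cfg = nucleiDetectorConfig(),
                         geom = PixelGeometry()) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@pixels
  out <- matrix(FALSE, nrow(m), ncol(m))
  if (any(m)) {
    lab <- .labelConnected8(m)
    idx <- which(m)
    for (p in split(idx, lab[idx])) {
      equivDiamUm <- 2 * sqrt(length(p) / pi) * geom@umPerPx
      if (equivDiamUm < cfg@diamRangeUm[1] ||
          equivDiamUm > cfg@diamRangeUm[2]) next
      pr <- (p - 1L) %% nrow(m) + 1L
      pc <- (p - 1L) %/% nrow(m) + 1L
      sh <- componentShape(pr, pc)
      if (sh$roundness >= cfg@minRoundness) out[p] <- TRUE
    }
  }
  BinaryMask(out, role = "diff_nuclei")
}

#' Detect differentiating nuclei in one step
#'
#' Convenience wrapper: [segmentDarkRegions()] then [selectNuclei()].
#'
#' @inheritParams segmentDarkRegions
#' @param geom a [PixelGeometry-class].
#' @return a [BinaryMask-class] with role `"diff_nuclei"`.
#' @export
detectNuclei <- function(tile, cfg = nucleiDetectorConfig(),
                         geom = PixelGeometry()) {
  selectNuclei(segmentDarkRegions(tile, cfg), cfg, geom)
}
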