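# Shared fixtures, built lazily once per session and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# independent brute-force implementation of the plurality-then-lowest
# vote aggregation rule, the oracle for enumeration checks
bruteAggregate <- function(labels) {
  lev <- qualityLevels()
  counts <- vapply(lev, function(l) sum(labels == l), integer(1))
  for (l in lev)   # worst-to-best order: first maximum is the tie-winner
    if (counts[l] == max(counts)) return(l)
}

# small blob SVM for unit tests (the acceptance suite trains its own)
testBlobModel <- function() {
  memo("blobModel", function() {
    pd <- generateNucleoliPatches(80, 80, seed = 9001)
    suppressWarnings(trainBlobSvm(pd$patches, pd$labels, seed = 9001))
  })
}

# flat-background recipe: constant background, hard-edged objects,
# no texture or noise -- the regime where adaptive thresholding must
# agree exactly with a global threshold
flatRecipe <- function(lambdaNucleoli = 6, ...) {
  classRecipe(lambdaNucleoli = lambdaNucleoli, textureSd = 0, noiseSd = 0,
              edgeSoftness = 0, ...)
}

# draw a hard-edged dark disc on a constant background
discTile <- function(diamPx, bg = 0.6, fg = 0.3, dims = c(150L, 150L),
                     centre = (dims + 1) / 2) {
  img <- matrix(bg, dims[1], dims[2])
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  img[(rr - centre[1])^2 + (cc - centre[2])^2 <= (diamPx / 2)^2] <- fg
  RoiTile(img)
}

# independent oracle: global threshold + flood-fill connected components
# (8-connectivity), written without the package's labelling code
oracleComponents <- function(img, threshold) {
  dark <- img < threshold
  nr <- nrow(img)
  lab <- matrix(0L, nr, ncol(img))
  comps <- list()
  for (start in which(dark & lab == 0L)) {
    if (lab[start] != 0L) next
    queue <- start
    lab[start] <- 1L
    members <- integer(0)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- c(members, p)
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        qr <- pr + dr; qc <- pc + dc
        if (qr < 1 || qr > nr || qc < 1 || qc > ncol(img)) next
        q <- (qc - 1L) * nr + qr
        if (dark[q] && lab[q] == 0L) { lab[q] <- 1L; queue <- c(queue, q) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# oracle pixel sets filtered by the same physical size gate the detector
# uses, for flat-tile equivalence checks
oracleBlobPixels <- function(tile, threshold, geom = PixelGeometry(),
                             diamRangeUm = c(2, 8)) {
  comps <- oracleComponents(imagePixels(tile), threshold)
  keep <- vapply(comps, function(p) {
    d <- 2 * sqrt(length(p) / pi) * umPerPx(geom)
    d >= diamRangeUm[1] && d <= diamRangeUm[2]
  }, logical(1))
  comps[keep]
}
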