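---
title: "Grading iPSC culture quality from phase-contrast morphology"
author: "morphoqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading iPSC culture quality from phase-contrast morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Human induced pluripotent stem cells (hiPSCs) must be kept in an
undifferentiated state during expansion. Culture experts grade regions of
a colony by eye under phase contrast, looking for three morphological
signs: prominent, abundant **nucleoli** (small dark ovals, 3--6 µm — a
sign of the undifferentiated state), bright intercellular **cracks**
(white linear gaps that open as cells begin to deviate), and dark
**differentiating nuclei** (~10 µm ovals that appear when chromatin
condenses). `morphoqc` quantifies exactly these three cues on 150 × 150 px
regions of interest (50 × 50 µm at the default pitch of 1/3 µm per pixel)
and grades each region **poor / mod / good** with an RBF-kernel support
vector machine, the way an expert panel would.

All development and validation run on a synthetic phase-contrast scene
generator with exact ground truth, because graded micrograph collections
of this kind are not publicly deposited. This vignette records the model,
every tunable that matters, and the design decisions taken where the
method description left choices open.

## Physical geometry

Every size threshold is expressed in micrometres and converted through a
`PixelGeometry` (default 1/3 µm/px, i.e. 150 px = 50 µm with a 10×
objective and a ~3 Mpx camera). Conversion is round-half-up and
monotone; the pitch is configurable because other optics differ.
Coordinates are 0-based `(row, col)`; tiles are half-open
`[r, r+150) x [c, c+150)`; partial edge tiles are discarded, never
padded. Multi-channel inputs collapse by unweighted channel mean (phase
contrast is single-channel; colour is a display artifact).

## Nucleolus detector

Candidates are connected components (8-connectivity) of pixels darker
than a **background-refined adaptive threshold**:

1. a robust global preliminary dark set, `I < median - k·MAD`;
2. local mean/sd computed over the remaining background pixels in a
   window spanning 3× the largest admissible diameter (integral images,
   border-clipped);
3. final dark set `I < mean - k·sd`.

The refinement exists because the plain local mean is dragged down by
the object itself whenever the object fills much of the field — on the
27 × 27 px training patches a 6 µm nucleolus covers a third of the patch
and the naive rule detects nothing. Both passes are exactly invariant
under constant intensity shifts. The depth default is `k = 2.5`: at
`k = 1.5` the rule marks the darkest several percent of *any* textured
image, and those correlated background dips bridge neighbouring blobs
into oversized components that the size gate then discards wholesale.
The admissible equivalent-diameter window is 2--8 µm — deliberately
wider than the biological 3--6 µm so that the learned classifier, not a
hard gate, decides borderline sizes.

Each candidate is summarized by `(equiv_diam_um, roundness,
mean_intensity, contrast, eccentricity)`; size and roundness are the
primary cues, intensity/contrast encode "appears black", eccentricity
"nearly oval". Roundness is `4πA/P²` with the perimeter measured along
the traced boundary chain (unit steps 1, diagonal steps √2; 1-px blobs
get the perimeter floor of 4). An RBF-SVM accepts or rejects candidates;
it is trained on 27 × 27 patches (positives centred at pixel (13, 13)),
with `(C, γ)` grid-searched (defaults `C ∈ 10^{-1..2}`, 7 log steps;
`γ ∈ 10^{-3..1}`, 9 log steps) under seeded stratified 3-fold
cross-validation maximizing the positive-class F-measure. The tile count
is the number of accepted candidates. Touching nucleoli are *not* split:
a merged pair counts as one (documented limitation; no watershed).

## Crack detector

Cracks are bright ridges a few pixels wide. The bank pairs
even-symmetric (cosine-phase, zero-mean) Gabor kernels with their odd
quadrature partners at 8 orientations × wavelengths {4, 8, 12} px,
envelope σ = 0.5 λ, isotropic envelope. The response is

> `max over bank of [ max(even, 0) − 0.5·|odd| ]`, clamped at 0,

normalized to [0, 1] per tile. Three choices here were settled
empirically on synthetic masked tiles (the original method was likewise
tuned on a masked dataset) and are worth recording:

* **Quadrature edge suppression.** Plain response magnitude folds the
  kernel's negative side lobes into the mask (detections 4× wider than
  the crack) and responds to the *rims* of bright blobs. The even phase
  peaks on ridges, the odd on edges; subtracting half the odd magnitude
  keeps cracks and silences rims.
* **Isotropic envelope.** An envelope elongated along the ridge
  direction makes every compact bright blob bleed streak artifacts
  tangent to its rim — webs of false cracks between dead cells.
* **Floored normalization.** Dividing by the per-tile maximum makes the
  threshold unitless but blows tile noise up to full scale when no crack
  is present; the normalizing maximum is therefore floored at 0.25× the
  bank's response to a unit-contrast 3-px reference ridge (0.25 being
  the faintest intensity excess still read as a crack).

The response map is thresholded at 0.3, and components are kept only if
they are (a) at least 20 px, (b) high-luminance (component mean above
the tile's 75th percentile), (c) linear — second-moment elongation ≥ 3
*or* curvature-invariant thinness `P²/(4πA)` ≥ 3, because a strongly
curved crack has low moment elongation yet stays thin, (d) not a closed
contour (filled-hull area ≤ 1.5× component area; blob rims form rings,
cracks enclose nothing), and (e) locally contrasted (component mean at
least 0.15 above its non-candidate surround; a crack is brighter than
the cells flanking it, an arc hugging a dead cell is not). The crack
area rate is mask pixels / tile pixels.

**Known limitation:** clusters of stacked bright cells produce genuine
bright thin wedges between lobes that are locally indistinguishable from
short cracks; isolated disc-like distractors are rejected reliably, but
stacked clusters can contribute small false crack areas.

## Differentiating-nuclei detector

A seeded iterative graph cut on the 4-neighbour pixel grid (a Dinic
max-flow in compiled code). Pixels below the 2nd intensity percentile
are hard source (dark) seeds, above the 60th percentile hard sink
seeds. Hard seeds are irreversible, so the source percentile must
*undershoot* the area fraction dark objects occupy — a darkest-10% rule
force-claims background texture on sparsely populated tiles and the
error snowballs through the model updates. Unary terms are negative
Gaussian log-likelihoods under foreground/background intensity models
estimated *robustly* (median/MAD, floor 0.01) from the current
segmentation — the single-Gaussian, robust stand-in for GrabCut's
mixture models; pairwise terms are contrast-modulated,
`2·exp(-ΔI²/2σ²)` with σ² the mean squared neighbour difference. Five
model/cut rounds are run (stopping early once the labelling changes by
under 0.1%), and the mask is opened with a 1-px-radius disc to strip
specks and thin tendrils. Tiles whose 0.5--99.5 percentile intensity
spread is below 0.05 have no contrast to segment and return an empty
mask (bulk quantiles such as p10/p90 would miss a single nucleus
covering 3% of the tile). Surviving components must have equivalent
diameter in 7--15 µm (bracketing the ~10 µm biology while excluding the
nucleolus size class) and roundness ≥ 0.6. The area rate is mask
pixels / tile pixels; overlapping crack and nuclei masks are *not*
disjointified — the rates are independent measurements.

## Quality classifier

The three features are z-scored (means/SDs frozen from training data)
and fed to a one-vs-one RBF-SVM over poor/mod/good. `(C, γ)` is
grid-searched (same default grid as above, which covers the magnitudes
reported for this problem class) by seeded stratified 3-fold
cross-validation maximizing **macro-averaged F** — macro because the
class balance (401/259/240) would otherwise let the majority class
dominate. Prediction evaluates the three pairwise decision functions
and votes; vote ties (the 1-1-1 cycle) resolve to the *lowest* grade,
matching the conservative rule used when aggregating expert votes.
Training is bit-deterministic given the seed. `scanImage()` grades
every stride-aligned window of a frame (default stride 50 px, i.e.
two-thirds overlap) into a quality map.

## Synthetic scenes

`generateTile()` draws a class-conditional scene: background
`0.55 + smooth texture (σ=4 px, amplitude 0.03) + fine grain (σ=1,
0.021)`, dark anti-aliased nucleolus ellipses (3--6 µm, intensity
0.15--0.30), bright meandering crack strokes (width 2--5 px, intensity
0.85--0.95, unit steps with heading drift sd 0.06/step), dark nucleus
ellipses (8.5--11.5 µm, 0.22--0.35), bright distractors (dead-cell
discs and stacked-region clusters, 0.78--0.95), and Gaussian pixel
noise (sd 0.02). Texture fields are scaled by the theoretical sd of
Gaussian-smoothed noise so the amplitude means the same on a 27-px
patch as on a 150-px tile. Object placement is rejection-sampled so
nucleoli never overlap each other, a nucleus, or a distractor (error
after 1000 rejections). Truth masks are exact rasterizations of the
object lists; the class label is the latent class the recipe was drawn
from, never a post-hoc threshold on features. Scenes larger than one
tile scale object counts by area (Poisson additivity), which is how
full 1920 × 1440 frames are produced.

Default class recipes follow the qualitative ordering observed in real
graded data: nucleolus abundance increases with quality
(Poisson means 2 / 4 / 8 for poor / mod / good), cracks concentrate in
mod (presence probability 0.2 / 0.9 / 0.05), differentiating nuclei in
poor (Poisson 3 vs 0.3), distractors equally everywhere (Poisson 0.5).
What the generator does **not** emulate: phase-contrast halo artifacts,
feeder-cell morphology, colony-scale geometry, illumination gradients,
and cell-line-specific feature shifts. Passing tests on these scenes
demonstrate the pipeline's internal correctness and its behaviour under
controlled morphology statistics — not performance on real micrographs.

## What the defaults can and cannot achieve

With the default recipes the class-conditional feature distributions
overlap by construction: one mod tile in ten carries no crack, one poor
tile in five does, and Poisson(4) vs Poisson(8) nucleolus counts share
considerable mass. `scripts/acceptance.R` therefore reports, alongside
the detector-based per-class F-measures, an *oracle* reference: the same
900-tile (401/259/240) dataset and seeded 600/300 split scored on the
true feature values, i.e. with perfect detectors. Across seeds the
oracle lands around 0.91--0.93 (poor), 0.84--0.89 (mod) and 0.87--0.93
(good); that is the Bayes-level ceiling these study conditions impose,
and it mirrors the real-world pattern that the intermediate grade is
hardest for human raters too. The detector-based pipeline sits a few
points below its oracle, the gap being mostly small false crack areas
from stacked-cell wedges. Accuracy targets above this ceiling (a 0.90
per-class bar) are reported honestly as not met rather than met by
re-tuning the scene statistics.

## Numerical choices and degenerate inputs

* Strict threshold comparisons carry a 1e-9 guard so exactly-constant
  backgrounds are immune to integral-image rounding dust.
* Constant tiles: zero Gabor response (zero-mean kernels, exact), no
  blob candidates, empty nuclei mask via the spread gate.
* Zero-denominator metrics (empty predicted class, etc.) are reported
  as 0 with a warning so batch evaluation never aborts; zero-variance
  truth makes detector agreement `NA` with a warning.
* Grid-search ties resolve to the first grid point in (C, γ) ascending
  order; all stochastic steps (fold assignment, scene draws, rater
  draws) derive from explicit integer seeds and restore the caller's
  RNG state.
* Problem sizes used by the validation suite: 50 flat tiles for the
  threshold-oracle identity, 200 tiles for counting, 100 each for crack
  recovery/specificity and nuclei recovery, the 900-tile reference
  dataset for the end-to-end split, and one 1920 × 1440 two-class frame
  scanned at stride 50 (26 × 36 windows).

## Session

```{r, eval = FALSE}
library(morphoqc)
# minimal end-to-end example: see README for a worked run with output
pd <- generateNucleoliPatches(150, 150, seed = 1)
blob <- trainBlobSvm(pd$patches, pd$labels, seed = 1)
g <- generateTile(defaultRecipes()$good, "good", seed = 2)
tileFeatures(g$tile, blob)
```
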