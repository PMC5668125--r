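# morphoqc

Morphology-based quality grading of human iPSC cultures from
phase-contrast micrographs.

During expansion, human induced pluripotent stem cells (hiPSCs) must be
kept undifferentiated, and culture experts grade colony regions by eye
using three morphological signs: prominent, abundant **nucleoli** (dark
ovals, 3–6 µm — a marker of the undifferentiated state), bright
intercellular **cracks** (white linear gaps that open as cells deviate),
and dark **differentiating nuclei** (~10 µm ovals from chromatin
condensation). `morphoqc` measures exactly those three features on
150 × 150 px regions of interest (50 × 50 µm at 1/3 µm/px) and grades
each region **poor / mod / good**, replacing the subjective step with a
reproducible one. It is aimed at cell-culture imaging groups and at
anyone studying interpretable (feature-based, not texture-based) quality
control for stem-cell imagery.

## Method at its core

For a tile \(T\), the feature vector is
\(x = (n_\mathrm{nucleoli},\; r_\mathrm{crack},\; r_\mathrm{nuclei})\):

* \(n_\mathrm{nucleoli}\) — connected dark components under a
  background-refined adaptive threshold (local mean − k·sd, k = 2.5,
  window 3× the largest admissible diameter), size-gated to 2–8 µm and
  accepted/rejected by an RBF-SVM on
  (diameter, roundness \(4\pi A/P^2\), intensity, contrast,
  eccentricity), trained on 27 × 27 px patches;
* \(r_\mathrm{crack}\) — area fraction of ridge components from a
  quadrature Gabor bank (8 orientations, λ ∈ {4, 8, 12} px; response
  \(\max(\mathrm{even},0) - 0.5\,|\mathrm{odd}|\)), kept only if thin,
  high-luminance, locally contrasted and not a closed rim;
* \(r_\mathrm{nuclei}\) — area fraction of round 7–15 µm components of
  a seeded iterative graph cut (darkest 2% = source, brightest 40% =
  sink, robust Gaussian intensity models, Dinic max-flow in C++).

Grading is a one-vs-one RBF-SVM over the z-scored features, with
\((C, \gamma)\) chosen by grid search (C ∈ 10⁻¹…10², γ ∈ 10⁻³…10) under
seeded stratified 3-fold cross-validation maximizing macro-averaged
F-measure; vote ties resolve to the lowest grade. `scanImage()` slides
the classifier across a full frame (stride 50 px) into a colour-coded
quality map.

Because graded micrograph collections of this kind are not publicly
deposited, the package ships a synthetic phase-contrast scene generator
with exact ground truth (object lists + masks + latent class labels)
that reproduces the qualitative class structure of real data — nucleoli
increase with quality, cracks concentrate in the mod class, dark nuclei
in the poor class — plus the full evaluation machinery (multi-rater
plurality-then-lowest label aggregation, per-class precision / recall /
F-measure / one-vs-rest accuracy, per-stratum breakdowns, detector–truth
R²).

## Worked example

```r
library(morphoqc)

# train the nucleolus detector on synthetic 27x27 patches
pd   <- generateNucleoliPatches(150, 150, seed = 1)
blob <- trainBlobSvm(pd$patches, pd$labels, seed = 1)
blob
#> BlobSvmModel (RBF): C=100 gamma=0.3162, 99 SVs, grid 7x9, 3-fold CV

# one synthetic "mod" tile with known truth
g <- generateTile(defaultRecipes()$mod, "mod", seed = 2)
g$truth
#> SceneTruth (mod, seed 2): 2 nucleoli, 1 crack(s), 0 nuclei, 2 distractor(s)

tileFeatures(g$tile, blob)       # measured by the three detectors
#> FeatureVector: n_nucleoli=2 crack_rate=0.0100 diff_nuclei_rate=0.0000
truthFeatures(g$truth)           # ground truth of the same scene
#> FeatureVector: n_nucleoli=2 crack_rate=0.0092 diff_nuclei_rate=0.0000
```

Both nucleoli are found, the crack area rate lands within a tenth of a
percentage point of the rasterized truth, and no differentiating-nuclei
area is hallucinated. Feeding such feature vectors (for a labelled tile
set) to `trainQualitySvm()` and `predictQuality()` yields the
poor/mod/good grades; `confusionAndMetrics()` scores them.

A thin command-line interface wrapping these functions is installed at
`inst/scripts/morphoqc` (`simulate`, `train-nucleoli`, `detect-*`,
`train`, `classify`, `scan`, `evaluate`).

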