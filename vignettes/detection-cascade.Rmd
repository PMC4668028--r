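---
title: "The microcalcification detection cascade: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The microcalcification detection cascade: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the detection model and its assumptions, the parameters that matter, what
the synthetic data generator does and does not emulate, and the numerical
and design choices made where more than one faithful reading existed.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The detection problem

Microcalcifications (μCs) are calcium deposits of roughly 0.1–1 mm that
appear as small bright blobs in a mammogram. Individually they are easily
confused with film noise, crossing vessels and dense tissue texture;
clinically the signal of interest is a *cluster* — three or more μCs
within a few millimetres. The pipeline therefore has two granularities:
individual μC detection (a per-pixel problem) and cluster detection (a
grouping problem over the individual detections).

## Stage 0: breast segmentation

Mammograms contain large near-constant background ("empty space") around
the breast. The segmenter builds an equal-width intensity histogram over
`[0, 2^bit_depth)`; the modal bin `b_max` is taken to be that background.
Scanning the `n_examine` bins to the right of `b_max`, the *declivity* of
bin `k` is `count(k) − count(k+1)` (a forward difference — the simplest
reading of "maximum declivity", and documented as such); the threshold is
the left edge of bin `k*+1` for the maximising `k*`, ties going to the
smallest `k`. Foreground is `intensity ≥ threshold` (breast tissue is
brighter than empty space), smoothed by dilation with a disk and reduced
to the largest 8-connected component.

Defaults: `n_bins = 64`, `n_examine = 8`, `dilate_radius_px = 5`. None of
these are published values — the method's description leaves them open —
so all are config-exposed. Degenerate inputs fail loudly: a constant image
has no usable histogram, and a modal bin at the top of the range leaves no
bins to examine. The modal-bin assumption itself is an assumption about
*mammograms*: an image that is mostly bright tissue with little empty
space (e.g. a texture-free synthetic phantom whose breast fills most of
the frame at a single grey level) can put `b_max` in the tissue mode and
segmentation will fail or invert. The phantom defaults keep enough tissue
texture that the background mode always dominates its single bin.

## Stage 1: Hessian eigenvalue features and the random forest

Second derivatives are computed by correlation with sampled
derivative-of-Gaussian kernels at scale σ (pixels): `x` is the column
direction, `y` the row direction, kernels are truncated at radius
`ceiling(4σ)` and the image border is reflected (edge-repeating). Two
small discrete corrections are applied: the 0th-order kernel is
renormalised to sum exactly 1, and the 2nd-order kernel is recentred to
sum exactly 0, so constant images give exactly flat responses. The
truncation matters for accuracy claims: against an *infinite-support*
closed form the clipped `g''` tail limits agreement to about `2–3 × 10⁻⁴`
relative, while against a dense spatial convolution with the same
truncated kernels the separable implementation agrees to `10⁻¹⁰`. The test
suite asserts both at those tolerances.

Eigenvalues of the 2×2 Hessian come from the closed form
`(tr ± √((Ixx−Iyy)² + 4Ixy²))/2`, ordered so `|λ₁| ≤ |λ₂|`. The per-scale
feature is `(λ₁, λ₂, ‖H‖_F, |λ₁|/|λ₂|)` with the `0/0 → 0` convention for
the ratio (flat regions should look maximally non-blob). No γ-normalised
scale-space derivatives are used — the responses are raw, so a blob of
width `s` has centre response `−A·s²/(s²+σ²)²`, which *decreases*
monotonically in σ. This means the feature vector has no built-in scale
selection; the forest learns the decay pattern across the scale list
instead. (Classical σ²-weighted responses do peak at σ ≈ s, and the test
suite checks exactly that property, but the features fed to the classifier
are deliberately unnormalised.)

The forest is implemented from first principles: bootstrap samples of the
full training-set size, 50 random axis-aligned split candidates per node
(dimension uniform; threshold uniform between the node's min and max in
that dimension), Shannon information gain in bits (the base only rescales
gains), strict `<` splits with ties to the first drawn candidate for
determinism, and three stopping rules — label homogeneity, `max_depth =
30`, and the published 1%-of-training-set minimum child size. The forest
posterior is the plain mean of leaf posteriors; prediction is a small C++
kernel because it runs over every breast pixel (a few hundred thousand per
image).

`θ_RF` is a dataset profile, not a universal constant: the published
values are 0.3 (SNUBH), 0.5 (MIAS), 0.5 (mini-MIAS). 0.3 deliberately
under-thresholds so stage 2 sees all plausible candidates.

## Candidate extraction

Thresholded pixels form 8-connected components (one convention throughout
the package, shared by segmentation, NMS and cluster rule 2). Each
component becomes exactly one candidate: the pixel maximising the
zero-normalised cross-correlation between the local window (side
`2·ceiling(3σ_NMS)+1`, reflect-padded) and a 2-D Gaussian template. The
NMS σ is never published; the package defaults it to the middle element of
the detection scale list, the natural match to the expected blob width.
Ties break to the lexicographically smallest `(row, col)`; a zero-variance
window scores `−∞` so it can only win if every window is flat. A
consequence of one-peak-per-component worth knowing: two μCs closer than
the flagged blobs' width merge into one component and can yield a single
detection.

## Stage 2: the DRBM patch classifier

The DRBM couples a visible patch `x ∈ [0,1]^{d²}`, binary hiddens `h` and
a one-hot label through `E(y,x,h) = −hᵀWx − bᵀx − cᵀh − d_y − hᵀU·ȳ`.
Inference needs no sampling: marginalising `h` gives the free energy
`F_y = d_y + Σⱼ softplus(c_j + U_{jy} + W_j·x)` and
`p(y|x) = softmax(F)`, computed in log space. The test suite pins this
closed form against brute-force enumeration of all hidden states on
hundreds of random small models — the core anti-bug oracle for the module.

Training is generative contrastive divergence on the joint `(y, x)`, the
method the original description names, with mini-batches. One update:
positive-phase hidden means with the data clamped; then `cd_steps`
alternations of hidden sampling, visible mean-field reconstruction
`sigmoid(b + Wᵀh)` and label resampling from `softmax(d + Uᵀh)`; negative
statistics use the hidden means given the reconstruction. The exact
gradient of the *discriminative* objective `−Σ log p(yᵢ|xᵢ)` is also
implemented (`drbm_disc_grad`) — it is verified against finite differences
and doubles as an optional alternative trainer — because the objective the
model family is named for and the training algorithm actually cited are
not the same thing; CD is the default. Visible units are treated as
Bernoulli means with real-valued inputs used directly (the conventional
treatment of intensity patches; no stochastic binarisation). Patches are
normalised by the full bit-depth range, not per-patch contrast: "raw"
patches mean absolute brightness is information.

Dataset profiles (patch side, hidden units, learning rate, epochs):
15/50/0.02/100 (SNUBH), 29/200/0.02/30 (MIAS), 9/200/0.04/30 (mini-MIAS).
"Iterations over the training set" is read as epochs. Weight
initialisation is Normal(0, 0.01), biases zero, `cd_steps = 1`,
batch 64 — standard choices where the description is silent.

The stage-2 training set follows the published protocol: positives are the
annotated μC patches, negatives are sampled from the *stage-1 false
positives*, and the negative set is sized like stage 1's negative set
(several times the positive count), not like the positive set — this
asymmetry is what makes the second stage a specialist in the first stage's
mistakes.

## Cluster rules

**Rule 1 (pairwise distance).** The rule's premise is "all pairwise
distances < d_c1 and ≥ 3 μCs in a region of area A_c1"; its published
implementation is seed-based ("for each detection, collect the detections
within d_c1"). A seed's neighbourhood can contain pairs up to `2·d_c1`
apart, so the two statements disagree. The package reconciles them:
candidates grow from the seed's neighbourhood in order of distance from
the seed, admitting a member only if it stays within `d_c1` of every
member already admitted. Every emitted cluster then honours the pairwise
premise while remaining seed-anchored. The `A_c1` region is realised as a
square of equal area centred on the member centroid (shape and anchoring
are unpublished); with the defaults (`d_c1 = 4 mm`, `A_c1 = 1 cm²`) the
pairwise bound is the binding constraint. Overlapping candidates resolve
greedily by size (ties to the smallest seed coordinate), so emitted
clusters are member-disjoint. The earlier phrase "three or more" and the
later "more than three" also disagree; ≥ 3 is adopted, matching the rule's
source description.

**Rule 2 (cumulative local probability).** `p_C` at a pixel is the box sum
of individual detection probabilities over a `√A_c2 × √A_c2` window
(zero-padded; exact integral-image computation, asserted identical to
nested-loop summation). The probability field is a sparse delta map —
detection scores at detection coordinates — because the pipeline's
individual probabilities exist only there; a dense map can be substituted
by passing any matrix. Supra-threshold window centres merge by
8-connectivity; the cluster box is the union of member windows. The
threshold on `p_C` has no published value; the default 1.0 means "at least
two or three confident detections in one window".

Distances are Euclidean in millimetres on pixel centres
(`mm = px · spacing`); window sides round to the nearest integer pixel, so
1 cm is 100, 200 and 50 px at 0.1, 0.05 and 0.2 mm/pixel.

## Evaluation semantics

Individual detections match ground truth greedily, nearest pair first,
one-to-one, within `point_tolerance_px` (default 0.5 mm at the working
spacing — the order of a μC radius; the matching tolerance is not
published). Greedy matching is order-independent and consistent but is not
a maximum-cardinality assignment; in rare geometries it can match one
fewer pair than the optimum, which the property tests acknowledge by
bounding rather than equating. ROC uses `FP / total non-μC breast pixels`
(breast pixels, not frame pixels, is the chosen denominator); PR omits
thresholds with no detections; FROC matches a detected cluster when its
*centre* lies inside an annotated box or circle, boundaries inclusive, and
images without annotations contribute false positives only. Trapezoidal
AUC is normalised by the x-axis cap (1 for ROC/PR; a stated
FP-per-image cap for FROC). Cross-validation folds partition *images*,
stratified by μC presence.

## The synthetic phantom generator

The generator is the package's study bed and defines its test conditions.
It emulates, on a half-ellipse breast against near-zero empty space at
0.2 mm/pixel (a digitised-film-like geometry where a 512×512 frame covers
~10 cm): spatially correlated tissue texture (white noise smoothed to a
6 px correlation length, scaled to sd 10 around base level 60 of the 8-bit
range); ~50 isotropic Gaussian-bump μCs per image with radii 0.8–1.6 px
(0.16–0.32 mm) and peak amplitudes 40–90; a 60% cluster fraction, cluster
members within 2 mm of their centre (so pairwise distances respect the
4 mm rule) and isolated μCs separated by at least three maximal bump radii;
2–3 bright Gaussian-profile ridges as vessel-like distractors; and
additive Gaussian noise (sd 5). Everything — placement, bump parameters,
texture, noise — is a deterministic function of one integer seed.

What it does *not* emulate: anatomy (pectoral muscle, ducts, skin line,
labels), the heavy-tailed morphology of real μCs (they are not Gaussian
bumps), film artefacts, and the class imbalance of a clinical archive
where most images have no μCs at all. Passing the end-to-end tests
therefore shows the machinery is correct and the cascade logic works on
blob-plus-ridge-plus-texture images; it does not certify clinical
performance.

The `phantom` configuration profile inherits the mini-MIAS-style geometry
(0.2 mm scales `{0.5, 1, 1.5, 2, 2.5}`) but re-tunes, on held-out
validation phantoms and in the same empirical spirit as the per-archive
profiles: `θ_RF = 0.7` (the generator's ridge intersections produce
mid-confidence false candidates that a stricter stage-1 threshold removes
at almost no sensitivity cost), patch side 15 (a 3 mm patch lets the DRBM
see whole ridge segments), 50 hidden units, learning rate 0.1 and 200
epochs (the phantom training sets are a few hundred to a couple of
thousand patches — far smaller than a clinical archive — and a smaller,
longer-trained model generalises better there).

## Problem sizes and numerical choices

The end-to-end experiment trains on 16 phantoms and tests on 20 (seeds
0–19), 512×512 each — sizes chosen so the full study runs in about two
minutes on one CPU while keeping ~1000 test μCs and ~150 test clusters.
The stage-1 training set samples 5 negatives per positive from the breast
region outside cluster boxes. Pixel-level ROC AUC scores the stage-1
posterior against disks of radius `ceiling(σ)` around planted bump
centres, pooled over test images; the cluster operating point is read off
a free-response sweep of the stage-2 threshold (sensitivity at ≤ 1 false
positive cluster per image).

Other numerics, in one place: reflect (edge-repeating) padding everywhere
a window leaves the image (convolution, NMS, patches); separable
convolution as two band-matrix products so BLAS carries the cost; forest
and DRBM training seeded per-substream so every model is a deterministic
function of one run seed; JSON serialization for both models with
full-precision numbers; detections CSV serializes scores to 17 significant
digits so round trips are lossless; 8-connectivity and row-major scan
order fixed package-wide; all user-facing coordinates 0-based `(row, col)`
with row 0 at the top.

## Known limitations

* One detection per connected component caps resolution: μCs closer than
  the flagged-blob width cannot be separated.
* The raw (unnormalised) multi-scale features make the classifier, not
  the feature, responsible for scale selection; a forest trained on one
  spacing does not transfer to another.
* CD training of the DRBM is stochastic and, on small training sets,
  sensitive to the learning-rate/epoch budget; the discriminative trainer
  is steadier on toy problems but is not the default because the
  generative objective is the documented method.
* The segmentation histogram heuristic assumes empty space dominates the
  modal bin; it is a mammogram-specific assumption, not a general-purpose
  segmenter.
* Rule 1's greedy overlap resolution and the seed-anchored pairwise
  growth are one consistent reading of an underspecified rule; other
  readings (e.g. maximal cliques) would differ on adversarial point sets.
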