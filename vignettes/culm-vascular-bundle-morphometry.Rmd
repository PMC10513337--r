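---
title: "Quantifying vascular-bundle gradients in bamboo culm cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular-bundle gradients in bamboo culm cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological measurement problem

A moso-bamboo culm wall is a fiber-reinforced gradient material. Vascular
bundles — strands of xylem, phloem and a sclerenchyma fiber sheath — are
scattered through the parenchyma ground tissue, densely near the epidermis
and sparsely toward the pith cavity. Their shape changes along the same
radial axis: near the epidermis they are small, almost pure fiber caps,
radially elongated (tangential/radial bounding-box ratio around 0.5); toward
the pith they grow, develop a phloem/metaxylem interior that splits the
fiber sheath into two and then four lobes, and end up tangentially elongated
(aspect above 1) in a single tangential row at the pith margin. Lower
internodes carry larger, more radially elongated bundles in a thicker wall
with a lower whole-wall bundle area ratio than upper internodes.

`culmorph` implements the full quantitative chain for studying these
gradients on cross-sectional images: semantic segmentation of bundles,
per-bundle morphometry, radial profiling on a normalized epidermis (p = 0)
to pith (p = 1) coordinate, internode-level statistics, and a variational
autoencoder (VAE) that embeds bundle shapes in a latent space so the radial
morphological transformation can be rendered as a continuous morph.
Because no public image set accompanies the descriptor data this package
was developed against, it ships a first-class synthetic-section generator
with instance ground truth; every claim the test suite makes is made on
those synthetic study conditions, not on real micrographs.

## The synthetic generator and what it does (not) emulate

`make_archetype()` fixes, per internode (2, 12, 22, 32, numbered from the
base), a wall thickness and four radial profiles: local bundle area
fraction, mean bundle area, aspect, and developmental morphotype
(stages 1–4). The profile shapes are calibration choices, made once, that
encode the qualitative trends above:

* area fraction `f(p) = f_pith + (f_epi − f_pith)(1 − p)²`, highest at the
  epidermis; the curve anchor `f_epi = 0.76` is set so that the *realized*
  fraction in the outermost 5% band is the declared target of 0.70 after
  placement margins and rasterization losses (the generator's calibration
  invariant, checked by the tests);
* mean area `A(p) = A0 + (A1 − A0) p^1.2`, increasing toward the pith;
* aspect `a(p)` linear from ≈0.5 to ≈1.2–1.3;
* morphotype stage stepping 1→4 at p = 0.12, 0.35, 0.65.

Bundle density (bundles per px²) is derived as `f(p)/A(p)` and is therefore
monotonically decreasing. Internode contrasts are encoded in the constants
(internode 2: thickest wall at 600 px, largest areas, lowest aspects,
lowest whole-wall ratio; internode 32 the opposite).

Bundles are placed by sequential rejection sampling with at most 200
attempts per bundle. The proposal is *stratified*: jittered tangential rows
whose cell sizes realize `f(p)` exactly. A plain i.i.d. proposal cannot be
used for the dense epidermal region — random sequential placement of
non-overlapping convex shapes saturates near 55% occupancy, well below the
~70% the epidermal band requires — while a jittered lattice mirrors the
quasi-regular packing visible in real sections. An `placement = "iid"` mode
(optionally with rejection disabled) is kept for statistical checks of the
position sampler itself. Placed instances are separated by at least one
background pixel, so ground-truth instances never merge under 8-connected
labeling.

Bundle outlines are superellipse-based stamps with stage-dependent boundary
notches: stage 1 a compact blob (bounding-box fill ≈0.82), stage 2 two
lobes flanking a narrow, deep radial pinch (the phloem/xylem gap), stages
3–4 four lobes with diagonal notches; extent declines monotonically
0.82 → 0.79 → 0.64 → 0.60. Images are formed as parenchyma texture
(intensity ≈0.72) minus a 0.4 contrast step under the bundle mask, plus
Gaussian noise (σ = 0.05), with the pith cavity bright (0.97): naive
thresholding is imperfect but the task is learnable.

What the generator does **not** emulate: cell-level lumina inside bundles
(masks are filled outlines), staining/illumination gradients, stitching
seams, node tissue, or out-of-plane sectioning artifacts. Tests passing on
these conditions therefore validate the analysis chain, not performance on
real micrographs.

## Segmentation

The segmenter is a U-Net-style encoder–decoder: per level two 3×3
convolutions + ReLU and 2×2 max pooling; a two-convolution bottleneck; a
decoder with nearest-neighbour upsampling, channel-halving convolution and
skip concatenation; and a 1×1 sigmoid head. The engine (convolution,
pooling, upsampling, and their backward passes; Adam) is implemented in
RcppArmadillo and verified against central-difference gradients.

Desk-scale defaults — 128-px tiles, depth 3, 16 base filters (535,505
parameters), Adam at 1e-3, at most 100 epochs with one tile per step —
train in a few minutes on one CPU. Training stops early once the epoch mean
binary cross-entropy falls below `stop_loss` (default 0.02); on the default
synthetic tiles this happens around epoch 10. The binarization threshold is
0.5. Full images are predicted tile-wise on the same edge-aligned grid used
by `crop_tiles()` (remainder tiles shift inward; nothing is zero-padded),
with probabilities averaged in overlaps before thresholding.

Evaluation reports pixel accuracy, *connection errors* (predicted
components overlapping two or more ground-truth instances by at least
`min_overlap_px = 10` pixels each — the merged-bundle failure mode) and
missed instances. The mixed- versus single-internode training contrast is
checked at a reduced scale (64-px tiles, depth 2, 8 base filters, three
seeds) and asserted on the seed-aggregated merge-error counts, since the
contrast is qualitative.

## Morphometry conventions

All descriptors are computed from first principles; conventions are fixed
so independent oracles can reproduce them exactly:

* pixel centers at integer 0-based (row, col); bounding boxes half-open;
* aspect = bbox width / bbox height (tangential/radial; rows are radial);
* extent = area / bbox area; eccentricity from the central second-moment
  eigenvalues, `sqrt(1 − λ₋/λ₊)`;
* convex area by monotone-chain hull over the four corner points of every
  boundary pixel (shoelace area), so `convex_area ≥ area` always;
* perimeter is the closed 8-connected Moore boundary-chain length through
  boundary pixel centers (axial 1, diagonal √2; a single pixel has
  perimeter 4). This chain metric is exact on axis-aligned rectangles
  (4(N−1) for an N×N square) and inflates smooth boundaries by a few
  percent — a documented digitization bias, which is why oracle
  comparisons use the same definition rather than an analytic circumference.

Components are labeled with 8-connectivity by default (thin bridges are
exactly how merged-bundle errors arise, so the conservative choice is to
connect them). Border-touching bundles are measured but flagged and
excluded from profiles by default; whether real analyses excluded
block-edge bundles is unknown, so this is a declared package decision.

## Radial analysis

`build_frame()` takes exact boundary rows from ground truth, or finds the
band in an image as the outermost/innermost rows whose fraction of
tissue-like pixels (intensity < 0.85, between the parenchyma and cavity
levels) exceeds 0.5. Area-fraction profiles use equal-width bins in p
(default 20; the alternative of equal-area annuli is not used, a declared
choice), assigning each tissue row to exactly one bin so that refining bins
preserves the tissue-weighted mean exactly. Count profiles default to 10
bins. Moving-window profiles slide a window of exactly 25 records sorted by
position and report the window mean ± population SD (the SD estimator is a
declared choice); an absolute-position mode (pixels from the epidermis) is
provided alongside the relative one. The whole-wall area ratio is bundle
pixels over tissue pixels across the band.

## Statistics

Internode comparisons use one-way ANOVA with Tukey–Kramer HSD (pairwise
`q = |m_i − m_j| / sqrt(MSE(1/n_i + 1/n_j)/2)` against the studentized
range with N − k df) and Kruskal–Wallis (tie-corrected, via
`stats::kruskal.test`) with the Dwass–Steel–Critchlow–Fligner all-pairs
post-hoc. For DSCF each pair is ranked jointly; with W the rank sum of the
first group, `q = √2 |W − n_i(N+1)/2| / σ` with
`σ² = n_i n_j/12 [(N+1) − Σ(t³−t)/(N(N−1))]` (N = n_i + n_j, t the tie
multiplicities) is referred to the studentized range with k groups and
infinite df. An all-tied pair gets p = 1 by convention. Studentized-range
tail probabilities come from R's `ptukey`, the vetted special-function
routine. α defaults to 0.05.

Compact letter displays use insert-and-absorb: one letter set splits on
every significant pair, subsets are absorbed, and letters are assigned in
stable group order. The output guarantees the sharing relation (two groups
share a letter iff not significantly different), not letter-count
minimality.

DSCF is validated against a 20,000-draw permutation oracle and, at k = 2,
against the tie-corrected normal rank-sum approximation (the two agree
analytically); Tukey's familywise type-I rate is checked by simulation
(1,000 null replicates, k = 4, n = 9).

## VAE morphing

Extracted bundle masks (cropped about their centroid, centered on a square
canvas with 10% margin, bilinearly resampled — aspect is preserved) feed a
convolutional VAE: three conv+pool stages to an 1/8-resolution feature map,
a 128-unit hidden layer, and a diagonal-Gaussian latent layer; the decoder
mirrors it with nearest-neighbour upsampling. The loss is summed per-pixel
binary cross-entropy plus β·KL (β = 1). Desk scale is 64-px inputs with a
32-dimensional latent space and 60 epochs by default (40 epochs suffice in
the acceptance checks); the full scale the method is meant for — 256-px
inputs, 200 latent dimensions, thousands of epochs — is the same
architecture scaled up and is not run in the test suite.

Morphing selects, for each target radial station (defaults 0.01, 0.09,
0.40, 0.71, 1.00), the extracted bundle nearest in relative position
(nearest-neighbour selection is a declared rule), encodes anchors to their
posterior means (no sampling, so paths are deterministic), interpolates
linearly between consecutive anchors and decodes every point. Endpoint
frames equal the decoded anchor means exactly, and the decoded path's
extent declines from the epidermal to the pith anchor, reproducing the
fiber-blob → four-lobe narrative. Anchors should come from the training
distribution: encoding clearly out-of-distribution shapes collapses them
toward generic reconstructions and flattens the morph.

## Numerical and engineering choices

* All randomness flows through R's RNG from explicit integer seeds;
  identical configs reproduce bit-identical sections and byte-identical
  CSVs. The C++ kernels are deterministic.
* Stamp shape constants (bounding-box fill, half-extents) are computed
  once by 4096-point numeric quadrature of the boundary curve.
* The im2col matrices built in the forward pass are cached and reused by
  the backward pass; this roughly halves training time.
* Degenerate inputs are rejected with informative errors (degenerate
  tissue frames, windows longer than the record list, empty tile or image
  sets, inconsistent duplicated pairwise results, stamps too small to
  carry their stage's lobes).
* Problem sizes in the test suite: sections of 380–600 × 1024 px, ~100–130
  bundles each; 30 training + 10 held-out 128-px tiles for the segmenter;
  ~100 64-px bundle images and 40 epochs for the VAE; 3 seeds for the
  training contrast. These sizes make the whole suite run in tens of
  minutes on a single CPU while leaving every scientific assertion intact.

## Known limitations

* Synthetic realism is deliberately limited (see above); accuracies near
  99% here say nothing quantitative about real micrographs.
* The chain-code perimeter inflates smooth contours by a few percent by
  construction; compare only against the same definition.
* The VAE is a desk-scale model; its reconstructions are coarse and the
  morph is validated through shape summaries (extent), not visual fidelity.
* Decoded morph paths move at non-uniform speed: equal latent steps produce
  small image changes near anchors and changes up to an order of magnitude
  larger where the path crosses a morphotype transition. The steps shrink
  proportionally as frames per segment grow (the decoded path is smooth),
  but the max-to-median step ratio stays near 10 regardless of the KL
  weight, training length or anchor choice, so frame-to-frame change is
  bounded yet not uniform along the path.
* Letter displays are not minimized; with many groups they may use more
  letters than strictly necessary.
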