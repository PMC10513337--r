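# culmorph

Quantitative morphometry of vascular bundles in moso-bamboo
(*Phyllostachys pubescens*) culm cross-sections.

A bamboo culm wall is a natural gradient composite: vascular bundles —
xylem, phloem and a sclerenchyma fiber sheath — are packed densely at the
epidermis and sparsely toward the pith cavity, and their shape transforms
along the same radial axis from small radially-elongated fiber caps to
large, lobed, tangentially-elongated bundles. These gradients drive both
the culm's mechanics and its physiology, so people studying bamboo as a
material or as a plant need them measured, not described. `culmorph` is an
R implementation of the full measurement chain for cross-sectional images:

* **synthgen** — a synthetic culm-section generator with instance-labeled
  ground truth that reproduces the radial gradients and internode
  archetypes (internodes 2, 12, 22, 32), used as the test bed for the
  whole chain;
* **segmentation** — a tile-based U-Net-style encoder-decoder (training,
  prediction, evaluation), with the convolution engine written in
  RcppArmadillo and verified against numerical gradients;
* **morphometry** — first-principles region descriptors per bundle: area,
  Moore boundary-chain perimeter, convex-hull area, moment eccentricity
  `sqrt(1 − λ₋/λ₊)`, aspect (tangential width / radial height of the
  bounding box), extent (area / bounding-box area), centroid;
* **radial_analysis** — the normalized epidermis (p = 0) → pith (p = 1)
  coordinate, area-fraction and count profiles per radial bin,
  moving-window (n = 25) mean ± SD descriptor profiles, whole-wall area
  ratios;
* **stats** — one-way ANOVA + Tukey HSD, Kruskal–Wallis +
  Dwass–Steel–Critchlow–Fligner (DSCF) all-pairs post-hoc, compact letter
  displays;
* **vae_morph** — a convolutional variational autoencoder over extracted
  bundle images and latent-space morphing through anchors at radial
  stations 0.01, 0.09, 0.40, 0.71, 1.00;
* **pipeline** — `run_pipeline()` plus a thin CLI (`inst/scripts/culmorph`)
  binding the stages, fully seeded and reproducible.

## Worked example

```r
library(culmorph)

arch    <- make_archetype(2, seed = 1)            # internode-2 archetype
sec     <- generate_section(arch)                 # image + ground truth
frame   <- sec$truth$frame
records <- measure_bundles(sec$truth$instance_mask, frame)
prof    <- area_fraction_profile(sec$truth$instance_mask, frame, n_bins = 20)

nrow(records)                                     # 106 bundles
area_ratio(sec$truth$instance_mask, frame)        # 0.317
prof$area_fraction[1]                             # 0.704
inner <- records[!records$touches_border, ]
mean(inner$aspect[inner$relative_position < 0.05])  # 0.51
mean(inner$aspect[inner$relative_position > 0.9])   # 1.29
```

The section carries 106 bundles; bundles fill 31.7% of the whole wall but
70.4% of the outermost radial bin, and the mean aspect ratio rises from
0.51 beside the epidermis (radially elongated) to 1.29 at the pith margin
(tangentially elongated). A moving 25-bundle window over `extent` falls
from 0.82 to 0.64 across the wall — the fiber blob → lobed bundle
transformation.

Comparing whole-wall area ratios across internodes (5 sections each):

```r
ratios <- lapply(c(2, 12, 22, 32), function(id)
  vapply(1:5, function(s) {
    x <- generate_section(make_archetype(id), seed = s)
    area_ratio(x$truth$instance_mask, x$truth$frame)
  }, numeric(1)))
names(ratios) <- paste0("i", c(2, 12, 22, 32))
res <- anova_tukey(ratios)
res$F                                      # 806.9, p = 1.15e-17
sapply(ratios, mean)                       # 0.317 0.338 0.368 0.402
compact_letters(res$pairwise, names(ratios))
#>  i2 i12 i22 i32
#> "a" "b" "c" "d"
```

The area ratio increases from the basal internode 2 to the upper internode
32, with every pairwise difference significant — the lower internodes
compensate with a thicker wall and larger, more radially elongated bundles.

Training the desk-scale segmenter and morphing bundle shapes:

```r
tiles <- crop_tiles(sec$image, (sec$truth$instance_mask > 0) * 1L, 128L)
cfg   <- seg_config()                      # 128-px tiles, depth 3, Adam 1e-3
model <- train_seg(build_unet(cfg), tiles, cfg)
pred  <- predict_mask(model, sec$image)
evaluate_seg(pred, sec$truth)              # pixel accuracy, merge errors

ext <- extract_bundle_images(sec$truth$instance_mask, records, 64L)
vae <- train_vae(ext$images, vae_config(seed = 2))
anc <- select_anchors(ext)                 # nearest bundles to the stations
path <- morph(vae, anc$images, anc$positions, frames_per_segment = 10)
write_frames_png(path, "morph_frames")     # the decoded transformation
```

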