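# cellasr

Automated **segmentation and identity recognition of densely packed cells**
in 3D fluorescence microscopy stacks of small model organisms — the
motivating case being the newly hatched L1-stage *C. elegans* larva, whose
558 whole-body cells sit in stereotyped positions but are crowded, dim at
their boundaries, and individually variable enough that both separating
them and naming them are hard problems.

The package is aimed at computational biologists who need per-cell,
per-identity readouts (gene expression, lineage, fate) from whole-body
stacks without fiducial markers, and at methods developers who want a
fully tested, CPU-only reference implementation of the underlying
algorithms.

## The method

**Segmentation** regresses, with a small 3D encoder–decoder network, the
*displacement vector field* (DVF): for every voxel the offset to its
nearest background voxel,

```
d_i = [0,0,0]                                    if voxel i is background
d_i = [x_i - x'_i,  y_i - y'_i,  z_i - z'_i]     otherwise,
```

where `(x'_i, y'_i, z'_i)` is the nearest background voxel.  The field's
L2 norm is the Euclidean distance transform, but unlike a distance map the
vectors *flip direction* across the interface of touching cells — a sharp,
learnable boundary signature.  Training minimises
`L = w1 * Ld + w2 * Lr` (squared displacement error plus mean cosine
dissimilarity; `w1 = 7`, `w2 = 1`).  Instances are then recovered by
thresholding the predicted distance map into seed cores and growing them
with a marker-controlled watershed.

**Recognition** matches segmented centroids against a three-part
statistical atlas built from identity-annotated training samples:
average spatial positions (ASP), per-axis positional standard deviations
(SPV, `sigma_m`), and shape-context variability (TSV, `gamma_m`).  A
deterministic-annealing robust point matcher with the pair similarity
`f(s_n|v_m) ∝ exp[-(d(s_n,v_m)/alpha + g(s_n,v_m)/beta)]` (spatial distance
`d`, shape-context chi-square distance `g`) establishes initial
correspondences; affine plus piecewise-affine mapping and consensus
bipartite assignment on the prior kernels

```
F_spv[n,m] = exp( -||(s_n - v_m) / sigma_m||^2 / (2 w^2) )
F_tsv[n,m] = exp( -g(s_n, v_m)^2 / gamma_m^2 / (2 w^2) )
```

are iterated until stable, and the final one-to-one identity assignment is
solved on `F_spv + F_tsv` with a Hungarian-style solver.

Evaluation metrics include voxel accuracy, instance precision/recall/F1,
the aggregated Jaccard index (AJI), the size-balanced per-cell IoU (IIoU),
`AP@t = TP/(TP+FP+FN)`, and an identity-aware recognition AP.

Everything is validated against independent oracles on synthetic data: a
phantom generator for image stacks with ground-truth masks, and a
synthetic "worm" generator producing identified point sets under
controlled deformation, jitter, and dropout.  See the methods vignette
(`vignettes/cell-segmentation-recognition.Rmd`) for models, parameters,
and limitations.

## Worked example

Segmentation round trip on a synthetic phantom, then atlas building and
recognition on a synthetic population:

```r
library(cellasr)

# phantom stack with ground-truth instance mask
ph    <- make_phantom(phantom_config(seed = 42))
field <- compute_dvf(ph$mask)           # ground-truth displacement field
seg   <- segment_from_dvf(field)        # distance map -> seeds -> watershed
evaluate_segmentation(seg, ph$mask)
#>   accuracy precision recall    f1   aji  iiou  ap50  ap75    ap
#> 1        1         1      1     1     1     1     1     1     1

# synthetic population: template, training samples, atlas
cfg     <- worm_config(n_cells = 60, seed = 1)
tmpl    <- make_synthetic_atlas(cfg)
samples <- lapply(1:10, function(s) make_synthetic_worm(tmpl, cfg, seed = s))
atlas   <- build_atlas(samples)
glance(atlas)
#>   n_cells n_samples iterations converged mean_sigma mean_gamma
#> 1      60        10          4 TRUE            1.06     0.0771

# recognise a new individual
worm <- make_synthetic_worm(tmpl, cfg, seed = 99)
res  <- recognize(worm, atlas)
head(tidy(res), 4)
#>   subject label id    confidence
#> 1       1     1 c000       0.800
#> 2       2     2 c001       0.404
#> 3       3     3 c002       0.770
#> 4       4     4 c003       0.381
recognition_accuracy(res, worm$id)
#> [1] 0.9666667
```

The segmentation row reads: perfect voxel accuracy, all 12 instances
matched one-to-one at IoU 0.5 (F1 = 1), and AJI/IIoU of 1 — the
ground-truth field reconstructs the mask exactly.  The recognition call
assigns 58 of this individual's 60 cells their correct atlas identity
(accuracy 0.967); `confidence` is the assigned pair's share of its row in
the summed prior-similarity matrix.

Training the network on phantoms instead of using the ground-truth field:

```r
pairs <- lapply(1:5, function(s) {
  ph <- make_phantom(phantom_config(seed = s))
  list(volume = ph$volume, mask = ph$mask)
})
fit <- train_dvf_net(pairs, model_config(), cube_spec(), cubes_per_epoch = 24)
seg <- segment_from_dvf(predict_dvf(make_phantom(phantom_config(seed = 99))$volume, fit))
```

A thin command-line wrapper over the same functions lives in
`inst/cli/asr.R` with subcommands `simulate`, `make-dvf`, `train`,
`segment`, `build-atlas`, `recognize`, and `evaluate`.

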