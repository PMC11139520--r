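---
title: "Segmenting and recognising whole-body cells in 3D image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and recognising whole-body cells in 3D image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cellasr)
```

`cellasr` implements a two-stage pipeline for 3D fluorescence microscopy of
small model organisms whose cells sit in stereotyped positions — the
motivating case is the newly hatched L1-stage *C. elegans* larva with its 558
whole-body cells.  Stage one segments densely packed nuclei by regressing a
displacement vector field; stage two assigns a biological identity to every
segmented cell by matching its centroid against a statistical atlas.  This
vignette explains the models, the tunable parameters, the numerical choices,
and what the synthetic validation does and does not demonstrate.

## 1. Displacement-field segmentation

### The displacement vector field

For a voxel $i$ at $(x_i, y_i, z_i)$ with nearest background voxel
$(x'_i, y'_i, z'_i)$, the displacement vector field (DVF) is

$$
\vec d_i =
\begin{cases}
[0, 0, 0] & i \in \Phi \ \text{(background)}\\[2pt]
[\,x_i - x'_i,\; y_i - y'_i,\; z_i - z'_i\,] & \text{otherwise,}
\end{cases}
$$

stored as three channels $D_x, D_y, D_z$.  Its L2 norm is the Euclidean
distance transform of the foreground (the distance map $P$), but unlike a
plain distance map the vector field *reverses direction* across the
interface of two touching cells, giving the network a sharp, learnable
signature exactly where segmentation is hardest.

`compute_dvf()` computes the ground-truth field with an exact separable
squared-distance transform followed by a bounded search for the nearest
background voxel.  Two conventions are fixed here and used everywhere:

* **Tie-break.** Equidistant background voxels are resolved to the smallest
  `(z, y, x)` lexicographic coordinate (z-major linear index).  Any fixed
  rule works; this one is deterministic and testable.
* **Borders.** Voxels outside the volume are *not* background: cubes are
  cropped from larger stacks, so a cell touching a crop border behaves as if
  it continued.  Cells genuinely touching the stack border therefore carry
  displacements pointing inward only.

### Losses

Training minimises $L = \omega_1 L_d + \omega_2 L_r$ with

$$
L_d = \frac{1}{3N}\sum_{i=1}^{N} \lVert \vec d_i^{\,pre} - \vec d_i^{\,gt}\rVert^2,
\qquad
L_r = 1 - \frac{1}{N}\sum_{i=1}^{N}
\frac{\vec d_i^{\,pre} \cdot \vec d_i^{\,gt}}
     {\lVert\vec d_i^{\,pre}\rVert\,\lVert\vec d_i^{\,gt}\rVert},
$$

and $\omega_1 = 7$, $\omega_2 = 1$ by default.  The cosine term is undefined
at zero norm, so `direction_loss()` excludes voxels where either vector's
norm is below `eps = 1e-8` — in particular all ground-truth background —
rather than padding the denominator, which would bias background toward
arbitrary directions.

The *training* gradient uses a slightly different surrogate for $L_r$: the
mean runs over ground-truth foreground only, and the predicted norm in the
denominator is floored at 0.5 voxel.  Without the floor the cosine gradient
scales like $1/\lVert \vec d^{\,pre}\rVert$ and, in the early regime where
the network output is still near zero, swamps the displacement gradient with
noise; a half-voxel floor bounds it without affecting converged behaviour.
The evaluation-side `direction_loss()` is exact.

### Network and training

`build_model()` constructs a 3D encoder–decoder regression network (U-Net
layout: two 3×3×3 convolutions per level, 2×2×2 max pooling,
nearest-neighbour upsampling, skip concatenation, linear 3-channel head).
Convolutions are executed as padded-volume GEMMs in compiled code; gradients
are analytic and verified against finite differences in the test suite.

Two deliberate deviations from textbook defaults:

* **Leaky rectifier (slope 0.1).**  With a hard rectifier this regression
  task has a strong degenerate attractor — predict zero everywhere, since
  most voxels are background — and units that die there stay dead.  The
  leaky slope removes the attractor's stability; in our experiments it is
  the difference between converging in a few dozen steps and stalling for
  hundreds.
* **Desk-scale default configuration**: 3 levels with 16/32/64 channels on
  16×32×32 cubes, Adam at `lr = 1e-3`, suited to CPU-only training on
  phantoms in minutes.  The full-scale variant used for real stacks
  (5 levels, 32/64/128/256/512 channels, 80×128×128 cubes, smaller learning
  rate) is expressed with the same `model_config()`/`cube_spec()` arguments.

`train_dvf_net()` samples random cube origins from each training volume every
epoch (large stacks are never loaded into the network whole) and recomputes
the ground-truth DVF per crop.  Intensities are min–max normalised per
volume.  Everything is deterministic given the config seed.
`predict_dvf()` partitions a volume on a regular grid, runs each cube, and
mean-blends overlaps.

### From field to instances

`segment_from_dvf()` chains three steps: the distance map (L2 norm of the
field), seed extraction (`extract_seeds()`: connected components of
`dist > t_seed`, components smaller than `min_size` removed), and a
marker-controlled watershed (`watershed_segment()`) flooding the negated
distance map so inter-cell boundaries fall on distance ridges, restricted to
`dist > t_fg`.

Defaults `t_seed = 2`, `t_fg = 0.5`, `min_size = 9`, 26-connectivity suit
nuclei of roughly 3–6 voxel radius: a seed core is the cell eroded by
`t_seed`, so it exists and survives the size filter whenever every semi-axis
exceeds `t_seed` by about one voxel.  The synthetic phantoms are sized
accordingly (semi-axes ≈ 3.6–5.9 voxels) so that the ground-truth
round trip — mask → DVF → distance → watershed — reproduces the instance
layout exactly; with smaller nuclei one should lower `t_seed`/`min_size`
together.

## 2. Statistical atlas

The atlas holds, per identified cell $m$:

* **ASP** — the average spatial position across aligned training samples;
* **SPV** — per-axis standard deviations $\sigma_m = (\sigma_x, \sigma_y,
  \sigma_z)$ of the aligned positions;
* **TSV** — a scalar $\gamma_m$: the mean chi-square distance between the
  cell's shape context in the ASP and in each aligned sample;
* the reference shape-context histograms used at recognition time.

### Average positions without template bias

`build_asp()` starts from the first sample, affine-aligns every sample to
the current template, and moves the template by the per-cell mean
displacement of the aligned samples.  Crucially, the freshly averaged
template is then transformed by the *inverse of the average fitted affine*.
A least-squares affine fitted on noisy source coordinates is systematically
contractive (errors-in-variables attenuation), and since the iteration
re-fits against its own output, the contraction compounds — without the
inversion the template's short body axes collapse within a few iterations.
With it, the iteration's fixed point is the configuration whose average
deformation is the identity, which also removes the shape bias toward the
arbitrarily chosen initial sample.  Convergence tolerance is
`1e-3 ×` body length, with at most 20 iterations.

### Piecewise-affine alignment and unbiased variability

Stacks of elongated animals deform far more along the body axis than any
global affine can express.  `fit_pwa()` splits the source along its longest
principal axis into `n_segments = 8` windows (20% overlap), fits an affine
per window, and maps points by linear cross-fade between the two bracketing
window affines; with one segment it reduces exactly to `fit_affine()`.

For the final atlas alignment the PWA is fitted in the *template-to-sample*
direction — clean predictor coordinates — and inverted pointwise by Newton
iteration on the blended affine (`invert_pwa()`).  Fitting directly on the
noisy sample coordinates would attenuate exactly the positional variability
the SPV is supposed to measure; with the inverse-direction fit the injected
per-axis scatter of synthetic populations is recovered to within a few
percent at 50 samples.

### Shape context

A cell's shape context is a histogram of its neighbours over `R = 5`
log-spaced radial shells between `r_min = 2` and `r_max = 100` voxels, each
divided into `F = 12` sectors (6 azimuthal bins × 2 polar hemispheres),
normalised to unit mass.  Angular bins are computed in the point set's own
deterministic PCA frame, making the descriptor pose-normalised; it is
invariant to translation and to duplication of the neighbour set.
Histograms are compared with the chi-square distance
$\tfrac12\sum_b (h_{1b}-h_{2b})^2/(h_{1b}+h_{2b}+\varepsilon)$.
All binning parameters are exposed in `shape_context_params()`.

## 3. Recognition

`recognize()` runs six stages, deterministic given inputs and config:

1. **Centroids** of the labelled segmentation (`extract_centroids()`).
2. **PCA pre-alignment** to the atlas: centre, rotate principal axes onto
   principal axes, scale per-axis; only proper rotations are considered.
   Because an elongated body is nearly symmetric under a 180° flip, the two
   best pose hypotheses are both carried through the full pipeline and the
   one ending with the higher summed prior similarity wins — spatial
   tightness alone cannot tell a flipped match apart.
3. **Annealed robust point matching** (`rpm_match()`): soft correspondences
   from $f(s_n|v_m) \propto \exp[-(d(s_n,v_m)/\alpha + g(s_n,v_m)/\beta)]$
   with $d$ the Euclidean distance and $g$ the shape-context chi-square
   distance, alternated row/column normalisation with an outlier slack
   row/column (score $e^{-1}$), a weighted affine re-fit per annealing step,
   and the schedule $\alpha \leftarrow 0.93\,\alpha$,
   $\beta \leftarrow \beta/0.93$: position dominates early, local topology
   fine-tunes late.  $\alpha_0$ defaults to the target's mean squared
   nearest-neighbour distance; $\beta_0$ equates the median magnitudes of
   the two exponent terms; annealing stops at $\alpha < 0.1$.  Subject shape
   contexts are recomputed whenever the pose changes (they are
   pose-dependent).  Hard correspondences come from the assignment solver on
   $-\log f$.  Setting `beta0 = Inf` recovers purely spatial matching.
4. **Mapping** (`map_subject()`): global affine then PWA on the current
   correspondences.
5. **Consensus refinement** (`refine_bipartite()`): position-prior and
   topology-prior similarity matrices
   $F^{spv}_{nm} = \exp[-\tfrac{1}{2\omega^2}\lVert (s_n - v_m)/\sigma_m
   \rVert^2]$ and
   $F^{tsv}_{nm} = \exp[-\tfrac{1}{2\omega^2} g(s_n,v_m)^2/\gamma_m^2]$ are
   each solved as an assignment problem; only pairs assigned identically by
   both solutions are kept, and steps 4–5 iterate until the correspondence
   set stabilises (at most 10 rounds).  A consensus smaller than 4 pairs
   cannot constrain a transform, so it falls back to the position-prior
   assignment with a warning.
6. **Final assignment** on $F^{spv} + F^{tsv}$; the reported confidence is
   the chosen entry divided by its row sum.  `omega = 1` by default — it
   rescales both kernels jointly and does not change the assignment.

The minimum-cost assignment solver is a shortest-augmenting-path
implementation validated against exhaustive enumeration on every instance up
to 7×7 in the test suite.  Rectangular problems assign the smaller side
fully; with more segmented cells than atlas entries the surplus cells come
back with `NA` identity.

For ablation studies `recognition_config(priors = ...)` restricts the
priors: `character(0)` uses distances to the average positions only, `"spv"`
adds the per-cell anisotropic position prior, and the default
`c("spv", "tsv")` adds the topology prior and the consensus refinement —
the ladder reproduced in the acceptance suite.

## 4. Synthetic data: what it emulates, and what it does not

`make_phantom()` renders densely packed, randomly oriented ellipsoidal
nuclei (semi-axis ratios within ×1.4) as blurred intensity blobs with
additive Gaussian noise, paired with exact instance masks.  Default geometry
(20×64×96 voxels, 12 nuclei of 3.6–5.9 voxel semi-axes, centre separation
≥ 15) keeps cells disconnected and their seed cores above the watershed
defaults, so segmentation accuracy reflects the learned field rather than
post-processing pathologies.

`make_synthetic_atlas()` samples uniquely identified cells in a tapered tube
(default 558 cells — the L1 whole-body count — in a 300×28×28-voxel
spindle).  Each cell carries a log-normal variability multiplier
(`heterogeneity = 0.5`): some cells are biologically more variable than
others, which is what makes the per-cell SPV prior informative.
`make_synthetic_worm()` deforms the template by, in order: a smooth random
body deformation (three sine harmonics per transverse axis plus a mild
axial compression wave, scale `bend_amp = 6` voxels), per-cell anisotropic
Gaussian jitter (default σ = (1.5, 1, 1) voxels, scaled per cell), an
optional dropout, and a bounded random affine pose.  The coherent
deformation component matters: inter-individual variability in a real
animal is dominated by posture and tissue deformation that displaces cells
*together*, preserving local neighbourhood structure — precisely the signal
the shape-context prior exploits.  A generator with only independent
per-cell jitter would scramble local topology and could not, even in
principle, show any benefit from the topology prior.

What the generators do **not** emulate: imaging artifacts in point sets
(segmentation-induced split/merge errors beyond plain dropout), spatially
varying cell density gradients of the real anatomy, intensity
heterogeneity between cell types, axial anisotropy of the point-spread
function, and any correlation between a cell's brightness and its
variability.  Passing the synthetic benchmarks therefore demonstrates the
correctness and calibration of the algorithms under controlled conditions,
not field performance on real stacks.

## 5. Problem sizes and numerical choices

The test and acceptance suites run at deliberately small scale so the whole
package validates on a single CPU in well under an hour: 3-level networks on
16×32×32 cubes (a 200-step single-cube overfit plus a 600-step run over five
phantoms), 100-cell recognition benchmarks with 15 training samples, and a
558-cell atlas with 50 samples for variability calibration.  The same code
paths scale to the full-size configurations by changing the config objects
only.

Other numerical conventions, collected in one place: seed components are
relabelled by their minimum linear array index; the watershed priority queue
breaks height ties first-in-first-out, making floods deterministic;
chi-square distances stabilise empty bins with `eps = 1e-10`; zero SPV/TSV
entries are floored at `1e-6` before entering a denominator; RPM similarity
values are floored at `1e-300` before logs; under-populated PWA windows are
widened geometrically until they hold 4 non-degenerate correspondences;
and all generators draw from `withr::with_seed()` so identical seeds give
bitwise-identical outputs.

## 6. Known limitations

* The border convention (no background outside the volume) makes
  displacement vectors of cells at the stack boundary point inward; their
  distance peaks are still correct, but seed cores of severely clipped cells
  may vanish.
* The watershed has no shape prior: non-convex or dumbbell-shaped cells can
  be split at internal distance ridges.
* PWA windows are defined along a single principal axis; strongly coiled
  (not merely bent) bodies would need a curved-axis parameterisation, which
  is out of scope here (inputs are assumed straightened).
* Recognition assumes the subject is a plausible sample of the atlas
  population; with more subject cells than atlas entries the surplus is
  left unidentified rather than modelled as a new cell type.
* TSV adds little over SPV when between-individual deformation is nearly
  affine, and it can add noise when per-cell jitter dominates; its value is
  greatest in the realistic regime of large coherent deformation with
  moderate local scatter.
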