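---
title: "Measuring chromatin fiber diameter from nanoparticle labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromatin fiber diameter from nanoparticle labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromothick)
```

## The measurement model

Electron tomograms of silver-enhanced Nanogold labeling show replicated
chromatin not as a continuous object but as clouds of discrete,
high-contrast particles (10–20 nm) decorating fiber-like structures of
the order of 100–200 nm across. Measuring a fiber diameter therefore has
two distinct halves: reconstructing a solid fiber surface from point
labels, and measuring the thickness of that reconstruction.

**Surface reconstruction by neighbor density.** For a particle set
$P$ and voxel centre $x$, the local density is

$$D_R(x) = \min\bigl(\,|\{p \in P : \lVert p - x\rVert \le R\}|,\; k\bigr),$$

a range count truncated at $k$ nearest neighbors ($k = 40$ by default).
Two parameters — the neighbor count $k$ and the expansion radius $R$ —
are exactly the knobs of this construction; $D_R$ reduces to a plain
range count when $k$ is large. Thresholding $D_R$ with the automatic
IsoData (iterative intermeans) rule produces candidate objects. The
right $R$ is not known in advance: the package sweeps $R$, counts the
thresholded objects at each radius, and looks for *plateaus* — runs of
radii over which the object count is stable. A plateau means the
density field has stopped resolving new structure at that scale: its
onset marks the edge scale of the labeled objects. Two plateaus are the
common pattern on labeled-chromatin data (individual fibers, then merged
bundles), and the package measures thickness at every plateau found.

**Thickness by medial-axis distance sampling.** The fiber mask's exact
Euclidean distance transform (EDT) assigns every interior voxel its
distance to the nearest background; sampled along the one-voxel medial
axis obtained by topology-preserving 3D thinning, these distances are
local fiber radii. Their histogram is summarized by the modal radius
(quadratically interpolated), the SD over all sampled voxels, and
SE $= \mathrm{SD}/\sqrt{n}$. The fiber diameter is reported as twice the
modal radius. The mode, not the mean, is the robust location summary
here: branch points, fiber ends and residual surface roughness all
produce a long left tail.

**Resolution control.** Fourier shell correlation between half-volumes
reconstructed from disjoint data,
$\mathrm{FSC}(S) = \mathrm{Re}\sum_{f\in S} A\bar B / \sqrt{\sum|A|^2\sum|B|^2}$
over spherical shells of physical frequency, read at the 0.143
criterion with linear interpolation between shells. No mask or
apodization is applied by default; anisotropic voxels give ellipsoidal
index shells that are spherical in physical frequency, cut at the
Nyquist of the coarsest axis.

## Choices the data forced

Several points are underdetermined by the qualitative description of the
procedure; the package resolves them as follows, and each is exposed as
a parameter.

**Plateau rule.** A plateau is a maximal run of at least `min_span = 3`
consecutive sweep radii whose counts lie within `rel_tol` of the run's
median. Object counts are small integers (often 3–6), so a tight
relative band like 0.05 admits literally no variation; `rel_tol = 0.2`
absorbs the ±1 Poisson-type flicker of threshold-marginal fragments and
is what the package's own validation runs use. Both knobs sit in
`run_config()`.

**Plateau representative: onset, not midpoint.** Within a plateau, the
object count no longer changes — but the segmented objects keep
*dilating* as $R$ grows: for $R$ well above the fiber radius the
half-density boundary sits near $0.87R$ regardless of the true size, so
the measured mode simply tracks the chosen radius. The scale the
plateau actually identifies is where the count *stops changing*, i.e.
its first radius. `detect_plateaus()` therefore represents each plateau
by its onset by default (`representative = "onset"`); the midpoint is
retained as a column and as an option.

**Segmentation radius: the saturation scale.** Within a plateau's range
the statistically best-resolved radius is the one at which a typical
labeled voxel's neighbor count reaches the cap $k$: there the IsoData
threshold settles near $k/2$ and the object boundary lands on the
half-density surface, i.e. the fiber surface. That scale is directly
estimable from the data as the median distance to the $k$-th nearest
neighbor (`knn_radius()`), about
$(3k/4\pi\lambda)^{1/3} \approx 36$ nm at the default phantom labeling
density $\lambda = 2\times10^{-4}\,\mathrm{nm}^{-3}$. The pipeline's
default `seg_rule = "sufficiency"` clamps this radius into each
plateau's range; smaller radii leave ragged, hole-ridden masks, larger
ones dilate.

**Hole filling.** A density field sampled from discrete particles has
interior dips; after thresholding these become enclosed cavities that
the EDT sees as background, biasing medial radii low. `segment_fibers()`
fills enclosed (6-connected, non-border-touching) background components
by default.

**Skeleton pruning.** Topological thinning grows a side branch toward
every surface bump, up to one object radius long; on thick fibers these
branch voxels can outnumber the true axis and drag the histogram mode
down. `local_thickness(prune_len = "adaptive")` (the pipeline default)
prunes terminal branches shorter than 80% of the mask's maximum
inscribed radius; the plain voxel-count default of `skeletonize()`
remains 3.

**Histogram and mode.** Bin width defaults to 5 nm; the mode is the
centre of the most populated bin refined by a three-point quadratic fit,
which is how sub-nanometre modes can be quoted from a binned histogram.
With the few hundred skeleton samples a 192³ phantom yields, the
Freedman–Diaconis rule suggests ~10 nm bins, and the validation runs use
`bin_width = 10`. If all radii are identical the mode is that value and
SD = SE = 0.

**EDT and border conventions.** Distances are voxel-centre to
voxel-centre, with everything beyond the volume faces counting as
background — the analogue of physical sectioning, which truncates
fibers at the slab surfaces. Because a skeleton voxel closer to a z-face
than its own radius has a face-truncated (hence meaningless) radius,
such voxels are excluded from the histogram by default
(`border_exclude = TRUE`). Anisotropic voxels are handled exactly in the
EDT (per-axis spacings in the separable transform) and by
nearest-neighbour resampling to an isotropic grid before thinning.

**Degenerate inputs.** Constant volumes refuse to threshold; empty
particle sets refuse density mapping; an all-zero density map is an
explicit empty-segmentation error; a sweep whose counts never stabilize
yields zero plateaus and the pipeline stops with the stage named.

## What the phantom emulates — and what it does not

`phantom_spec()` encodes the study conditions the generator reproduces:

* **Geometry.** Tube-like fibers along persistent random-walk
  centerlines in a slab (default 72 × 192 × 192 voxels at 4 nm — a
  288 nm section; walks are clipped at the faces as sectioning clips
  fibers). Default radius 75 nm, in the 100–200 nm diameter range
  reported for chromonema fibers. `persistence = 0.97` keeps the walk's
  curvature radius (~175 nm at 40 nm steps) above the largest tube
  radius — a tube bent tighter than its own radius would
  self-intersect. Fibers grow bidirectionally from their seed point
  (length default 1000 nm) and whole centerlines are rejection-sampled
  to stay `min_separation = 300` nm apart, emulating distinct fibers.
  The direction update draws the step cosine uniformly on
  $[2p - 1,\, 1]$, giving expected cosine exactly $p$, straight lines at
  $p = 1$ and isotropic steps at $p = 0$.
* **Labeling.** Particle counts are Poisson with mean
  `label_density` × tube volume, positions uniform in the tube; the
  default $2\times10^{-4}\,\mathrm{nm}^{-3}$ (mean spacing ~17 nm)
  represents the high-density labeling regime in which neighbor counts
  saturate $k = 40$ below the smallest fiber radius of interest.
  Background noise particles are Poisson-uniform in the box. Particles
  render as hard-edged 12 nm spheres (silver-enhanced particles are
  high-contrast; a Gaussian blob option exists for robustness checks) at
  the nearest voxel, so the rendered mass is exactly particle count ×
  blob integral.
* **Reproducibility.** One master seed expands into fixed per-stage,
  per-fiber substreams: adding a fiber does not perturb the noise field,
  and identical spec + seed gives bit-identical phantoms.

Not emulated: tilt-series projection, the missing wedge, CTF,
reconstruction artifacts, labeling-efficiency chemistry, or particle
size dispersion. Passing parameter recovery on phantoms therefore
validates the *analysis chain* — detection, density, plateaus,
segmentation, thickness, FSC — not the microscopy; on real tomograms the
absolute accuracy is additionally limited by labeling density and
reconstruction anisotropy.

One phantom-specific artifact deserves note: at high labeling density,
rendered blobs overlap and connected-component detection merges chains
of particles, roughly halving the effective marker density and blurring
centroids along fibers. Real silver particles clump too, but the
phantom's severity is a rendering choice, not data. The pipeline's
phantom mode therefore runs the density stages on the phantom's
ground-truth centroids by default
(`phantom_particles = "true"`); the rendering → detection path is
validated separately (count and sub-voxel centroid recovery on
well-separated particles, and end-to-end runs from MRC volumes) and can
be forced with `phantom_particles = "detected"`.

## Validation problem sizes

The test suite checks the voxel-level cores against brute-force oracles
(all-pairs density counts, BFS labeling, $O(V^2)$ distance maps,
exhaustive intermeans threshold search) on dozens of random ≤ 24³
instances, where exact equality is asserted. End-to-end recovery runs
noiseless phantoms with fiber radii 50/75/100 nm at 192³ voxels (4 nm),
ten seeds per radius, asserting the median recovered mode within 15% of
truth and strictly increasing in the true radius; per-seed modes carry a
few nanometres of histogram sampling noise at $n \approx 500$ skeleton
voxels, which the median absorbs. The mixed-population check (75 + 90 nm
fibers) asserts at least two plateaus across five seeds. FSC checks use
64³ volumes: identical halves at FSC ≡ 1, independent noise inside the
$3/\sqrt{n}$ null band, and half-volumes band-limited at 9 nm recovering
that cutoff within one shell at 0.143. Closed-form fixtures (a digital
cylinder of radius 15 voxels at 5 nm; a ball of radius 10 voxels) pin
the thickness and distance conventions. `scripts/acceptance.R` re-runs
this battery from a single seed and writes the numbers as JSON.

## Known limitations

* The measured mode depends on the segmentation radius whenever that
  radius is far from the saturation scale; the sufficiency rule removes
  the arbitrariness but inherits a small positive bias (~5–10%) for
  fibers thinner than the saturation radius and a comparable negative
  bias for strongly curved thick fibers.
* IsoData places its threshold slightly below half the interior density
  level (the foreground class mean includes the boundary shell), so
  masks dilate by a few nanometres; Otsu is available as an alternative.
* Topological thinning shortens skeletons at fiber ends by about one
  radius; fibers much shorter than ~3 diameters are dominated by end
  effects and their modes are unreliable.
* `min_voxels`, the particle size filter, defaults to 2 voxels; whether
  any size filtering preceded density analysis in typical practice is
  not documented, and single-voxel noise suppression is this package's
  choice.
* FSC shell width (one frequency voxel of the coarsest axis) and the
  absence of windowing are defaults, not canon; both matter only near
  the criterion crossing.
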