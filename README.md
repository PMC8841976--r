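# chromothick

Diameter morphometry of higher-order chromatin fibers from
nanoparticle-labeled electron tomograms.

## The problem

Replicated euchromatin can be visualized in 3D electron tomography by
marking nascent DNA (EdU incorporation) with Nanogold probes that are
silver-enhanced into discrete 10–20 nm electron-dense particles. The
labeled chromatin appears as fiber-like structures ("chromonemata",
~100–200 nm across) decorated by hundreds of particles per fiber. The
quantitative question is: **what is the diameter of these fibers?** The
raw data is not a solid object but a cloud of point labels, so the fiber
surface must first be reconstructed from local particle density, and only
then can a thickness be measured.

`chromothick` implements the full measurement chain:

1. **Particle detection** — automatic global threshold (iterative
   intermeans / IsoData by default) and 3D connected-component labeling
   turn the grayscale tomogram into particle centroids
   (`binarize()`, `label_particles()`, `detect_particles()`).
2. **Local density mapping** — for every voxel `x`,
   `D(x) = min(#{particles within radius R of x}, k)` with `k = 40`
   neighbors by default (`density_map()`).
3. **Radius sweep and plateau detection** — the density map is thresholded
   and its objects counted for a sweep of radii `R`; stable stretches
   (plateaus) of the count-versus-radius curve mark the scales at which
   the labeled structures are resolved — typically two
   (`sweep_radii()`, `detect_plateaus()`).
4. **Fiber segmentation** — the density map at a plateau-validated radius
   is binarized into a fiber mask (`segment_fibers()`; the radius inside
   the plateau is chosen by the neighborhood-saturation rule
   `knn_radius()`).
5. **Local thickness** — the exact Euclidean distance transform is sampled
   along the 3D medial-axis skeleton of the mask; the histogram's mode is
   the fiber radius, reported with SD, SE and the diameter `2 × mode`
   (`distance_map()`, `skeletonize()`, `local_thickness()`,
   `radius_report()`).
6. **Resolution estimation** — Fourier shell correlation between
   even/odd half-volumes, resolution read at the 0.143 criterion
   (`fsc_curve()`, `resolution_at()`).

A synthetic **phantom generator** (`phantom_spec()`, `phantom()`)
produces labeled-fiber volumes with known ground truth (centerlines,
particle positions, tube masks), so every stage is testable by parameter
recovery without any microscopy data. `run_pipeline()` orchestrates
everything with reproducible seeding and persists all intermediates
(MRC volumes, CSV tables, PNG plots, a JSON report).

## Worked example

```r
library(chromothick)

spec <- phantom_spec(volume_shape = c(96, 144, 144), n_fibers = 3,
                     fiber_radius = 75, seed = 42)
cfg <- run_config(phantom_spec = spec, decimate = 2, bin_width = 10,
                  plateau_rel_tol = 0.2, sweep_min = 20, sweep_max = 160,
                  sweep_step = 10, seed = 42)
report <- run_pipeline(cfg)
print(report)
#> <run_report> 4674 particles, 2 plateau(s); 20.6s
#> # A tibble: 2 x 7
#>   label     segmentation_radius_nm modal_radius_nm sd_nm se_nm     n diameter_nm
#>   <chr>                      <dbl>           <dbl> <dbl> <dbl> <int>       <dbl>
#> 1 plateau_…                   38.4            68.2  15.4  1.00   237        136.
#> 2 plateau_…                   80              84.2  25.3  1.44   308        168.
```

The phantom contains three 75 nm-radius fibers. The sweep shows two
plateaus; at the first (individual fibers) the measured modal radius is
68.2 nm (SD 15.4 nm over 237 skeleton voxels), i.e. a 136 nm fiber
diameter; the second plateau describes the coarser merged scale. On real
tomograms the same call takes `volume_file = "tomogram.mrc"` (or a
particle CSV) instead of a phantom spec. `tidy()`, `glance()` and
`autoplot()` methods give tibble summaries and ggplot figures of sweeps,
histograms and FSC curves.

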