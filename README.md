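# centriolr

Quantification of centriole-group migration in the olfactory epithelium.

Olfactory sensory neurons (OSNs) are born near the basal lamina of the
olfactory epithelium and must move dozens of centrioles 50–100 µm up the
growing dendrite before those centrioles can dock at the dendritic knob
and template the sensory cilia. Measuring that process from fluorescence
microscopy involves a chain of quantification steps — counting
diffraction-limited centriole puncta in 3D, matching cilia to the
centrioles that nucleate them, clustering puncta into migrating groups,
tracking groups through time-lapses, scoring group positions against
epithelial landmarks, and testing drug effects on paired explant counts.
`centriolr` implements that chain as a tested R package, together with a
synthetic-scene simulator that provides ground truth for every stage.

## What the package computes

* **Simulation** (`scene_config`, `generate_knob_scene`,
  `generate_timelapse`, `generate_count_table`): dendritic knobs bearing
  *n* centriole puncta (anisotropic 3D Gaussians) with attached
  filamentous cilia, 4D time-lapses of puncta clusters moving along the
  apical axis beside a static fiducial cluster, and paired drug/control
  Poisson count tables — all with exact ground truth and mandatory seeds.
* **Detection** (`detect_spots`, `detect_cilia`, `associate`,
  `count_centrioles`): multi-scale Laplacian-of-Gaussian blob detection
  with sub-voxel refinement; filament tracing by Hessian tubeness,
  geodesic path extraction, spine re-centering and half-maximum end
  refinement; and one-to-one centriole–cilium matching by optimal
  assignment within a capture radius. The associated fraction is
  `matched spots / all spots`.
* **Grouping** (`cluster_groups`, `measure_lag`): single-linkage
  clustering at a physical cutoff into migrating groups (id ≥ 0) and
  singletons (id −1), and the arc-length lag of a group behind the
  dendrite tip.
* **Tracking** (`project_side_view`, `link_tracks`, `classify_direction`,
  `build_kymograph`): maximum-intensity side views, greedy
  nearest-neighbour linking with gap bridging and fiducial drift
  correction, net rates defined as
  (last − first observed position) / elapsed time (a regression rate is
  reported alongside), apical/basal/none direction classes, and
  kymographs sampled along a polyline.
* **Compartments** (`classify_compartment`, `tabulate_counts`,
  `linear_density`, `read_count_table`): subapical versus middle/basal
  classification against landmark polylines (closed on the apical side),
  with counts normalized per 100 µm of basal-lamina arc length.
* **Statistics** (`summary_stats`, `sem`, `paired_permutation_test`,
  `pair_counts`, `fold_change`, `traversal_time`): mean/SD/SEM with the
  n−1 convention, the paired sign-flip permutation test of the mean
  drug − control difference (exact enumeration when `2^n_pairs` fits the
  resampling budget, add-one Monte-Carlo otherwise), fold changes of
  normalized densities, and traversal-time arithmetic.

## Worked example

```r
library(centriolr)

cfg   <- scene_config(seed = 42)               # 0.27/0.11/0.11 um voxels
scene <- generate_knob_scene(cfg, n_centrioles = 36, n_cilia = 31)
scene$image
#> <voxel_grid> 1 t x 2 c x 64 z x 160 y x 160 x
#>   spacing (z,y,x): 0.27 x 0.11 x 0.11 um
#>   channels: centrin, actub
#>   apical: decreasing z

spots <- detect_spots(scene$image, channel = "centrin")
cilia <- detect_cilia(scene$image, channel = "actub")
associate(spots, cilia, capture_radius_um = 0.5)
#> <association_result> 31/36 spots matched to 31 cilia (fraction 0.861)
```

All 36 simulated centrioles are recovered, the 31 cilia are traced, and
each cilium base is matched to its anchoring centriole, so the ciliated
fraction is 31/36 ≈ 86%. The same stages run on real TIFF stacks read
with `read_stack()`.

Drug-versus-control scoring uses the paired permutation test:

```r
ct  <- generate_count_table(
  n_animals = 2,
  drug_multiplier_by_compartment = list(subapical = c("1h" = 1.38,
                                                      "6h" = 2.58)),
  seed = 7)
paired_permutation_test(pair_counts(ct), n_resamples = 10000, seed = 1)
#> Paired sign-flip permutation test
#>   statistic: mean paired difference (drug - control) = 1.726 (n_pairs = 8)
#>   p-value (two.sided): 0.02344 [exact enumeration]
```

With 8 pairs the `2^8 = 256` sign patterns are enumerated exactly, so the
p-value is a lattice value `k/256`. A traversal-time sanity check:
`traversal_time(100, 0.18)` returns `9.26` hours for a 100 µm epithelium
at the fastest observed group rate.

A command-line wrapper over the same functions is installed at
`inst/scripts/centriolr-cli.R`
(`simulate | detect | cilia | associate | group | score | test | run`).

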