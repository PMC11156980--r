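# osmapr — orientation-selectivity map analysis for retinal calcium imaging

`osmapr` analyzes population calcium imaging of retinal neurons responding
to moving bars, and maps how orientation selectivity is organized across
the retina. It is written for retinal physiologists working with
two-photon or epifluorescence recordings of the ganglion cell layer: many
fields of view (FOVs), hundreds of segmented cells each, k stimulus
directions x R repetitions of dF/F per cell.

The package covers the full chain:

- **Tuning** — response quality index
  `QI = Var_t[<C>_r] / <Var_t[C]>_r` (1 for perfectly repeatable
  responses); vector-sum tuning
  `L_dir = |Σ_k R(θ_k) e^{iθ_k}| / Σ_k R(θ_k)` and its double-angle
  counterpart `L_ori = |Σ_k R(θ_k) e^{2iθ_k}| / Σ_k R(θ_k)`, whose phase
  (halved, for `L_ori`) gives the preferred direction/orientation; and the
  contrast indices DSI = (pref − null)/(pref + null) and
  OSI = (pref − orth)/(pref + orth).
- **Significance** — block-shuffled permutation test: direction labels of
  whole trials are permuted 1000 times and a cell is orientation- or
  direction-selective iff its observed `L_ori` / `L_dir` strictly exceeds
  more than 95% of the permuted values; cells are classified OS / DS /
  both / none.
- **Subtypes** — k-means over k = 2..10 on ON-OFF response features with
  silhouette scoring `SV(i) = (b(i) − a(i)) / max(a(i), b(i))`, a
  permuted-data control, and centroid-rule naming of the sustained-ON
  (ONs), transient-ON (ONt) and OFF groups.
- **Map statistics** — orientation histograms by retinal region, signed
  deviation of preferred axes from the ventral cardinal axis versus
  distance from the optic nerve, vector flow fields, and KS + permutation
  comparisons of regional distributions.
- **Concentric model** — preferred orientation modeled as the tangent of
  concentric circles/ellipses anchored at a retinal point; exact
  line–conic intersections, tangent axes via
  `atan2(y_r² (x − x_c), −x_r² (y − y_c))`, quadratic fits of deviation
  versus distance, and a deterministic grid search for the anchor and the
  horizontal/vertical radius ratio minimizing the area between data and
  model fits.
- **Synthetic retina** — a generator that emulates the study conditions
  (425 µm FOVs, 590 ± 170 cells, ~30% OS / 12% DS / <1% both, ONs/ONt/OFF
  = 70/20/10 with inversely ordered tuning, concentric-ellipse map with a
  ventral anchor and 1.09 aspect, orthogonal minority group), so every
  stage is testable with known ground truth.

Conventions: origin at the optic nerve, +x temporal, +y dorsal;
orientation axes in [0°, 180°), directions in [0°, 360°); deviation from
the ventral (vertical) axis is `90° − axis`, negative toward ventronasal,
positive toward ventrotemporal.

## Worked example

```r
library(osmapr)

cfg  <- retina_config(n_fovs = 20L, cells_per_fov_mean = 120,
                      cells_per_fov_sd = 30, seed = 7L)
pipe <- pipeline_config(retina = cfg, seed = 7L, output_dir = "demo_out")
res  <- run_pipeline(pipe)

table(res$classified$selectivity_class)
res$onoff_clusters$chosen_k
table(res$os_cells$subtype_called)
res$model_fit$anchor; res$model_fit$aspect
res$region_comparison
```

This simulates 20 ventronasal/ventrotemporal FOVs (2460 cells), computes
dF/F tuning summaries, tests selectivity (1000 permutations per cell and
statistic), clusters the OS cells, and fits the concentric map. It prints:

```
both   DS none   OS
  13  366 1252  798

chosen k (ON-OFF clustering): 3

OFF ONs ONt
 46 617 148

fitted map: anchor ( -100 , -200 ) um, aspect 1.02

Region comparison (more vs less ventral FOVs (median center y))
  n = 336 vs 328;  KS D = 0.3266 (p = 8.88e-16);  permutation p = 0.000999
```

Reading the numbers: 33% of quality-passing cells test orientation
selective and 0.5% are selective in both spaces; silhouette analysis
recovers exactly the three generated kinetic subtypes with ONs most and
OFF least prevalent; the fitted anchor lands ~50 µm from the generating
anchor (−100, −250) µm, while the aspect ratio at this modest FOV count
sits below the generating 1.09 — pinning the aspect needs the larger
map-study design used in the acceptance analysis (100 FOVs; see the
vignette on identifiability). The regional comparison shows what the
ventral-anchored map predicts: more-ventral FOVs have preferred axes
deviating farther from the ventral axis.

Every stage table is also written to `demo_out/` as CSV with a JSON
manifest; reruns with the same seed are byte-identical.

## Documentation

The methods vignette (`vignettes/orientation-map-analysis.Rmd`) describes
the models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical choices and degenerate-input policies, and known limitations.
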