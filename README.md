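# crownfit

Digital metrology for the **marginal and internal fit of crown-shaped
restorations** from 3D surface meshes. crownfit is for dental-materials and
prosthodontics researchers who measure how well crowns (e.g. zirconia crowns
from different sintering protocols) fit a prepared abutment, entirely from
intra-oral-scanner meshes — no sectioning, no replicas.

## What it computes

* **Marginal fit — absolute marginal discrepancy.** The finish line of the
  preparation and the margin of the crown are represented as closed 3D
  curves (ordered from ~50 annotated landmarks). The per-crown metric is
  their symmetric **Hausdorff distance**

  H(A, B) = max { max_a min_b ‖a − b‖ , max_b min_a ‖a − b‖ } ,

  evaluated point-to-segment on densified curves and reported in µm.

* **Internal fit — sampled gap field.** The crown intaglio is sampled with
  **dart-throwing Poisson-disk sampling** (uniform by area, minimum pairwise
  spacing guaranteed), and each sample's distance to the opposing abutment
  surface is measured (exact point-to-triangle; a graph-geodesic mode is
  available for sensitivity analysis). The per-crown metric is the mean gap
  in µm, with histogram and colour-PLY deviation-map outputs.

* **Reference best-fit alignment.** Scans are registered rigidly by
  **trimmed ICP**: only correspondences below a predefined distance
  threshold drive the update; no scaling, deterministic tie-breaks.

* **Cohort comparison.** Pooled two-sample t tests (df = n1 + n2 − 2) on
  per-crown metrics, computable from raw values **or directly from printed
  summary statistics** (n, mean, SD), with the two-sided p-value from the
  regularized incomplete beta.

* **Synthetic studies.** A generator builds abutment/crown cohorts with
  analytic ground truth (cementation spacer, occlusal doming, shrinkage,
  margin extension, scanner noise, residual seating transform), so the whole
  chain is testable without any scan data.

File formats: STL (binary + ASCII, read/write), colour PLY (write), plain
text for landmarks (`x y z` per line), transforms, configs and reports.
Geometry is handled in mm; metrics are reported in µm.

## Worked example

Reproduce a published-style comparison straight from summary statistics
(two cohorts of 30 crowns; marginal-fit means 419.384 and 400.482 µm, SDs
24.558 and 41.430 µm):

```r
library(crownfit)
cmp <- student_t_from_summaries(
  group_summary("conventional", 30, 419.384, 24.558),
  group_summary("high-speed",  30, 400.482, 41.430))
print(cmp)
#> <group_comparison> independent-sample t test (pooled)
#> <group_summary> conventional: n = 30, mean = 419.384 um, sd = 24.558 um
#> <group_summary> high-speed: n = 30, mean = 400.482 um, sd = 41.430 um
#>   t(58) = -2.150, p = 0.036 (significant at alpha = 0.05)
#>   sign convention: t is computed on high-speed mean minus conventional mean
#>   note: normality of the per-crown metrics is assumed, not tested
```

The high-speed cohort's maximum marginal discrepancy is significantly
smaller (t(58) = −2.150, p = 0.036): the sintering protocol affects the
marginal fit at α = 0.05.

End-to-end on synthetic data — generate two 2-crown cohorts with a 40 µm
spacer and no distortion, write the STL/landmark file tree, and run the
whole pipeline (align → marginal fit → internal fit → t tests):

```r
dir <- tempfile("demo")
make_cohorts(crown_spec_distribution(label = "conventional"),
             crown_spec_distribution(label = "highspeed"),
             n_per_group = 2, master_seed = 11,
             abutment = abutment_spec(mesh_resolution = 0.25),
             out_dir = dir)
report <- run_pipeline(list(
  abutment_mesh      = file.path(dir, "abutment.stl"),
  abutment_landmarks = file.path(dir, "abutment_margin.xyz"),
  group1_dir = file.path(dir, "conventional"),
  group2_dir = file.path(dir, "highspeed"),
  group1_label = "conventional", group2_label = "highspeed",
  disk_radius = 0.2, seed = 5))
report$per_crown[, c("group", "marginal_hausdorff_um", "internal_mean_um")]
#>          group marginal_hausdorff_um internal_mean_um
#> 1 conventional              4.257815         40.23843
#> 2 conventional              1.476706         39.73778
#> 3    highspeed              3.823461         40.22108
#> 4    highspeed              1.698733         39.78184
```

Both cohorts recover the designed 40 µm spacer to well under 1 µm through
mesh write/read, landmark ordering, marginal-ROI trimmed-ICP alignment and
Poisson-disk gap sampling; the marginal discrepancy sits at the
noise-plus-alignment floor of a few µm.

A thin CLI wraps the same functions (`exec/crownfit`): subcommands `synth`,
`align`, `margin`, `margin-fit`, `internal-fit`, `compare`, `run`.

See `vignettes/crownfit-methods.Rmd` for the model, parameter meanings,
design choices and limitations.

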