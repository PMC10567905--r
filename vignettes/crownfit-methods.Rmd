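---
title: "Measuring marginal and internal crown fit from surface meshes"
author: "crownfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring marginal and internal crown fit from surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownfit)
options(crownfit.quiet = TRUE)
```

## The measurement problem

How well a milled crown fits its prepared tooth is described by two
quantities. The *marginal fit* is the discrepancy between the finish line of
the preparation (the "marginal line") and the corresponding edge of the
crown; a large marginal gap exposes cement and predisposes to secondary
caries. The *internal fit* is the space between the prepared tooth surface
and the crown's intaglio (inner) surface; some space is designed in — the
cementation spacer, typically 40 µm starting 0.5 mm above the finish line —
but manufacturing distortion (notably sintering shrinkage of zirconia) adds
to it unevenly.

crownfit implements a fully digital measurement chain for these quantities
from triangle surface meshes:

1. **Margin curves.** Annotated margin landmarks (conventionally 50 points)
   are ordered into a closed polyline by projecting onto their best-fit
   plane and sorting by polar angle. This assumes the finish line is a
   near-planar ring, which holds for molar preparations; geometry that
   fails a ring test (projected radius sd/mean > 0.9, or two landmarks at
   the same polar angle) is rejected with advice to supply ordered input
   rather than silently mis-ordered.
2. **Alignment.** Scans are brought into the reference frame by a
   *reference best-fit* registration: trimmed iterative closest point,
   where only correspondences with residuals below a predefined threshold
   drive the rigid update. Scaling is never estimated — a fit discrepancy
   must not be absorbed by scale.
3. **Marginal fit.** The absolute marginal discrepancy is the symmetric
   Hausdorff distance between the abutment and crown margin curves,
   \(H(A,B)=\max\{\max_{a\in A}\min_{b\in B}\|a-b\|,\;
   \max_{b\in B}\min_{a\in A}\|a-b\|\}\), reported in µm. Distances are
   point-to-segment, so the metric converges as curves are densified; both
   curves are resampled to 500 equally spaced points by default, with a
   raw-landmark mode retained for sensitivity analysis. The per-crown
   statistic is this maximum (not a mean gap), which is why marginal-fit
   values from this metric run higher than mean-gap figures from
   cross-sectioning studies.
4. **Internal fit.** The intaglio surface is sampled by dart-throwing
   Poisson-disk sampling (uniform by area, minimum pairwise spacing
   guaranteed and asserted) and, for each sample, the gap to the opposing
   surface is measured. The per-crown statistic is the mean gap in µm.
5. **Cohort statistics.** Two cohorts of per-crown metrics are compared
   with a pooled two-sample t test (df = n1 + n2 − 2), computable either
   from raw values or directly from printed summary statistics, with the
   two-sided p-value obtained from the regularized incomplete beta
   \(p = I_{df/(df+t^2)}(df/2, 1/2)\).

## What "gap distance" means between two disjoint surfaces

A shortest-path ("geodesic") distance between a node on the tooth surface
and a node on the intaglio surface is geometrically ambiguous when the two
surfaces are disjoint: a graph path must jump between the meshes somewhere.
crownfit therefore provides two modes and logs the choice in every report:

* `nearest_surface` (default): the exact Euclidean distance from each
  intaglio sample to the opposing abutment surface (point-to-triangle,
  minimised over all faces). This is the standard cement-gap reading and
  the mode behind all headline numbers. Gaps are signed: positive when the
  sample lies on the outward side of its closest abutment triangle,
  negative when the intaglio penetrates the abutment (physically
  impossible after seating; a useful diagnostic of alignment faults).
  Signing requires consistently wound abutment normals, which is checked.
* `edge_graph_geodesic`: Dijkstra shortest paths on the union of both
  meshes' vertex-adjacency graphs, with each sample bridged to its three
  nearest abutment vertices and to its containing intaglio face corners by
  Euclidean-weighted edges. Graph paths can never beat the Euclidean
  minimum, so this mode is an upper envelope of the first; it is retained
  for sensitivity analysis of the "shortest path" reading.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| vertex merge tolerance | 1e-6 | mm | STL facet dedup on load; far below scanner noise |
| ICP inlier threshold | 0.5 | mm | reference best-fit trimming; a free choice, always logged |
| ICP convergence tol | 1e-5 | mm | change in inlier RMS that stops iteration |
| curve samples | 500 | – | densification per margin curve for the Hausdorff metric |
| Poisson-disk radius | 0.15 | mm | sample spacing; ~thousands of samples on a molar-scale crown |
| marginal ROI band | 0.5 | mm | margin + surface 0.5 mm above the finish line, used for alignment |
| internal exclusion | 0.6 | mm | samples this close to the margin belong to the marginal—not internal—region |
| alpha | 0.05 | – | significance level of the cohort comparison |

All geometry is millimetres internally; fit metrics are reported in µm.
STL carries no units, so the unit assumption is logged loudly on every
read. Sampling seeds are mandatory wherever randomness enters.

Numerical conventions: closest-face ties are broken by the lowest face
index, so distance queries and ICP are deterministic; an ICP update that
would increase the inlier RMS is rejected and terminates iteration, making
the objective non-increasing; p-values are stored at full precision and
rounded only for display.

## The synthetic study and its ground truth

No scan data ship with the package, so the generator builds cohorts with
known truth. The abutment is a parametric solid of revolution — base
radius 4.5 mm, wall to a 3.5 mm top radius over 5 mm height, a 1.0 mm
quarter-round chamfer whose outer rim is the margin, and a rounded-edge
flat occlusal table. Anatomy is deliberately absent: metric correctness
does not depend on it, and the simple geometry admits analytic oracles
(margin circumference, band areas, exact nominal gaps).

The crown intaglio is the abutment surface offset outward along vertex
normals by the spacer profile (zero below 0.5 mm above the margin,
blended over 0.1 mm, the spacer above), then distorted: occlusal doming
(a vertical lift, full over the occlusal table and cosine-tapered to zero
at the wall, emulating the occlusally concentrated sintering distortion
reported for zirconia crowns), uniform shrinkage about the centroid,
margin extension (radial displacement of the crown margin, decaying to
zero 0.3 mm up), isotropic Gaussian scanner noise, and a small residual
seating transform. Truth is captured *before* noise, so it describes the
noise-free nominal gap; recovery tests measure within the fully offset
zone (one mesh edge above the end of the spacer blend) because faces
straddling the blend are only partially offset. Cohort parameters are
drawn from normal distributions truncated at ±3 sd and at physical
bounds.

Default cohort conditions: a 40 µm spacer in both groups; the
conventional-sintering group draws occlusal doming ~ N(180, 25²) µm and
margin extension ~ N(0.10, 0.02²) mm, the high-speed group N(120, 15²) µm
and N(0.08, 0.015²) mm; scanner noise 5 µm; residual seating rotation
0.2° sd and translation 0.02 mm sd. The doming contrast follows the
configured-effect example used throughout the test suite; the extension
and seating scales are what a well-seated, lightly distorted crown would
plausibly show. These distributions are *not* calibrated to reproduce any
particular published spread and make no such claim; the published
statistics themselves are reproduced exactly from their printed summary
inputs instead.

What the generator does **not** emulate: real tooth anatomy, scanner
artefacts beyond isotropic noise (no patch seams, no specular dropouts),
remeshing/optimization of scans, cement films, or physically based
sintering mechanics. Passing recovery tests therefore demonstrate that
the *measurement chain* is unbiased at the micrometre scale on clean
geometry, not that it is robust to every scanner pathology.

## Pipeline alignment choice

A real study aligns each scan to a reference quadrant scan. The synthetic
study has no quadrant, so the pipeline aligns each crown by trimmed ICP of
its *marginal ROI* (the band within 0.5 mm of the crown margin) onto the
reference abutment: for a seated crown the designed gap in that band is
zero, so the band is the crown's most reference-like region. Aligning on
the full intaglio instead would let the optimizer sink the crown by part
of the spacer and bias gaps low — the exact error the reference best-fit
technique exists to avoid.

```{r demo, eval = FALSE}
dir <- tempfile("demo")
make_cohorts(crown_spec_distribution(label = "conventional"),
             crown_spec_distribution(label = "highspeed"),
             n_per_group = 2, master_seed = 11,
             abutment = abutment_spec(mesh_resolution = 0.25),
             out_dir = dir)
report <- run_pipeline(list(
  abutment_mesh = file.path(dir, "abutment.stl"),
  abutment_landmarks = file.path(dir, "abutment_margin.xyz"),
  group1_dir = file.path(dir, "conventional"),
  group2_dir = file.path(dir, "highspeed"),
  group1_label = "conventional", group2_label = "highspeed",
  disk_radius = 0.2, seed = 5))
report
```

## Problem sizes

The suite and the acceptance study run at a target mesh edge length of
0.20–0.30 mm (roughly 10⁴ faces per surface) with Poisson-disk radii of
0.20–0.25 mm (2–3·10³ samples per crown). These sizes were chosen because
the analytic recovery errors they leave — faceting of the curved chamfer
and occlusal bevel — are already below 1–2 % of the quantities measured,
and finer meshes only polish digits the tolerances do not see. The
generator default of 0.1 mm reproduces intra-oral-scanner-like density
when higher fidelity is wanted.

## Known limitations

* Margin-landmark ordering assumes a ring-like margin; extreme vertical
  scalloping (anterior preparations) could defeat the planar angular sort.
  The failure is detected, not repaired.
* The ROI band uses 3D point-to-polyline distance, not along-surface
  distance; at the 0.5 mm scale the difference is below facet error on
  the fixtures used here.
* `edge_graph_geodesic` distances depend on mesh resolution through the
  bridging edges; they are a sensitivity check, not a calibrated metric.
* The Hausdorff marginal metric is a maximum and inherits its statistical
  fragility: one bad landmark inflates it. The mean curve gap is reported
  alongside as a diagnostic.
* Shapiro–Wilk normality screening of per-crown metrics is out of scope;
  reports state that normality is assumed.
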