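---
title: "Methods: organelle morphometry and distance-banded contact mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle morphometry and distance-banded contact mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgContact)
```

# The measurement model

`orgContact` treats an instance-segmented label volume — a 3D integer
grid in `(z, y, x)` order with a physical voxel pitch, canonically 8 nm
isotropic for FIB-SEM liver data — as the primary observation. Three
families of quantities are derived from it.

**Morphometry.** Per instance: volume $V$ = voxel count × voxel volume;
surface area $SA$ by one of two estimators (below); Wadell sphericity
$\psi = \pi^{1/3}(6V)^{2/3}/SA$; and the mitochondrial complexity index
$\mathrm{MCI}^2 = SA^3/(16\pi^2 V^2)$, both dimensionless and invariant
to uniform rescaling. The bivariate "complex" class is the fraction of
objects with $\mathrm{MCI}^2 > 5$ and $V > 3\,\mu m^3$ (both thresholds
adjustable).

**Contact.** The outer shell of each mitochondrion is the object minus
its one-step erosion (a single-voxel layer; out-of-volume counts as
background, so faces at the volume boundary are shell). The partner mask
is expanded by iterated one-voxel dilations of a face-connected cross,
which realizes discrete city-block distance: after $k$ iterations the
front has reached exactly the voxels at city-block distance $\le k$
through the allowed region. Contact in band $(lo, hi]$ nm is the set of
shell voxels first reached at an iteration in
$(\lfloor lo/p \rfloor, \lfloor hi/p \rfloor]$ at pitch $p$; inner bands
claim voxels exclusively, so the 25–56 nm band never re-counts a voxel
already inside 24 nm. Fractions divide by the instance's shell size. The
voxel-by-voxel profile reports, per iteration, the newly claimed shell
voxels; its cumulative sum at step $k$ equals the $0..kp$ nm band total
by construction, a conservation law the test suite asserts.

**Inference.** Group comparisons use a permutation test on pooled
per-object values (two-sided absolute difference of means) and bootstrap
percentile confidence intervals; frequency distributions use fixed,
half-open bins (last bin closed).

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| voxel pitch | 8 nm (isotropic) | physical size of a voxel; band-to-iteration conversion requires isotropy |
| bands | 0–24, 25–56 nm | MAM band (3 iterations) and rough-ER-sheet band (iterations 4–7); 2D TEM uses 0–24 / 25–80 nm |
| connectivity | 26 | component labeling ("full connectivity"); 6 and 18 available |
| `sa_method` | `"mesh"` | see estimator study below; `"voxel_face"` for voxel-native replication |
| `min_voxels` | 0 | proof-reading size floor; named presets carry the per-dataset minima used on the study data (e.g. `lean_fasted` = 92,243 voxels, ER floor 1e5) |
| `n_perm` | 1e5 | Monte-Carlo permutations |
| `n_boot` | 20 | bootstrap replicates (see caveat below) |
| bin width | 5 % | zonation binning; bins labeled by lower edge, summary bins 10 and 90 |

# Surface-area estimator

Voxel-face counting over-estimates the area of smooth bodies by a
orientation-dependent factor (3/2 for a sphere), which would bias
$\psi$ and $\mathrm{MCI}^2$; it is kept as an explicit option because
voxel-native pipelines report exactly that quantity. The default mesh
estimator was chosen after a digitization study on digital balls:

* marching cubes/tetrahedra on the raw binary grid: flat ≈ 8.5%
  over-estimate at all radii (cross-checked against an independent
  marching-cubes implementation);
* meshing a Gaussian-smoothed binary grid: a curvature-dependent
  shrinkage at small radii plus a scale-independent residual, so the
  error does not vanish with size;
* **adopted**: marching tetrahedra (Kuhn 6-tetrahedra decomposition, all
  crossings linearly interpolated) on the zero level of a signed
  Euclidean distance field (exact separable EDT, inside minus outside),
  regularized with a σ = 1 voxel Gaussian. The distance field carries
  true sub-voxel geometry, so the error decreases with object size:
  sphericity of digital balls of radius 5, 10, 20, 40 voxels measures
  1.108, 1.023, 1.004, 0.9994 — monotone convergence of $|\psi - 1|$,
  within 0.4% at radius 20.

Because the estimator is near-unbiased, the sign of its small error is
not fixed; convergence is therefore asserted as a shrinking $|\psi-1|$,
not one-sided approach. Objects with radius below ~5 voxels (40 nm) are
at the digitization limit and their $\psi$ can exceed 1 by up to ~10%;
at realistic mitochondrial sizes (≥ 30 voxels radius at 8 nm) the error
is far below other sources of variation.

# Contact-engine numerics

*Metric.* The default `volume3d` mode dilates with the full 3D 6-neighbor
cross. The original analysis described plane-wise operations, which in
slice-oriented software means 2D morphology per z-slice; a
`planewise_xy` fidelity mode (4-neighbor cross per slice, erosion
included) is provided. Neither is asserted to be exactly what the
original software executed; the 3D mode is geometrically isotropic and
is the package default.

*Masking.* Dilation never expands through a mitochondrial interior
(interior = object minus shell): contact is by exterior approach. The
front therefore computes a geodesic city-block distance, which equals the
plain city-block distance whenever no shortest path is forced through an
organelle interior. With bands up to 7 iterations this holds as long as
organelles are thicker than the band reach; the synthetic generator's
4-voxel minimum radius guarantees it on generated scenes, which is what
makes the brute-force plain-distance oracle in the tests exact. Partner
voxels that overlap a mitochondrion (segmentation conflicts) seed the
front at distance 0, count toward the innermost band, and are reported
via a message.

*Band conversion.* Iterations = ⌊hi nm / pitch⌋, anchored at
24 nm → 3 voxels and 56 nm → 7 voxels for 8 nm data; a non-multiple
upper bound warns and floors. Anisotropic pitches are rejected for nm
conversion (the discrete metric would no longer be isotropic).

*Degenerate inputs.* Empty partner masks give zero fractions; empty
label volumes give empty tables; a single-voxel object is its own shell.

*Lipid-droplet prevalence.* The "% of mitochondria displaying
interaction" statistic needs a cut-off that the source material does not
state; the package default counts a mitochondrion as interacting when at
least one shell voxel lies within the innermost band (≥ 1 voxel,
0–24 nm), with both voxel-count and fraction thresholds exposed.

# 2D TEM analysis

The 2D path is deliberately a different metric: the TEM macro is a
distance map, so the exact Euclidean distance transform is used
(delegated to EBImage's exact EDT), not discrete dilation. Coverage is
reported per perimeter pixel (mask minus 4-neighbor erosion) as the
default statistic, with the per-ER-pixel distance distribution emitted
alongside, since the original computation could be read either way.
Roundness and aspect ratio use standard fitted-ellipse moment
definitions (axes $4\sqrt\lambda$ with the 1/12 uniform-pixel variance
correction; degenerate, collinear masks are an error); both equal 1 for
a disc by construction.

# Zonation

Profiles are affinely mapped to percent (0 = central-vein edge,
100 = portal-vein edge; reversed lines are flagged and flipped), binned
in half-open 5% bins labeled by lower edge — "bin 10" is [10, 15) — with
the last bin closed, and summarized across profiles at bins 10 and 90.
Whether the named summary bins denote lower edges or centers was an open
reading; the lower-edge convention matches the binned-percent phrasing
and is the default, and a center-labeled convention is a one-line change
at the call site (`cvBin`, `ppBin`).

# Statistics

The Monte-Carlo permutation p-value uses the +1-corrected estimator
$p = (1 + \#\{|T_\pi| \ge |T_{obs}|\})/(n_{perm}+1)$, which is a valid
p-value and can never be 0 — a deliberate deviation from a literal
proportion. With ≤ 12 units the test enumerates all splits and returns
the uncorrected proportion over the complete enumeration (the observed
split is one of them), so small examples are exact. The default
permutes at the object level after pooling; `unit = "cell"` permutes
whole cells to respect within-cell correlation. The direction of the
test is two-sided by default because the study-style comparisons are
two-condition contrasts.

Bootstrap CIs honor the field default of 20 replicates but interpolate
percentiles linearly; 20 replicates is statistically coarse for 95%
percentile intervals (the interval endpoints are then order statistics
of a sample of 20), so calibration-grade use should raise `nBoot` — the
coverage test in the suite runs at `nBoot = 2000`, where empirical
coverage of the Gaussian mean at n = 200 sits within the binomial 99%
band around 0.95. The resampling unit is the individual value
(mitochondrion); resampling cells instead was left out as the source
procedure did not specify it.

# The synthetic generator, and what passing tests do not show

`generateScene()` rasterizes balls, ellipsoids and capsules (digital
solid = voxel centers on or inside the continuous surface), wrapped ER
shells placed on the exact city-block ring $[g+1, g+t]$ of their
mitochondrion, parallel sheet stacks, tubules, lipid droplets and up to
two nuclei, and emits a manifest with voxel counts, analytic
volumes/areas where closed forms exist (Thomsen's approximation for
ellipsoid area; capsule closed form), centroids, gaps and seeds. Because
the wrap ring uses the same discrete metric as the contact engine, band
assignment of generated contacts is exact, which is what turns gap
recovery into a sharp test (gap 6 → modal step 7, the 49–56 nm bin).

The generator emulates geometry, not imaging: no EM texture, no
segmentation errors, no anisotropy, no touching-organelle ambiguity
beyond simple overlap rejection. Passing the suite therefore
demonstrates that the measurement code is correct on known geometry —
it does not validate segmentation quality, nor the biological
interpretation of band thresholds on real tissue, and absolute distances
on chemically fixed material retain the fixation caveat.

Test and acceptance problem sizes — scenes of 36–84 voxels per side,
up to ~50 random scenes per property, 500–1000 inference replicates —
were chosen so the brute-force oracles (pairwise distance scans,
exhaustive permutation enumeration) stay exact and the whole suite runs
in well under a minute of compute per property family.

# Known limitations

* HDF5 containers are not read in this build; multi-page TIFF (plus a
  JSON sidecar for metadata) is the supported container, with OME-XML
  physical sizes honored on read.
* Label ids are stored losslessly in TIFF up to 2^24 − 1.
* nm-band conversion requires isotropic voxels; metric computations
  accept anisotropic pitches but the discrete contact metric does not.
* No skeletonization/branch-graph analysis (complexity is measured by
  MCI²), no ER sheet/tubule classification (sheet masks are consumed),
  no Euclidean-distance-transform contact definition in 3D (that would
  be a different estimand than iterated dilation).
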