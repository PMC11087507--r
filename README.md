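# orgContact

Quantification of organelle architecture and inter-organelle contacts in
instance-segmented volume electron microscopy of liver tissue.

Hepatocytes remodel their endoplasmic reticulum (ER) and mitochondria as
they move between fed and fasted states: mitochondria fuse into larger,
flatter, more complex shapes, and rough ER sheets wrap around them at a
characteristic membrane-to-membrane distance, while tight smooth-ER
contacts (mitochondria-associated membranes, MAMs) sit closer. Measuring
these changes from FIB-SEM label volumes requires a reproducible pipeline:
per-mitochondrion morphometry, a principled definition of "contact at a
distance band", and inference that respects how the data were pooled.
`orgContact` provides that pipeline for anyone working with
instance-segmented 3D label volumes (plus the matching 2D TEM and
immunofluorescence-zonation analyses), together with a synthetic
label-volume generator that gives every stage analytic ground truth.

## What it computes

For each mitochondrion with surface area *SA* (µm²) and volume *V* (µm³):

- **Mitochondrial complexity index**  MCI² = SA³ / (16 π² V²)
  (0.716 for a sphere, larger for branched/flattened shapes);
- **Wadell sphericity**  ψ = π^(1/3) (6 V)^(2/3) / SA (1 for a sphere);
- *V* by voxel counting; *SA* either by a mesh estimator (marching
  tetrahedra on a regularized signed Euclidean distance field) or by
  voxel-face counting.

Contact quantification follows the dilation-band construction: the
single-voxel-thick outer shell of each mitochondrion is extracted (object
minus its one-step erosion), the partner mask (ER, ER sheets, or lipid
droplets) is expanded by iterated one-voxel dilations — 3 iterations = 24
nm, 7 = 56 nm, 10 = 80 nm at the 8 nm voxel pitch — and the contacted
shell fraction is reported per band, with inner bands claiming voxels
exclusively (0–24 nm = MAM band; 25–56 nm = rough-ER sheet band). A
voxel-by-voxel mode records, per dilation step, the newly contacted shell
voxels, yielding contact-distance profiles. Spatial statistics (distance
to the nucleus with the binucleate midpoint rule), 2D TEM distance-map
analysis (exact Euclidean, bands 0–24 / 25–80 nm, area / roundness /
aspect ratio), central-vein→portal-vein zonation profile binning (percent
positions, bin width 5, bins 10/90 summary), permutation tests
(pooled values, n = 1e5 default) and bootstrap percentile CIs
(n = 20 default) complete the pipeline.

## Worked example

Two synthetic mitochondria — a ball wrapped by ER at a 2-voxel gap (a
MAM-like tight wrap) and an ellipsoid wrapped at a 6-voxel gap over 60%
coverage (a rough-ER-sheet-like wrap):

```r
library(orgContact)
sc <- generateScene(sceneSpec(c(48, 48, 48),
  mitochondria = list(mitoBall(c(16, 16, 16), 7),
                      mitoEllipsoid(c(34, 32, 30), c(6, 9, 5))),
  erStructures = list(erWrap(1, gapVoxels = 2),
                      erWrap(2, gapVoxels = 6, coverage = 0.6, axis = "z")),
  seed = 42))

instanceMetrics(sc$mito)
#>   object_id voxels volume_um3  sa_um2 sphericity   mci2
#> 1         1   1419  0.0007265 0.03729      1.048 0.6222
#> 2         2   1105  0.0005658 0.03254      1.017 0.6816

bandContact(sc$mito, sc$er)
#>   mito_id shell_voxels contact_0_24 fraction_0_24 contact_25_56 fraction_25_56
#> 1       1          446          446             1             0          0.000
#> 2       2          406            0             0           299          0.736
```

The ball's shell is fully covered within the 0–24 nm band (its wrap sits
3 dilation steps away), while the ellipsoid registers no MAM-band contact
and 73.6% coverage in the exclusive 25–56 nm band — exactly the
constructed geometry. The voxel-by-voxel profile locates that wrap at a
single step:

```r
subset(distanceProfile(sc$mito, sc$er, maxNm = 56),
       mito_id == 2 & new_voxels > 0)
#>    mito_id step distance_nm new_voxels cumulative_voxels
#> 16       2    7          56        299               299
```

i.e. first contact at dilation step 7 (49–56 nm), the signature
distance of the fasting-induced single-ER-sheet wrap. `runPipeline()`
chains generation/reading, filtering, morphometry, contact banding,
frequency distributions and permutation/bootstrap statistics from one
declarative (YAML) config.

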