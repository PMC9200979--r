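# crc3d — 3D phenotyping of cassava root crowns

`crc3d` turns photogrammetry-derived triangle meshes of excavated cassava
root crowns (CRCs) into a reproducible trait table, and provides the
downstream statistics used in augmented-RCBD field trials. It is aimed at
cassava breeders and root-phenotyping researchers who reconstruct crowns
from field photographs (crown laid on a background sheet next to a cuboid
reference box) and need the whole analysis after mesh export to be
automatic.

## What it computes

From one crown mesh (OBJ or PLY), after noise clearing, watertight repair,
scale calibration and stem removal:

| trait | definition |
|---|---|
| 3D crown volume `V` | split-half protocol: crown cut by the vertical plane through the stem axis, each half re-closed, volumes summed |
| 3D crown surface area `A` | triangle-area sum of the repaired surface |
| crown diameter | maximum horizontal caliper (top view) |
| cylinder soil volume `V_cyl` | π r² h of the minimal vertical cylinder around the stem axis |
| CRC compactness | 100 · V / V_cyl (%) |
| root density ρ | 1000 · weight[kg] / V (g/cm³) |
| surface-to-volume ratio | A / V (1/cm) |
| root number | edge-connected components after hub clearance |
| crown root angle | mean of the 3 lowest per-root basal angles (0° = horizontal) |
| mean root length | mean per-root centerline length |

Individual storage roots are dissected digitally (`segment_roots`) and
measured for centerline length, basal angle and maximum equivalent-circle
diameter. The statistics layer implements validation regression (R² plus
mean/max absolute percentage error), Pearson correlation matrices with
significance stars (df = n − 2), correlation-matrix PCA, Federer's
augmented-RCBD adjusted means and ANOVA, and broad-sense heritability
H² = σ²G/(σ²G + σ²e) with σ²e from check replication.

A procedural generator (`generate_crown`, `simulate_defect_cohort`,
`make_trial_dataset`) builds synthetic crowns with voxel-oracle ground
truth — the in-silico stand-in for water-displacement reference
measurements — so the whole pipeline is testable without field data.

## Worked example

```r
library(crc3d)

# a synthetic crown with 7 storage roots, exported at an arbitrary scale
cr <- generate_crown(crown_spec(n_roots = 7, seed = 42))
write_mesh(scale_mesh(cr$mesh, 0.01), "crown.obj")
write_mesh(scale_mesh(box_mesh(c(12.5, 12.5, 34), center = c(60, 0, 10)),
                      0.01), "box.obj")

res <- cmd_phenotype("crown.obj", "box.obj", weight = 2.4)
res$traits
#> Crown traits:
#>   crown_volume_cm3           2878.23
#>   crown_surface_area_cm2     2447.07
#>   crown_diameter_cm          50.7235
#>   cylinder_soil_volume_cm3   75564.9
#>   compactness_pct            3.80896
#>   root_density_g_cm3         0.833845
#>   surface_to_volume_per_cm   0.850198
#>   root_number                7
#>   crown_root_angle_deg       31.4661
#>   mean_root_length_cm        21.4467
#>   root_weight_kg             2.4
```

The mesh was written at 1/100 scale; calibration against the 34 cm box
dimension recovers `scale_factor = 100`, so all traits are in physical cm.
The generator's voxel-oracle volume for this crown is 2870.6 cm³ — the
pipeline's split-half estimate lands within 0.3%. All seven roots are
recovered; the mean centerline length (21.4 cm) matches the generator's
ledger (21.1 cm). Compactness of 3.8% says this crown fills under a
twenty-fifth of its enclosing soil cylinder — wide-spreading, shallow
architecture.

A command-line wrapper is installed with the package
(`system.file("exec", "crc3d", package = "crc3d")`) with subcommands
`phenotype`, `batch`, `simulate`, `validate` and `trial-stats`.

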