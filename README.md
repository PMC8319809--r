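# nanocontact

Quantifying physical interactions between bacteria and nanostructured
surfaces from FIB-SEM slice-and-view stacks.

Nanopillar surfaces (TiO2 on titanium, black silicon) can deform,
penetrate, rupture or laterally impede bacterial cells; resolving which
mechanism a given surface exerts requires the full 3D adhesion interface.
Focused ion beam scanning electron microscopy supplies it as an anisotropic
stack of milled cross sections. `nanocontact` turns such stacks - or
ground-truthed synthetic phantoms of them - into per-nanostructure
interaction classifications and per-cell morphometric reports:

* **phantom** - synthetic scenes: nanopillar fields with the four
  characterized surface presets (`ah-ns-medium`, `to-ns-short`,
  `to-ns-long`, `pe-ns-short`), rod (*E. coli*) and coccus (*S. aureus*)
  cells, imposed interactions (penetration depth, deformation dimple,
  lateral impedance, rupture volume loss), and simulated acquisition
  (52-degree stage-tilt foreshortening, per-slice drift, noise, texture,
  curtaining), with every realized value recorded as ground truth;
* **stack processing** - translation alignment by cross-correlation,
  `1/sin(tilt)` foreshortening correction, multi-level segmentation with
  morphological cleanup;
* **reconstruction** - watertight triangle meshes per object (marching
  tetrahedra, guaranteed closure) and per-pillar connected components,
  OBJ in/out;
* **morphometry** - envelope surface area (um^2), cell volume (um^3,
  divergence theorem), penetration depth (anisotropic Euclidean distance
  transform), deformation depth against a reference surface, nanopillar
  tip contact areas and tip/sidewall contact zones;
* **classification** - the explicit decision ladder
  rupture > penetration > deformation > impedance > none, with
  config-exposed thresholds;
* **reporting** - per-cell report rows (counts, percentages, mean depths,
  total contact area, contact % of envelope), CSV/JSON export, and a
  one-call `run_pipeline()` that writes every artifact plus a
  ground-truth comparison.

## Worked example

Simulate an *E. coli* cell on the densest surface with 24 contacting
pillars, two of them penetrating, then run the full pipeline on the
corrupted stack:

```r
library(nanocontact)

run <- run_pipeline(list(
  preset = "pe-ns-short", cell_kind = "rod",
  interactions = c(rep("penetration", 2), rep("none", 22)),
  cell_length_nm = 3000,
  seed = 3, out_dir = "pe-run"))

run$reports[[1]]
#> <cell_report>
#>   cell_id                      1
#>   envelope_surface_area_um2    4.8
#>   cell_volume_um3              0.55
#>   n_penetrating                2
#>   pct_penetrating              8.33
#>   mean_penetration_depth_nm    46.21*
#>   n_deforming                  0
#>   pct_deforming                0.00
#>   mean_deformation_depth_nm    -
#>   n_impeding                   0
#>   pct_impeding                 0.00
#>   total_contacts               24
#>   total_tip_contact_area_nm2   766441
#>   contact_surface_area_pct     15.86
```

All 24 contacts are recovered and the two imposed penetrations are
classified as penetrations, with depths read from the interior distance
field (truncated table rendering: `8.33` is 2/24 truncated to two
decimals, the `*` marks a depth mean over several contacts), and
`pe-run/comparison.json` tabulates every measured value against the
phantom's ground truth. `pe-run/` also holds the simulated stack
(multipage TIFF + JSON sidecar), true and segmented label volumes, OBJ
meshes, contact records and the run log.

Lower-level entry points do the same stepwise: `phantom_scene()` /
`compose_scene()`, `simulate_acquisition()`, `align_stack()`,
`correct_foreshortening()`, `segment_labels()`, `extract_surface()`,
`tip_contact_area()`, `classify_contact()`, `build_cell_report()`. The
methods vignette (`vignettes/methods.Rmd`) documents the model, the
numerical choices and their rationale.

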