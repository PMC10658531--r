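# eafadapt

Personalized 3D-printable ring adapters for isolating enteroatmospheric
fistulas (EAF) in open abdominal wounds treated with negative pressure wound
therapy (NPWT).

An enteroatmospheric fistula is an opening of the intestine onto the surface
of an open abdominal wound. Effluent leaking from the fistula contaminates
the wound bed and breaks the vacuum seal that NPWT depends on. A
patient-specific ring adapter — a hollow solid whose inner hole matches the
fistula outline and whose flanged outer wall interfaces with the NPWT sponge
and sealing film — isolates the fistula as a "floating stoma" so that
negative pressure therapy can continue around it.

`eafadapt` implements the full digital workflow for such devices:

1. **Scan QC** — ingest a structured-light scanner point cloud (XYZ or PLY)
   and apply the capture-quality gate: clouds under 400,000 points require a
   re-scan (a second scan is merged and re-checked).
2. **Surface reconstruction** — a 2.5-D height-field triangulation of the
   wound patch over its best-fit plane, with dropout-hole filling.
3. **Morphometry** — wound length/width/depth and per-fistula orifice height
   from a clinician-drawn wound rim and fistula lassos.
4. **Parametric design** — three offset sketches of the extracted fistula
   contour (bottom, middle, top brim, optionally eccentric), lofted into a
   solid; the straight extrusion of the fistula contour is subtracted to open
   the through-hole. The result is always a watertight ring (Euler
   characteristic 0) with the exact volume identity
   `volume(adapter) = volume(loft) − area(hole) × height`.
5. **Fit check & export** — penetration, hole-contains-fistula and
   rim-clearance checks in a resting pose, then binary or ASCII STL export
   for printing; remodeling appends new device versions as the wound evolves.

Because patient scans cannot be distributed, the package ships a **synthetic
wound phantom** (flat skin, cosine-tapered elliptical crater, plateau-topped
stoma bumps, Gaussian scanner noise along the surface normal) with exact
analytic ground truth for every downstream measurement, plus the **clinical
outcome tables** of the original case series (16 devices, 8 patients) as
checksummed fixtures, together with the statistics conventions needed to
reproduce every published aggregate from them exactly: weighted-average
`(n+1)p` quantiles, paired/pooled t tests, and the zero-drop tie-corrected
normal-approximation Wilcoxon signed-rank test (with exact-enumeration
oracles).

## Worked example

A complete scan-to-STL run on the patient-like phantom:

```r
library(eafadapt)

## 1. synthesize a scan (or read_point_cloud("scan.xyz"))
ph <- generate_phantom(phantom_preset("patient-like", n_points = 450000, seed = 1))
ph$cloud
#> point_cloud: 449579 points, first_scan (phantom(seed=1))

## 2. quality gate
qc_point_cloud(ph$cloud)
#> scan QC: 449579 points (threshold 400000) -> accept

## 3. reconstruct the wound surface
mesh <- reconstruct_surface(ph$cloud, grid_pitch = 1)
mesh_stats(mesh)
#> mesh: V=19200 F=37842 E=57041 boundary edges=556 chi=1

## 4. select the fistula and measure the wound
region <- select_fistula_region(mesh, truth_stoma_lasso(ph$truth))
meas <- measure_wound(mesh, truth_rim(ph$truth), list(region))
meas
#> wound: length 12.0 cm, width 8.0 cm, depth 2.0 cm
#> fistula orifice heights (cm): 1.5

## 5. design the adapter from the extracted fistula contour
frame   <- fit_design_frame(region)
contour <- extract_contour(region, frame)
adapter <- design_adapter(contour,
                          adapter_spec(height = 15, bottom_offset = 5,
                                       top_offset = 15))
adapter
#> adapter_solid: volume 14471.6 mm^3, hole area 446.6 mm^2, chi=0, watertight
ledge_report(adapter)
#> device: height 1.5 cm, width 5.3 cm, length 5.4 cm; top ledge 1.5 cm, bottom ledge 0.5 cm

## 6. fit-check and export
fit_check(adapter, mesh, frame, offset = c(0, 0, 2),
          fistula_contour = contour, rim = truth_rim(ph$truth))
#> fit: max penetration 0.00 mm, hole contains fistula: TRUE, rim clearance 12.7 mm
write_stl(adapter$mesh, "adapter.stl")          # binary STL, print-ready
```

The same pipeline in one call, with QC gating, automatic height/brim rules
and deterministic JSON reporting:

```r
bundle <- run_workflow(ph$cloud, truth_rim(ph$truth), truth_stoma_lasso(ph$truth),
                       workflow_config(), case_id = "demo")
render_report(bundle)
write_case_report(bundle, "case_report.json")
```

## Clinical outcome statistics

The packaged tables reproduce every published aggregate of the case series:

```r
describe(load_fixture_tables()$patients$cures_before_week)
#> n=8  mean 23.62 +/- 10.54  median 28.00 (14.00-33.25)  [mean_sd]
reproduce_paper_report()
#> outcome report: 53/53 published aggregates reproduced
#> known discrepancies in the published aggregates: ...
```

`reproduce_paper_report()` recomputes 53 descriptive statistics and
hypothesis-test p-values from the raw tables, compares each against its
published value at the published rounding (half-up), and lists the three
published aggregates that the raw tables do not support (a variance/sd slip,
an unstated exclusion, and aggregate device dimensions that are not column
means).

## Command-line interface

A thin CLI over the package functions is installed under `exec/`:

```sh
CLI=$(Rscript -e 'cat(system.file("exec/eafadapt", package="eafadapt"))')
Rscript "$CLI" phantom --out-dir case1 --preset patient-like --seed 1
Rscript "$CLI" qc      --cloud case1/cloud.xyz
Rscript "$CLI" run     --cloud case1/cloud.xyz --rim case1/rim.txt \
                       --lasso case1/lasso.txt --out-dir case1/out
Rscript "$CLI" report  --case case1/out/case_report.json
Rscript "$CLI" stats   --report outcomes.json
```

Subcommands: `qc`, `reconstruct`, `measure`, `design`, `fitcheck`,
`phantom`, `stats`, `run`, `report`. Workflow settings may be supplied as a
YAML file via `--config`.

## Scope and limitations

- Reconstruction is 2.5-D (height field over the best-fit plane): correct
  for open abdominal wound patches, not for undercut or closed anatomy.
  Real scanner meshes can bypass it entirely via `read_stl()`.
- The hole subtraction is an analytic ring assembly, valid because the hole
  is a straight extrusion strictly inside every cross-section — the package
  deliberately avoids general mesh Booleans.
- The phantom emulates scan geometry and sensor noise, not tissue deformation,
  specularity or registration error; clouds are assumed pre-registered.
- Statistics are limited to the conventions needed for the packaged case
  series (no survival modeling beyond the 3-month proportion, no
  multiplicity correction).
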