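# ivcsim — finite-element simulation of left-ventricular isovolumic contraction

`ivcsim` is an R package for studying how **transmural gradients in
electromechanical delay (EMD) and myocyte shortening velocity (MSV)** shape
the isovolumic contraction (IVC) of the left ventricle (LV). Across the
ventricular wall, subendocardial myocytes are depolarized first but shorten
late and slowly, while subepicardial myocytes are depolarized last but
respond fast and shorten about twice as quickly. The package implements an
idealized LV as a truncated-ellipsoid finite-element model, lets you switch
these gradients on and off, and quantifies the consequences for LV
contractility — the IVC duration and the maximum rate of pressure rise,
(dp/dt)max.

It is aimed at cardiac-mechanics researchers who want a transparent,
self-contained implementation of this electromechanical thought experiment:
every stage, from constitutive fitting to the isovolumic pressure
computation, is an exported, tested R function.

## The model in brief

* **Geometry** — the LV wall between two coaxial ellipsoids truncated at the
  equator (base), meshed with trilinear hexahedra in 7 transmural layers;
  muscle-fibre helix angle ramps +60° → −60° from endocardium to epicardium.
  The mesh is calibrated so the end-diastolic cavity volume is 122 ml.
* **Passive myocardium** — transversely isotropic hyperelasticity,
  `W = Σ aᵢ(Ī₁−3)ⁱ + b₁(Ī₄−1)² + b₂(Ī₄−1)⁴`, with published biaxial-fit
  constants × 6 for physiological strain rates and a volumetric penalty for
  near-incompressibility.
* **Active contraction** — fibres (80% of wall volume) generate
  `σ = E₀ e^ε (e^ε − 1)` (E₀ = 200 kPa, no compressive stress), driven by a
  prescribed linear shortening ramp starting at each element's mechanical
  onset = electrical activation time (endocardial depolarization spreading
  at 47 cm/s) + EMD (47 → 28 ms across the 9 mm wall, i.e. 2.1 ms/mm).
* **Isovolumic phase** — quasi-static total-Lagrangian Newton solver; the
  cavity volume is constrained exactly and the cavity pressure is the
  constraint's Lagrange multiplier. The zero-pressure reference geometry is
  recovered by backward-displacement iteration, and the subendocardial MSV
  is calibrated so the control IVC lasts 60 ms.
* **Scenarios** — `control`, `const_emd`, `const_msv`, `const_both`
  (gradients homogenised at the subendocardial value) and `intramural`
  (inner wall half activated simultaneously).

## Worked example

A desk-scale run (coarse 8 × 4 × 7 mesh, ~1 min; the default 16 × 8 × 7 mesh
gives almost identical numbers in a few minutes):

```r
library(ivcsim)

mesh  <- build_lv_mesh(n_circ = 8, n_long = 4)
mesh
#> LV mesh: 224 hexahedral elements (8 circ x 4 long x 7 layers), 265 nodes
#>   cavity volume 122.00 ml, wall volume 112.73 ml, wall thickness 9.43 mm (equator)
#>   helix angle +60 to -60 deg across layers

model <- prepare_lv_model(mesh = mesh)   # unloading + end-diastolic inflation
model
#> LV model bundle: EDV 122.0 ml at 1.30 kPa, unloaded volume 107.7 ml

suite <- run_experiment_suite(
  model, scenarios = c("control", "const_emd", "const_msv", "const_both"))
suite
#> scenario suite (msv_scale = 0.0020496 /ms):
#>     scenario ivc_ms dpdt_max_mmHg_s ivc_change_pct dpdt_change_pct
#> 1    control   60.1            1540            0.0            0.00
#> 2  const_emd   70.0            1520           16.4           -1.41
#> 3  const_msv   93.3             986           55.1          -35.99
#> 4 const_both  101.0             980           68.1          -36.39
```

Reading the table: with the physiological gradients (control), the
calibrated ventricle raises its cavity pressure from 1.3 to 10.7 kPa in
60 ms. Homogenising EMD alone desynchronizes the onset of contraction and
prolongs IVC by ~16% while barely touching (dp/dt)max; homogenising MSV
slows tension development in every layer, cutting (dp/dt)max by ~36% and
prolonging IVC by ~55%; homogenising both is worst (IVC +68%). The
transmural gradients thus act as a synchronizing mechanism that maximizes
contractile performance. Per-scenario pressure traces
(`suite$runs$control$trace`), per-layer fibre-stress histories
(`layer_stress_summary()`) and end-IVC transmural stress profiles
(`...$profile`) are included, and `plot(suite)` overlays the pressure
traces.

Other entry points: `compute_unloaded()` (zero-pressure geometry with a JSON
report), `calibrate_msv_scale()`, `build_schedule()` / `write_schedule_csv()`,
`write_mesh_vtk()` for visualization, and the synthetic biaxial stage
(`generate_biaxial_dataset()`, `fit_passive_params()`) that validates the
constitutive-parameter recovery used for the passive law.

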