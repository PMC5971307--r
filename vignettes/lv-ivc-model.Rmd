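---
title: "Modelling isovolumic contraction of the left ventricle with transmural electromechanical gradients"
author: "ivcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling isovolumic contraction of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physiological question

Ventricular myocytes differ across the wall: subendocardial cells start
shortening much later after their electrical depolarization (a long
electromechanical delay, EMD) but the depolarization reaches them first;
subepicardial cells are depolarized last but respond quickly and shorten
about twice as fast (myocyte shortening velocity, MSV). `ivcsim` implements a
finite-element model of the left ventricle (LV) built to ask what these
opposing transmural gradients do for the pump: it simulates the isovolumic
contraction phase (IVC) — both valves closed, cavity volume constant,
pressure rising from the end-diastolic 1.3 kPa to the diastolic aortic
10.7 kPa — and compares the control gradients against artificially
homogenised variants.

## Geometry and discretization

The LV is idealized as the wall between two coaxial ellipsoids truncated at
the equatorial plane (the base), meshed with trilinear hexahedra in 7
transmural layers; the apical element ring uses collapsed (wedge) hexahedra
so the cavity is watertight. Default dimensions are inner semi-axes
30/30/65 mm with a uniform 9 mm wall. Because the physiological anchor of
the geometry is the end-diastolic cavity volume (122 ml) rather than exact
semi-axes, and because a faceted surface inscribed in the ellipsoid encloses
less volume at coarse resolution, the builder rescales the mesh by one
similarity factor so the discrete cavity volume (divergence-theorem surface
integral over the endocardium plus basal cap) equals the target exactly;
`target_volume_ml = NULL` disables this for convergence studies, where the
discrete volume converges to the analytic truncated-ellipsoid value.

Each element carries a unit fibre direction tangent to its layer surface at
a helix angle ramping linearly from +60° (subendocardial layer) to −60°
(subepicardial layer) in 20° steps. Wall depth — the coordinate driving all
transmural gradients — is measured against the *discrete* endocardial
surface: in the structured mesh the element centroids of a transmural stack
and the stack's endo/epi face centres are collinear, so depth fractions are
exactly $(k-\tfrac12)/7$ for layer $k$. Default resolution is 16
circumferential × 8 longitudinal divisions (896 elements); the simulated IVC
duration changes by under 1% when the in-plane resolution is halved or
increased by 50%, so desk-scale runs use this size.

## Passive myocardium

Passive tissue is transversely isotropic and hyperelastic with the
polynomial strain energy

$$W = \sum_{i=1}^{3} a_i\,(\bar I_1-3)^i + b_1 (\bar I_4-1)^2 + b_2 (\bar I_4-1)^4,$$

where $\bar I_1$ is the isochoric first invariant of the right Cauchy–Green
tensor and $\bar I_4$ the isochoric squared fibre stretch. The default
constants (kPa) are $a_1 = 0.347$, $a_2 = 13.438$, $a_3 = 48.846$,
$b_1 = 0.436$, $b_2 = 27.692$, fitted to quasi-static biaxial data of
passive myocardium; because the beating heart deforms at much higher strain
rates, all stress-like coefficients are multiplied by a rate factor of 6
(`apply_rate_factor()`) before simulation. Incompressibility is imposed by
an isochoric–volumetric split with penalty $\tfrac{\kappa}{2}(J-1)^2$,
$\kappa = 10^3$ kPa, which keeps $|J-1| < 1\%$ at peak load while avoiding a
mixed formulation; the volumetric term is integrated at the element centre
(selective reduced integration) to prevent locking. Stiffening the penalty
five-fold changes the reported metrics negligibly (< 1%), confirming the
penalty is not a hidden compliance.

## Active contraction

Activated myocytes obey the uniaxial law
$\sigma = E_0\, e^{\varepsilon}(e^{\varepsilon}-1)$ with $E_0 = 200$ kPa,
zero stress in compression ($\varepsilon \le 0$) and initial slope $E_0$.
The fibres occupy 80% of the wall volume, so the total Cauchy stress is the
passive tissue stress (acting on the full volume, as the biaxial fits are
whole-tissue) plus $0.8\,\sigma_a$ along the deformed fibre direction.
Contraction is prescribed kinematically: from its mechanical onset each
element's fibre natural length shortens linearly at its scenario rate, and
the elastic strain entering the active law is the log fibre stretch measured
from the configuration at onset minus the (negative) prescribed strain. Two
choices deserve note:

* *Strain reference at onset.* Contractile elements are inactive during
  filling and come alive strain-free at their onset (their reference stretch
  is recorded then). The alternative — measuring the active strain from the
  unloaded configuration — would fire several kPa of fibre stress
  instantaneously at onset and produce a nonphysical pressure jump.
* *Symmetric active tangent.* The active second Piola–Kirchhoff stress is
  taken as $S_a = 0.8\,\sigma_a(\varepsilon_e)\, I_4^{-1}\, f_0 \otimes f_0$,
  the form generated by a fibre pseudo-potential. The exact push-forward of
  a prescribed Cauchy stress carries an extra factor $J$; with $|J-1|<1\%$
  the difference is below 1%, and the pseudo-potential form keeps the global
  tangent symmetric, which the supernodal Cholesky solver requires. (With
  the unsymmetric form the symmetrized Newton iteration stalls and then
  diverges late in IVC, when active stiffness dominates.)
* The shortening ramp is uncapped over the simulated window (a safety cap of
  0.25 strain exists); simulations end at IVC completion long before
  physiological shortening limits matter.

## Activation timing

Electrical activation starts simultaneously on the whole endocardial surface
and propagates transmurally at 47 cm/s; an element's activation time is its
wall depth over the conduction velocity. EMD interpolates linearly with
depth from 47 ms (endocardium) to 28 ms (epicardium) over the local wall
thickness — a 2.1 ms/mm gradient for the 9 mm wall — and the mechanical
onset is their sum. With the control values the conduction delay
(≈ 19.1 ms across the wall) is almost exactly cancelled by the EMD decrease,
so all onsets fall within 1 ms of each other. The contraction rate
(MSV) rises linearly with depth fraction to twice the subendocardial value
at the epicardium. The scenarios are:

| scenario     | EMD profile        | MSV profile        | electrical activation |
|--------------|--------------------|--------------------|----------------------|
| `control`    | 47→28 ms gradient  | 1→2× gradient      | endocardial, 47 cm/s |
| `const_emd`  | 47 ms everywhere   | gradient           | endocardial          |
| `const_msv`  | gradient           | subendo value      | endocardial          |
| `const_both` | 47 ms everywhere   | subendo value      | endocardial          |
| `intramural` | gradient           | gradient           | inner half at t = 0  |

`intramural` emulates species whose conduction fibres penetrate the wall:
elements with depth fraction ≤ 0.5 are activated simultaneously and
conduction only delays the outer half, so contraction starts epicardially
and desynchronizes mildly. EMD and MSV are evaluated at element centroids
(continuum interpolation) rather than as 7 discrete per-layer values; at
default resolution the two conventions differ by well under the layer
spacing.

## Quasi-static solver

The formulation is total-Lagrangian with Newton iteration; tangents are
assembled per element by forward finite differences of the exact residual
(step $10^{-6}$ mm), which is robust against the kinks of the active law.
The cavity pressure acts as a follower load on the deforming endocardial
faces; for the enclosed cavity this load is conservative and equals the
gradient of the cavity-volume functional, which is also used as the
isovolumic constraint: during IVC the solver enforces $V(u) = V_{ED}$
exactly, with the cavity pressure as the Lagrange multiplier of the bordered
Newton system, eliminated by a Schur complement. Volume is conserved to
relative $10^{-9}$ (tolerance), observed ≈ $10^{-11}$. Basal-plane nodes are
fully fixed (attachment to the valvular skeleton); a symmetry variant
(axial fixation only) exists for benchmarking, where a hemispherical mesh
reproduces the semi-analytic thick-walled-sphere inflation relation within
1%. Filling applies the end-diastolic pressure in 6 substeps; the 1 ms IVC
time step only controls schedule resolution (the problem has no inertia),
and steps that fail to converge are bisected automatically. Newton
tolerance is $10^{-8}$ relative to the applied pressure load.

## Unloaded geometry and calibration

The meshed geometry is the *loaded* end-diastolic state, so the stress-free
reference is recovered by backward-displacement iteration:
$X_{k+1} = X_k + \omega\,(X_{ED} - (X_k + u_k))$, where $u_k$ inflates
candidate $X_k$ to 1.3 kPa; convergence is declared when the re-inflated
candidate matches the end-diastolic nodes within 0.05 mm (3 iterations at
default settings, relaxation $\omega = 1$). The subendocardial contraction
rate is then calibrated by secant iteration on its logarithm so the control
IVC lasts 60 ms (tolerance 0.5 ms); duration decreases monotonically with
rate, and runs that never reach the aortic pressure are scored by the
simulation window so the search is pushed back toward faster rates. The
same calibrated rate is reused by every scenario.

## Derived metrics

IVC duration is measured on the 1 ms pressure trace from the onset of
pressure rise — detected at the first sample exceeding $p_{ED}+0.05$ kPa and
back-extrapolated to $p_{ED}$ along the local slope, so a flat latent period
is excluded exactly — to the linear-interpolated crossing of 10.7 kPa.
$(dp/dt)_{max}$ is the maximum of central differences over the IVC window,
reported in mmHg/s (1 kPa = 7.50062 mmHg). Per-layer stress histories are
volume-weighted means of the Cauchy stress resolved along the deformed
fibre direction, and the transmural profile samples them at the layer
centroid depths at the end of IVC.

## What the synthetic biaxial stage does and does not show

The constitutive-fitting module generates biaxial stress–stretch records
from the closed-form incompressible membrane response of the energy above
(equibiaxial plus off-biaxial strain-ratio paths, additive Gaussian stress
noise, fixed seed) and recovers the five coefficients by bounded
Levenberg–Marquardt least squares. Noiseless recovery is exact to optimizer
tolerance and datasets lacking fibre stretch are flagged non-identifiable.
Because the generator is the model itself, this validates the fitting
machinery, not the constitutive law against real tissue; at the default
1.1 maximal stretch the three isotropic coefficients are strongly
collinear (as they are for real biaxial data), so statistical checks of
estimator behaviour use a wider 1.2-stretch design.

## Known limitations

* The exact ellipsoid dimensions behind the published geometry are not
  recoverable; the defaults reproduce the 122 ml end-diastolic volume but
  absolute stress/pressure-rate levels inherit some uncertainty. The
  comparative (percent-change) results are insensitive to this: the
  simulated $(dp/dt)_{max}$ values run ≈ 11–13% below the reference values
  while IVC durations and all relative changes agree within a few percent,
  and the offset is unchanged under mesh refinement or a stiffer volumetric
  penalty.
* One LV only: no right ventricle, pericardium, or basal motion; the rigid
  basal fixation stiffens the base region.
* Transverse isotropy only (no sheet structure); rate dependence is the
  scalar ×6 factor, not true viscoelasticity.
* The ejection phase is out of scope; simulations end when the aortic
  pressure is reached.

## Reproducing the study numbers

```{r}
library(ivcsim)

model <- prepare_lv_model()          # mesh, unloading, end-diastolic state
suite <- run_experiment_suite(
  model, scenarios = c("control", "const_emd", "const_msv",
                       "const_both", "intramural"))
print(suite)
plot(suite)
```

At default resolution this takes a few minutes on one core;
`scripts/acceptance.R` in the source repository wraps exactly this pipeline
and writes the headline quantities as JSON.
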