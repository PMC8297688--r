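---
title: "Conduction-velocity-driven parametrization of atrial electrophysiology: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conduction-velocity-driven parametrization of atrial electrophysiology: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atrialcv)
```

## The modeling problem

Atrial fibrillation is promoted by the interplay of an ectopic trigger
(usually from the pulmonary veins), electrical remodeling (shortened action
potential and refractory period through reduced I_to, I_CaL and I_Kur), and
structural remodeling (fibrosis, seen functionally as slow conduction).
High-density electroanatomical maps taken in sinus rhythm measure local
activation times, from which a conduction-velocity (CV) vector field can be
reconstructed. `atrialcv` turns that CV field into a complete
parametrization of a tissue-scale electrophysiology model and simulates the
induction and sustainment of reentrant activity on it.

The tissue model is the monodomain reaction–diffusion equation coupled to
the Courtemanche–Ramirez–Nattel (CRN) human atrial ionic model (15 gating
variables, 5 intracellular concentrations):

$$\frac{\partial V}{\partial t} + I_{ion}(V, w, c) =
  \nabla \cdot (D \nabla V) + I_{app}(t), \qquad
  D = \sigma_l\, f_0 \otimes f_0 + \sigma_t\, s_0 \otimes s_0,$$

with homogeneous Neumann (no-flux) boundaries. The cell model runs in
physical CRN units (mV, ms, mM, pA/pF); the normalized potential
$u = (V + 84)/100$ is available for I/O
(`normalize_potential()`). Stimulus amplitudes quoted in $s^{-1}$ on the
normalized potential convert to mV/ms through the 100 mV span, so the
standard 200 s$^{-1}$ impulse drives 20 mV/ms.

## CV as the single driving datum

Everything heterogeneous in the model derives from the nodal CV magnitude:

* **Conductivity.** $\sigma_l = C_l\,CV^2$ along fibers; across fibers
  $\sigma_{t} = C_l\,CV^2$ below 0.4 m/s and the constant $C_{t,n}$ above
  it, which preserves the physiological anisotropy ratio in healthy tissue
  and makes severely slow tissue isotropic. Both shipped coefficient pairs
  (`conductivity_presets()`: baseline $C_l = 3.0\cdot10^{-4}$ s,
  progressed $C_l = 2.0\cdot10^{-4}$ s, each with $C_{t,n} = 0.16\,C_l$)
  keep this law continuous at the threshold. With $C_l$ in seconds and CV
  in m/s, $C_l\,CV^2$ has units m²/s — the tensor is a diffusivity with
  the surface-to-volume ratio and membrane capacitance absorbed; the
  solver converts to mm²/ms (1 m²/s = 10³ mm²/ms).
* **Ionic remodeling.** The fraction
  $I_{CV} \in [0,1]$ ramps linearly from `cv_lo` to 1.25 m/s
  (`remodeling_law()`: baseline 0.25 m/s, progressed 0.5 m/s) and scales
  the maximal conductances:
  $g_{to} = (0.5 + 0.5\,I_{CV})\,\bar g_{to}$,
  $g_{CaL} = (0.3 + 0.7\,I_{CV})\,\bar g_{CaL}$,
  $g_{Kur} = (0.5 + 0.5\,I_{CV})\,\bar g_{Kur}$.
  At $I_{CV}=0$ the cell is fully remodeled: APD90 drops from about 296 ms
  to about 222 ms at 1 Hz, shortening refractoriness in fibrotic tissue.

## CV estimation from activation maps

`estimate_cv_field()` follows the polynomial-surface-fitting family of CV
estimators: for each map point, neighbors within a 7.1 mm ball are
projected onto a local total-least-squares tangent plane; the points whose
tangent coordinates fall in the 1 cm × 1 cm square around the center form
the patch (at least 6 points); a degree-2 polynomial $T(x,y)$ is fit to
their activation times; the velocity is the inverse-gradient transform
$v = \nabla T / \|\nabla T\|^2$ at the center, lifted back to 3D. Speeds
outside [0, 2] m/s — the physiological 0–200 cm/s range — are invalidated,
never clamped, and `project_to_mesh()` later fills mesh nodes by
nearest-neighbor donation from valid points only.

Numerical notes: the design matrix is centered and scaled before the QR
solve and refused above condition number $10^8$; a gradient below
$10^{-6}$ ms/mm (wavefront collision plateaus) invalidates the point. On
noise-free planar fields the estimator is exact to solver precision. On
circular wavefronts the inverse-gradient rule carries a curvature bias
that decays like $1/r^2$: a few percent at 1 cm from the source with the
2.5 mm sampling used by high-density catheters — the round-trip tests
against the eikonal generator therefore assert a median error under 10%
rather than pointwise exactness.

## Discretization

Space: bilinear quadrilateral finite elements on structured sheets
(`gen_sheet_mesh()`); consistent mass matrix; element-constant diffusion
tensors (element CV = mean of its four nodes). Time: BDF of order 1–3 with
matching-order extrapolation, starting up through orders 1 and 2 while no
history exists. The coupling is segregated: at every node the ionic model
advances first, then the potential solves
$(\alpha/\Delta t\,M + A)\,u^{n+1} = \Delta t^{-1} M u_{BDF} - I_{ion} +
I_{app}$ with Jacobi-preconditioned conjugate gradients (relative
residual $10^{-8}$ — a solver contract, not an algorithmic requirement).
The ionic current vector uses state-variable interpolation (SVI): gates,
concentrations and the extrapolated potential are interpolated to the 2×2
Gauss points, where $I_{ion}$ is evaluated and tested against the basis
functions. SVI avoids the conduction-velocity inflation that nodal
ionic-current interpolation shows on coarse meshes.

One scheme detail deserves emphasis. Each CRN gate obeys
$\dot w = (w_\infty(V) - w)/\tau_w(V)$ with $\tau_m$ as small as 5 μs at
resting potential. Evaluating the gate right-hand side at *extrapolated*
gate values makes the update explicit and unconditionally unstable at any
practical Δt (0.05–0.1 ms); the update is therefore resolved implicitly in
the gate's own linear term — closed form, no iteration — while the voltage
and all cross-state dependencies stay extrapolated. Concentrations, whose
dynamics are slow, remain extrapolated-explicit. A Rush–Larsen
(exponential) gate update is available as a configuration switch
(`solver_config(rush_larsen = TRUE)`), default off. Gates are clamped to
[0,1] and concentrations floored at $10^{-10}$ mM after every update;
these guards should never engage in a stable run and are asserted in the
tests.

Voltage-only CRN rate functions are tabulated on a 0.05 mV grid over
[−120, 80] mV with linear interpolation (direct evaluation outside);
removable singularities in the rate expressions are evaluated by their
analytic limits inside a ±10⁻⁶ mV guard band. Runs are bitwise
deterministic for identical inputs; every result carries a content hash of
its full configuration.

## Stimulation protocols

`baseline_preset()` encodes the physiological activation sequence as three
spherical impulses (radius 6 mm; 7 mm in the paroxysmal variant) standing
in for the Bachmann's bundle, fossa ovalis and coronary-sinus inter-atrial
connections, repeating at 1.82 Hz with per-cycle delays of 0/10/20 ms — the
delays recur every cycle so each beat reproduces the physiological
pattern. `trigger_preset()` superimposes a cubic impulse of side 6 mm at
8.26 Hz (a clinically derived pulmonary-vein trigger rate), starting
together with the baseline. All impulses are 200 s⁻¹ for 5 ms. On
synthetic sheets the baseline landmarks sit along one edge (15 mm apart)
and the trigger in the opposite corner, preserving the geometric roles
without atrial anatomy. Cube "length" is interpreted as side length;
overlapping supports superpose.

## Analysis

* **Activation maps** use the discrete BDF-form derivative: AT is the
  argmax of $|\alpha u^{n+1} - u_{BDF}|/\Delta t$, tracked online during
  the run; nodes whose best slope is below 10% of the median upstroke are
  invalid. Map pairs on nested meshes are compared by the relative L1
  error after bilinear interpolation onto the reference nodes.
* **Dominant frequency** is the spectral peak of the detrended,
  Hann-windowed, zero-padded probe trace (resolution ≤ 0.25 Hz).
* **Phase singularities** use the delayed-signal phase
  $\varphi = \operatorname{atan2}(u(t-\tau) - \bar u,\; u(t) - \bar u)$
  with τ = 8 ms and the node's temporal mean as origin; a rotor tip is any
  element whose corner-wise phase winding is ±2π. Tips are linked across
  frames by nearest-neighbor association; a track is *anchored* if its
  bounding radius stays under 5 mm for over 1 s, *wandering* if sustained
  but mobile, *terminated* otherwise, and an aspect ratio above 3 flags a
  functional line of block. The thresholds are this package's own
  quantitative rendering of behaviors that are usually judged visually.
* **Vulnerable-window scans** classify each S1–S2 coupling interval as
  *early* (no propagated response), *reentry* (a phase singularity
  persisting beyond 250 ms — about two rotation periods — after S2) or
  *late* (one extra beat, then quiescence).

## The synthetic substrate generator

No patient data ship with the package, so `gen_cv_field()` emulates the
two mapped phenotypes: smoothed Gaussian random fields with persistent-like
(mean 0.60 m/s, three 6 mm slow patches reaching a 0.15 m/s floor) and
paroxysmal-like (mean 1.00 m/s, minimum clipped at 0.3 m/s, no severe slow
zones) presets, both with 0.25 m/s standard deviation and an 8 mm
correlation length, chosen so the paroxysmal mean exceeds the persistent
mean by 0.40 m/s with comparable spread — the printed contrast between the
two phenotypes. After patches and clipping the field is recentred onto the
preset mean (two passes). All outputs are pure functions of
(mesh, spec, seed). `eikonal_activation()` provides ground-truth
activation maps via Dijkstra on the mesh graph (diagonals included to
bound the metric overestimate at about 8%), subsampled at the 2.5 mm
interelectrode spacing of high-density catheters.

What the generator does *not* emulate: anatomical geometry and wall
thickness, fiber disarray inside fibrotic patches, mapping noise and
annotation error, and spatial correlation between slow conduction and
low voltage. Passing round-trip tests on these fields therefore validates
the estimator's numerics, not its robustness to clinical artifacts.

## Study problem sizes and what the desk-scale runs show

The package's own verification studies are scaled-down analogs of
full-atrium experiments, sized for a single CPU:

* Convergence ladder (`sinus_rhythm_convergence()`): 5×5 cm
  paroxysmal-like sheet, the (h, Δt) ladder (0.65, 0.1) → (0.17, 0.025)
  mm/ms, one sinus beat in a 200 ms window (the ~87k-node reference level
  dominates the runtime at a few minutes on one CPU). The once-refined
  level (0.33 mm, 0.05 ms) reproduces the reference activation map to an
  L1 relative error of about 0.025, with the 0.65 mm levels roughly 2.3x
  worse — the same convergence ordering, but an absolute level about 1.5x
  above the 0.016 reported for this discretization pair on the full
  atrium. The gap is structural to the desk-scale analog: on a
  uniform-fiber sheet paced from one edge most propagation is cross-fiber,
  where the ~0.25 mm transversal front is under-resolved at h = 0.33
  (inter-level speed error 3.7% across vs 1.3% along fibers), and the
  sheet's shorter activation times inflate the relative norm. Space, not
  time, dominates the residual, which still motivates (0.33 mm, 0.05 ms)
  as the production resolution.
* Trigger dominance (`trigger_dominance()`): uniform 0.7 m/s sheet,
  2.5 s. On this substrate the probe's dominant frequency is the 2:1
  subharmonic (~4.1 Hz) of the 8.26 Hz trigger, not the trigger frequency
  itself: with remodeling restricted to I_to/I_CaL/I_Kur (I_K1 and I_Na
  deliberately untouched), the tissue ERP (~200 ms even fully remodeled)
  exceeds the 121 ms trigger period, so 1:1 capture is impossible and the
  trigger sets the rhythm through its subharmonic. Full-atrium dominance
  of the trigger frequency plausibly rides on induced reentries that a
  uniform sheet deliberately excludes; the package reports the honestly
  measured value.
* Vulnerable window (`vulnerable_window_experiment()`): 3×3 cm fully
  remodeled slow sheet (0.3 m/s), cross-field S2, coupling intervals
  160–320 ms in 20 ms steps. Both coefficient presets show the
  early/reentry/late partition with a reentry window of 200–260 ms; the
  slow-conduction preset never narrows the window.

## Known limitations

2D sheets only (the architecture keeps assembly element-generic, but
hexahedral 3D slabs are not wired up); no bidomain, no mechanics or
hemodynamics; remodeling limited to the three currents above; rotor-track
thresholds (5 mm / 1 s / aspect 3) are package conventions, not
literature-calibrated constants; the eikonal oracle ignores wavefront
curvature and anisotropy, so it serves as ground truth only for the
estimator, never for the monodomain solver.
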