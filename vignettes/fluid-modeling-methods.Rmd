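---
title: "From DCE-MRI to interstitial fluid pressure: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DCE-MRI to interstitial fluid pressure: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dceflow)
```

`dceflow` estimates two physical properties of the tumor microenvironment —
interstitial fluid pressure (IFP) and interstitial fluid velocity (IFV) —
from dynamic contrast-enhanced (DCE) MRI. Solid tumors, and pancreatic
ductal adenocarcinoma in particular, combine leaky vessels with absent
lymphatic drainage and a dense stroma; the result is interstitial
hypertension that approaches microvascular pressure, impedes drug delivery,
and drives an outward fluid flux at the tumor rim. Neither IFP nor IFV is
routinely measurable in patients (the invasive wick-in-needle probe is the
reference method), so this package simulates both from quantities DCE-MRI
*can* measure, and provides the longitudinal statistics used to track them
across a course of therapy. Everything is exercised on synthetic phantoms
with known ground truth.

This vignette explains the models, the numerical choices, and what the
synthetic validation does and does not demonstrate.

## 1. Tracer kinetics

### Signal to concentration

The dynamic series is modeled as a spoiled gradient-recalled echo (SPGR)
steady state,

$$ S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha}, \qquad
   E_1 = e^{-\mathrm{TR}\,R_1}, \qquad R_1 = \frac{1}{T_{10}} + r_1 C, $$

with flip angle $\alpha$ (default 15°), TR = 5.6 ms, and relaxivity $r_1$
(default 4.5 L mmol⁻¹ s⁻¹, a gadobutrol-like value; configurable since
protocols differ). `concentration_from_signal()` inverts this per voxel
using the mean of the first three pre-bolus frames as $S_0$ and the supplied
$T_{10}$ map. The inversion is algebraically exact on noiseless input
(tested to 1e-9); signals that would imply a negative relaxation rate
(possible under noise) are clamped to the attainable range and the
voxel-frame is flagged rather than silently altered. Echo-time/T2* weighting
is treated as a constant factor that cancels in the $S/S_0$ ratio.

### Extended Tofts model

Tissue concentration follows

$$ C_t(t) = K^{\mathrm{trans}} \int_0^t e^{-k_{ep}(t-\tau)} C_p(\tau)\,
   d\tau + v_p C_p(t), \qquad k_{ep} = K^{\mathrm{trans}}/v_e , $$

where $C_p$ is the arterial input function (AIF), $K^{\mathrm{trans}}$
(min⁻¹) the plasma-to-interstitium transfer constant, $v_e$ the
extravascular-extracellular volume fraction, and $v_p$ the plasma fraction.

The convolution is evaluated by the exponential-kernel recursion, which is
*exact* when $C_p$ is piecewise linear between samples. Clinical DCE
sampling is coarse (about 12 s here, under 15 s in the emulated protocol),
where FFT- or quadrature-based convolution commits visible errors; the
recursion commits none on the interpolant, and a fine-grid trapezoidal
oracle in the test suite confirms agreement to better than 1e-4. The
$k_{ep}\Delta t \to 0$ limit is handled by series expansion.

`fit_etm()` runs bounded Levenberg–Marquardt least squares with
$K^{\mathrm{trans}} \in [0, 5]$ min⁻¹, $v_e \in [10^{-3}, 1]$,
$v_p \in [0, 0.5]$, started from a fixed three-point grid spanning slow to
fast kinetics. Ties between starts break by lowest residual, then lowest
$K^{\mathrm{trans}}$, so fits are bit-deterministic. Non-convergence
returns NA parameters and a flag, never a silent value. For whole-ROI maps,
`fit_etm_map()` fits the tumor-mean curve with the full grid first and
warm-starts each voxel from that solution — an order-of-magnitude speedup
that leaves noiseless recovery exact (tested to 1e-3 relative, and in
practice to machine precision).

### Transcapillary flux model and conductivity rescaling

The extravascular-extracellular (EES) concentration obeys

$$ v_e \frac{dC_e}{dt} = \frac{PS}{V}(C_p - C_e) +
   \frac{J_v}{V}(1 - \sigma_T)\,C_p , $$

diffusive exchange plus convective delivery. The convective term carries the
plasma concentration: the printed form of this model omits a concentration
factor, and the package follows the primary references in attaching $C_p$.
$C_e$ itself comes from the compartmental identity
$C_e = (C_t - v_p C_p)/v_e$ (`derive_ce()`).

**Identifiability.** From a single $C_e(t)$ curve this model exposes only
two parameter combinations — the rate $(PS/V)/v_e$ and the amplitude
$(PS/V + (J_v/V)(1-\sigma_T))/v_e$ — so the triple $(v_e, PS/V, J_v/V)$
cannot be jointly estimated: any rescaling of all three leaves the curve
unchanged. `fit_flux_model()` therefore requires $v_e$ from the Tofts fit
and estimates $(PS/V, J_v/V)$; a joint-refit mode is deliberately not
offered. $\sigma_T$ is a tissue constant (tumor 0.82), not fitted. With
$v_e$ fixed the recovery is exact on noiseless input (tested against a
`deSolve` integration of the governing ODE).

The fitted filtration-rate map rescales the capillary hydraulic
conductivity,

$$ L_p \frac{S}{V} = L_{p,0}\,\frac{S}{V}\,
   \frac{J_v/V}{\langle J_v/V\rangle}, $$

so that vessel-wall conductance varies spatially with measured filtration
while its tumor mean stays pinned to the literature value
$L_{p,0} S/V$ (`rescale_lp()`, default $2.1\times10^{-11} \times 2\times
10^4$ Pa⁻¹ s⁻¹).

## 2. The fluid model

### Governing equation

Interstitial flow in tissue is Darcy flow, $u = -K_H \nabla p_i$, with
$K_H$ the tissue hydraulic conductivity (porous-medium permeability over
interstitial fluid viscosity). Mass conservation with a Starling source and
a lymphatic sink gives the stationary elliptic equation solved by
`solve_ifp()`:

$$ -K_H \nabla^2 p_i =
   \frac{K^{\mathrm{trans}}}{\langle K^{\mathrm{trans}}\rangle}
   \left[ L_p \frac{S}{V}\bigl(p_V - p_i - \sigma_T(\pi_V - \pi_i)\bigr)
   \right] - L_{pL}\frac{S_L}{V}(p_i - p_L). $$

The normalized $K^{\mathrm{trans}}$ field modulates vessel-wall conductance
voxel-by-voxel, conveying relative vascular leakiness; it enters as a
dimensionless ratio, so the min⁻¹ storage unit never touches the physics.
The lymphatic sink is active only in normal tissue (tumor lymphatics are
dysfunctional). Defaults in `tissue_constants()` (tumor / normal):
$L_{p,0} = 2\times10^{-11} / 3\times10^{-12}$ m Pa⁻¹ s⁻¹,
$S/V = 2\times10^4 / 7\times10^3$ m⁻¹,
$L_{pL}S_L/V = 0 / 10^{-7}$ Pa⁻¹ s⁻¹,
$K_H = 1.9\times10^{-12} / 3.8\times10^{-13}$ m² Pa⁻¹ s⁻¹,
$p_V = 2300$ Pa, $p_L = 0$ Pa, $\pi_V = 2670$ Pa,
$\pi_i = 3230 / 1330$ Pa, $\sigma_T = 0.82 / 0.91$.

Two algebraic consequences anchor the validation. Where diffusion and sink
vanish, pressure relaxes to the local Starling equilibrium
$p_V - \sigma_T(\pi_V - \pi_i)$ = **2759.2 Pa** in tumor; with the sink, the
normal-tissue balance point is the conductance-weighted mixture
$(g_v p_{eq} + g_L p_L)/(g_v + g_L) \approx$ **187.5 Pa**
(`starling_equilibrium()`). Every computed pressure must lie between these
two, and the solution approaches the tumor equilibrium in the core of any
tumor whose size exceeds the screening length — for the defaults,
$\alpha = R\sqrt{L_p (S/V) / K_H} \approx 4.6$ at $R = 10$ mm, enough for a
visible plateau; the package's plateau property test uses an elevated
conductivity giving $\alpha > 10$, where the core sits within 1% of
equilibrium.

### Domain construction

`build_domain()` reslices the tumor ROI and $K^{\mathrm{trans}}$ map to
1 mm isotropic voxels (nearest-neighbor for labels, mask-weighted trilinear
for the map, which is undefined outside the tumor), then dilates the tumor
by a 10-voxel Euclidean ball to attach a normal-tissue shell. Dilation
happens *after* reslicing so "10 voxels" always means 10 mm; the margin is
spherical rather than cubic so it is isotropic. The grid pads itself if the
shell would touch an edge. Labels partition the grid exactly into
outside / normal / tumor; $\langle K^{\mathrm{trans}}\rangle$ is the
arithmetic tumor mean. The ROI can also be exported as a watertight STL
surface (marching tetrahedra at iso-level 0.5) for interchange; the mesh is
provenance, not the solver geometry.

### Discretization and solve

The equation is discretized with 7-point finite differences on the voxel
lattice — the domain is voxel-native, the operator is isotropic, and a
finite-difference solve is directly checkable against one-dimensional
references. Faces between unlike tissues use the harmonic mean of $K_H$
(the flux-continuous choice); faces to unlabeled voxels carry no flux,
which places the homogeneous Neumann boundary on the dilation surface.
The resulting system is symmetric positive definite (the Starling reaction
term guarantees it whenever any source or sink is active; if all vanish the
pure-Neumann problem is singular and the solver refuses with a diagnosis).
It is solved by Jacobi-preconditioned conjugate gradients from a zero start
with fixed ordering — bit-deterministic — to a relative residual of 1e-10.
A 64³ domain solves in about two seconds.

Summing the discrete equations over the no-flux domain cancels every flux
term, so net source must balance net sink:
$|\sum(\varphi_v - \varphi_L)| / \sum|\varphi_v| < 10^{-6}$ holds at
convergence and is recorded in the solver diagnostics. (At exact Starling
equilibrium the gross source itself vanishes and the ratio is 0/0; the
diagnostics report 0 and the tests assert $\varphi_v \approx 0$ directly.)

Velocity maps use central differences in the interior and one-sided
differences at the domain surface (`compute_ifv()`); $u = -K_H \nabla p_i$
exactly reproduces hand-computed linear-ramp fields.

### Validation against the 1D spherical reference

For a spherical tumor the problem reduces to a two-region radial ODE.
`solve_ifp_radial()` solves it on a fine 1D finite-volume grid (4000 cells)
— an independent code path sharing no assembly with the 3D solver. For an
$R = 10$ mm tumor on a 64³ 1 mm grid the 1-mm-binned radial profile of the
3D solution matches the reference with 0.4% relative L2 error (1.9%
voxelwise; the difference is rasterization staircase at the interface,
where pressure falls by an order of magnitude over ~2 mm). Halving the
voxel size moves the tumor-mean pressure by under 1%. The solution shows
the expected structure: a near-uniform core, a drop of more than half the
core-to-far-field contrast within 5 mm of the boundary, and peak velocity
in the rim shell.

## 3. The synthetic cohort

Real DCE exams for this pipeline are not publicly available, so the package
generates its own. `phantom_spec()`/`generate_phantom()` forward-compose
the Tofts model with the SPGR equation on an ellipsoidal tumor (simplified
geometry is standard practice for this simulation family): a ramp +
bi-exponential AIF (onset 30 s, peak 6 mM, fast/slow washout 0.03/0.0015
s⁻¹ — first-pass and clearance scales typical of population AIF models),
TR/TE = 5.6/2.3 ms, flip angle 15°, 20 frames at 12 s, $T_{10}$ = 0.8 s,
tumor $v_e = 0.3$, $v_p = 0.04$, and lognormal $K^{\mathrm{trans}}$
heterogeneity with CV 0.2. Noise is additive Gaussian on magnitude signal,
default SD 5% of baseline (SNR 20); a Rician option is out of scope.
Identical spec + seed is bit-identical.

`cohort_spec()`/`generate_cohort()` build longitudinal triplets: subject
baselines $K^{\mathrm{trans}} \sim N(0.14, 0.06)$ min⁻¹ truncated at 0.02,
multiplied at the three time points by effects defaulting to the ratios of
the published cohort means, (1, 1.93, 1.36) — an *emulation* of the
reported shift, not ground truth. Volumes are log-uniform over the reported
1.08–68.53 cm³ pre-treatment range (volume distributions in small cohorts
are right-skewed). With nine or more subjects the default missingness
reproduces the study's exam pattern (n = 8, 8, 9).

What the phantoms do **not** emulate: breath-hold gaps and motion, B1
inhomogeneity, Rician noise at low SNR, irregular tumor shapes, partial
volume at the ROI boundary, and any real coupling between
$K^{\mathrm{trans}}$ change and fluid-property change. Passing tests
therefore demonstrate that the *chain of computations* is correct and
self-consistent under known ground truth — not that the physiological
parameter values are accurate in patients.

One algebraic property of the fluid model matters when interpreting the
synthetic longitudinal results: $K^{\mathrm{trans}}$ enters the continuity
equation only through the *normalized* field
$K^{\mathrm{trans}}/\langle K^{\mathrm{trans}}\rangle$, so a uniform
multiplicative shift of a tumor's $K^{\mathrm{trans}}$ — exactly what the
cohort effects impose — leaves the source term, and hence mean IFP and
IFV, almost unchanged (only the resampled heterogeneity pattern moves
them). The synthetic cohort consequently shows near-constant IFP across
time points, echoing the small longitudinal IFP changes this class of
model reports clinically, while large longitudinal IFV contrast would
require geometry or volume changes between exams — which the generator
deliberately holds fixed within subject, volume being a subject-level
draw.

## 4. Statistics

Time points are compared with the two-sided Mann–Whitney rank-sum test
(`wilcoxon_compare()`), exact for group sizes ≤ 10 without ties and normal
approximation otherwise; the unequal group sizes caused by missed exams
make a paired test impossible. `spearman_corr()` reports the rank
correlation of tumor volume against IFP and IFV with mid-ranks for ties and
the strength bands weak (|ρ| ≤ 0.3), moderate (0.3, 0.7], strong (0.7, 1] —
the published banding leaves gaps at the boundaries, which are assigned to
the closure of the lower band. `percent_change()` is plain relative change
in percent. No multiple-testing correction is applied (none is described
for the original analysis); the report footer flags this.

## 5. Problem sizes and determinism

The test suite and the acceptance script run on one CPU in a few minutes
total: phantoms of 10–40 voxels per side, a 64³ solver benchmark, 50-replicate
noise studies, and a 10,000-replicate rank-sum calibration at n = 8 per
group — sizes chosen so each check has clear statistical resolution while
the whole suite stays quick. The analysis drivers under `analysis/` run the
full nine-subject cohort at study-scale volumes (minutes, not hours; the
voxelwise fits dominate). Every stochastic step takes an explicit integer
seed; fits and solves are deterministic given their inputs.

## 6. Known limitations

- The solid-stress mechanics of the stroma, transient pressure evolution,
  and vessel-compression feedback are not modeled (stationary fluid only).
- $K_H$ is a literature constant per tissue class; treatment effects on the
  extracellular matrix are not reflected in it.
- The Tofts-model stage assumes fast water exchange; shutter-speed effects
  are out of scope.
- The Starling source linearizes vessel behavior; IFP exceeding $p_V$
  (reported transiently in some tumors) cannot arise in this model — by
  construction pressure is bounded by the tumor Starling equilibrium.
- Mesh export is for interchange/provenance; the solver runs on voxels.
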