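---
title: "An electromechanical model for CRT pacing optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An electromechanical model for CRT pacing optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtsim)
```

`crtsim` simulates the electromechanics of a failing biventricular heart with
complete left bundle branch block (LBBB) and sweeps biventricular pacing
configurations — LV lead site × interventricular delay (VVD) — to find the
optimum under a mechanical (CURE) or electrical (E_RMS) criterion. This
vignette is the package's own account of the model: what is computed, which
assumptions and parameter choices went into it, and what the desk-scale
idealization can and cannot show.

## The synthetic anatomy

Real studies of this kind use subject-specific anatomy and measured fiber
fields. `crtsim` replaces these with an idealized, fully parameterized
geometry so that every result is reproducible from code alone:

* The LV is a thick-walled truncated ellipsoid (default cavity semi-axes
  18 × 18 × 45 mm, wall 8 mm), truncated at the base plane at 40% of the long
  semi-axis. The wall is divided into `n_layers = 14` equal-height
  longitudinal bands numbered 1 (apex) to 14 (base); this spacing choice is
  the package's own, made once, since equal-height and equal-arc-length
  conventions differ negligibly away from the apex.
* A closed ellipsoidal apex would require collapsed hexahedra with
  non-positive Jacobians, so the mesh also truncates a small polar cap
  (default 1% of the long semi-axis, a hole of ~2.5 mm radius). The cavity
  volume closes the endocardial surface with both the basal and the tiny
  apical cap; the analytic reference volume (`analytic_cavity_volume()`) is
  the ellipsoid slab between the two planes, so mesh refinement converges to
  it exactly.
* The RV free wall is a thin shell (4 mm) bulging radially from the LV
  epicardium over a 120° septal sector, sharing its rim nodes with the LV so
  the crescent-shaped RV cavity is closed. The septum is therefore LV wall
  between the two cavities, as in the real heart.
* Fibers follow a rule-based transmural helix: the helix angle interpolates
  linearly in transmural depth from +60° (endocardium) to −60° (epicardium),
  each fiber lying in its element's circumferential–longitudinal plane. This
  preserves the circumferential-dominant anisotropy that both conduction and
  the circumferential-strain analysis depend on.
* Wall segments (anterior, lateral, posterior, septum) are quadrants of the
  short-axis angle, septum centred on the RV attachment and the lateral wall
  diametrically opposite — the standard short-axis segmentation.
* Seven pacing sites are resolved by (segment, level) rather than by
  coordinates: RVA at the RV endocardial apex, and {POST, LAT, ANT} × {B, E}
  on the LV epicardium, equatorial sites adjacent to layers 6–9 and basal
  sites to the top two layers.

Papillary muscles, atria, and coronary-vein constraints on lead placement are
out of scope.

## Excitation: monodomain with two-variable kinetics

Propagation solves the monodomain equation with a conductivity tensor
aligned to the fiber field,

$$D = \left[\tfrac{1}{\beta}\tfrac{k}{k+1}\right]
      \left(D_t I + (D_l - D_t)\, f f^\top\right),$$

discretized with trilinear finite elements (lumped mass, natural no-flux
boundary) and advanced by operator splitting: an explicit reaction substep
followed by an implicit backward-Euler diffusion substep with a pre-factored
sparse Cholesky solve (`dt` = 0.1 ms).

The ionic kinetics are a two-variable phenomenological excitable model
(normalized potential with a cubic upstroke, one recovery variable, time
scaled by `tau_ms`). The pipeline consumes only two properties of the
membrane model — activation times and refractoriness — and the stand-in
preserves both: the upstroke threshold crossing is sharp, and the recovery
variable keeps tissue inexcitable for well over 150 ms, which is what makes
an RV stimulus fired late into already-activated tissue fail to capture (the
mechanism that saturates the indices for extreme VVDs). The kinetics sit
behind `reaction_step()` so a detailed ionic model could be swapped in.

Calibration was done once, on planar-wave slabs, and is config-overridable:

* `d_long = 5`, `d_trans = 1.25` mm²/ms (effective 2.5/0.625 after the
  monodomain scaling with β = k = 1) give a fiber-direction conduction
  velocity of ≈0.6 m/s, grid-convergent to within 5% between h = 1.5 mm and
  h = 0.375 mm, and a 2:1 velocity anisotropy.
* The endocardial fast shell (one element thick on both ventricular
  endocardia, standing in for the Purkinje network) multiplies the diffusion
  tensor by 6; conduction velocity scales roughly with the square root of
  that multiplier, i.e. ≈2.4× faster than working myocardium.
* With these defaults the LBBB protocol (right bundle entry stimulated at
  t = 0, left bundle silent, fast shell otherwise intact) activates the whole
  coarse heart with the latest depolarization near 100 ms, the septum well
  before the lateral wall, and the latest-activated element in the LV free
  wall — the qualitative LBBB signature.
* Stimuli are the protocol default 100 µA/cm² for 0.5 ms, applied over a
  10 mm capture footprint (`capture_nodes()`). A point stimulus cannot ignite
  a wave whose natural front width exceeds the mesh spacing; the footprint
  plays the role of the virtual-electrode region at desk-scale resolution.
* Activation time is the first linearly interpolated crossing of the 0.5
  upstroke level; nodes that never cross carry an NA sentinel and are
  rejected by the electrical index.

## Contraction: quasi-static FEM with activation-triggered twitches

The mechanics solve is linear in the displacements, [K]{δ} = {F_f}, with
8-node isoparametric hexahedra and 2×2×2 Gauss quadrature; the
Green–Lagrange strain E = ½(FᵀF − I) is computed as a finite-strain
post-process from the trilinear deformation gradient. This mixed
small-displacement-solve / finite-strain-measure formulation keeps every
frame a single sparse Cholesky back-substitution, so a 41-frame contraction
costs little more than one factorization.

* **Material**: transversely isotropic with the fiber as the symmetry axis
  (fiber modulus 60 kPa, cross-fiber 20 kPa, in-plane Poisson ratio 0.45,
  fiber-transverse 0.3, fiber shear 10 kPa). The 6×6 elasticity matrix is
  built from the compliance form, checked positive definite, and rotated
  into each element's fiber frame with the Voigt (Bond) rotation; the
  rotation is cross-checked in the tests against brute-force rotation of the
  full 4th-order tensor. The fiber is the third material axis, so a uniaxial
  active stress is the Voigt vector {0, 0, σ, 0, 0, 0}.
* **Active stress**: each element's twitch starts at its activation time
  (mean of its nodes' activation times), rises as sin²(πs/2t_rise) to the
  peak `t_max` at t_rise = 60 ms, decays exponentially (t_decay = 80 ms)
  under a smooth taper, and is exactly zero after 400 ms. The equivalent
  nodal force −∫Bᵀσ|J| is self-equilibrated per element. `t_max = 10 kPa`
  was chosen once so the LBBB baseline ejection fraction lands in the
  20–30% range of a failing ventricle; because the solve is linear, `t_max`
  scales displacements nearly proportionally and cancels out of the
  scale-free CURE. Sarcomere-length dependence of active tension is a
  documented simplification (length-independent twitch).
* **Basal restraint**: stiff springs (default 50 kPa·mm) on every basal-ring
  node dof rather than hard fixation, making the constrained system positive
  definite while letting the base move physiologically.
* **Reference state**: the undeformed mesh is end-diastole. There is no
  diastolic filling step and no cavity-pressure afterload; LVEF is purely
  kinematic (active-contraction volume change), so its absolute value should
  be read as a calibrated index, not a hemodynamic prediction.
* **Frames**: mechanics is evaluated every 10 ms over 0–400 ms.

## The four indices

* **CURE**: ε_cc is sampled at 30 equiangular mid-wall points on each of the
  four equatorial rings (layers 6–9; LV + septum only). Per ring and frame,
  the zero-order power is the squared ring mean and the first-order power the
  squared amplitude of the first circumferential harmonic (2/N convention).
  Powers are summed over slices and frames — uniformly weighted, over the
  systolic window from the earliest activation to the minimum-volume frame —
  and CURE = √(A₀²/(A₀² + 2A₁²)). The fixture generator
  `make_ring_series(c, a)` makes the closed form √(c²/(c² + 2a²)) testable to
  1e-10, including the boundary cases CURE = 1 (uniform) and 0 (pure first
  harmonic).
* **E_RMS**: root-mean-square difference of nodal activation times against
  the sinus reference over all mesh nodes.
* **DI**: segment-mean maximum principal strain E1 traces at layer 7; DI is
  the latest minus the earliest time-to-peak, ties broken by the earliest
  frame.
* **LVEF**: divergence-theorem volume of the deformed, capped LV endocardial
  surface; EDV is the reference volume, ESV the minimum over frames.

## The sweep

`run_sweep()` evaluates the sinus reference, the LBBB baseline, and every
(site, VVD) configuration of the grid — the default grid is the 6 LV sites ×
13 delays (−72…+72 ms step 12), 78 configurations. Paced protocols keep the
intrinsic right-bundle activation firing at t = 0, since the saturation of
the indices at large VVD requires intrinsic/LV wavefronts to pre-empt the RV
lead. The optimum is the argmax of CURE (mechanical strategy) or argmin of
E_RMS (electrical strategy); score ties are broken by smaller |VVD| (simpler
device programming), then catalogue order. Failed configurations are
recorded with their failing stage and excluded from selection. The two
strategies may disagree — surfacing that disagreement is the point of the
report, which carries both optima plus the baselines
(`tidy()`/`glance()`/`autoplot()`).

## Problem sizes and numerical choices

The package's standard study conditions, used throughout the tests, are a
coarse heart of 24 circumferential × 14 longitudinal × 2 transmural LV
elements plus the RV shell (752 hexahedra, 1249 nodes): large enough to show
all the physiological orderings, small enough that a full
electromechanical configuration evaluates in seconds. The default
`mesh_spec()` is finer (32 × 14 × 4, ≈2000 hexahedra) for standalone use.
Oracle checks run on micro-fixtures: unit-cube and distorted single
hexahedra, ≤50-node slabs for the dense monodomain reference, and analytic
ring series for the index layer. Degenerate inputs are rejected loudly:
non-positive Jacobians name the offending element, identically-zero strain
series make CURE report "undefined" rather than 0 or 1, flat strain traces
reject the DI, and unactivated nodes reject the E_RMS.

## What passing tests do and do not show

The synthetic generator emulates the *structure* the analysis assumes —
two cavities, circumferential-dominant fibers, a fast endocardial pathway,
mean-plus-first-harmonic circumferential strain, septum-early/lateral-late
LBBB activation — not any individual heart. On these conditions the package
reproduces the formula-level values exactly (CURE boundary cases and closed
form, E_RMS/DI/LVEF arithmetic, 78-configuration cardinality) and the
qualitative physiology (LBBB worse than sinus, pacing recovery of CURE and
LVEF, LV-first ≥ RV-first, VVD saturation). The headline numbers of a
subject-specific study (which configuration is optimal, and its exact CURE)
depend on the anatomy, the measured fiber field and the full ionic model,
none of which a desk-scale idealization can supply; they are treated as
qualitative pattern targets only.

Two desk-scale artifacts deserve explicit mention. First, the synthetic
sinus reference is driven from two septal-base bundle entries through a
moderately fast shell, so it is less uniform than a real Purkinje-driven
beat; the LBBB map consequently sits unrealistically close to the reference
and the absolute E_RMS values are compressed. Rankings between paced
configurations are still meaningful, but E_RMS magnitudes are not
comparable to voxel-anatomy studies. Second, without cavity pressure the
volume curve is purely activation-shaped, so ESV timing (and hence the
systolic window) is earlier than in a pressure-loaded ventricle.

## Limitations

No bidomain electrics, body-surface ECG, or defibrillation physics; no full
ionic calcium subsystem; no cavity pressure, circulation coupling, or
dP/dt; no large-deformation Newton iteration; no AV-delay optimization (held
fixed); no gradient-based search (the sweep is exhaustive, as the study
design requires). The linear-kinematics solve under-resolves wall thickening
at large twitch amplitudes, which is why the default calibration keeps peak
strains moderate.
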