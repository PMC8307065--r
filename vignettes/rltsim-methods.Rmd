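---
title: "rltsim: models, parameters, and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rltsim: models, parameters, and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rltsim` simulates PSMA-directed radioligand therapy at the scale of the
tumor microenvironment: a 1.6 × 1.6 mm² tissue region interspersed with
vessel lumina, through which oxygen and the radiolabeled ligand enter.
This vignette is the package's own account of the science: the models
and their assumptions, every tunable parameter with units and default,
the numerical methods and their tolerances, the design choices that were
genuinely open, and the known limitations.

## 1. The computational domain

A `vessel_map` is a binary raster on a physical grid: `TRUE` pixels are
vessel lumina, everything else is tissue. Vessels are not simulated
tissue — they are holes in the mesh that act as flux sources through
Robin (permeability) conditions on the tissue faces adjacent to them.
Outer domain edges are no-flux. The default grid is 400 × 400 pixels at
4 µm/pixel; `voxel_depth_um` defaults to the pixel size (cubic voxels)
for all volume, activity, and dose conversions. Pixel centers sit at
(i + 0.5)·h in 0-based row-major convention.

Masks come from two sources:

* **Histology.** `binarize_histology()` applies Huang's fuzzy-entropy
  threshold (the candidate split minimizing the summed Shannon fuzzy
  entropy of the two-class memberships `u = 1/(1 + |g − µ_class|/C)`),
  then `clean_mask()` removes connected components below
  `min_object_px` and fills enclosed holes so lumina are solid. A
  constant image has no threshold and is an error. The exact cleaning
  used for any particular published dataset is rarely specified; this
  size-filter-plus-fill is a reasonable, idempotent stand-in, not a
  reproduction of any one pipeline.
* **Synthesis.** `generate_synthetic_map()` places disc vessels with
  lognormal radii (default meanlog = log(8 µm), sdlog = 0.4 — capillary
  scale) until a target vascular fraction is met within 10% relative,
  radius-capping the final discs so the target is not overshot.
  Placement follows a Thomas cluster process: parents uniform, vessels
  scattered around a parent with an isotropic Gaussian
  (`cluster_sigma_um`, default 50 µm), on average `1 + 15·clustering`
  vessels per cluster. `clustering = 0` recovers uniform (Poisson)
  placement. The same seed and spec reproduce the map bitwise.

**Why clustering defaults to 0.4.** The generator's purpose is to
emulate xenograft ROIs whose vasculature is strongly clumped, leaving
large avascular regions — the geometric driver of diffusion-limited
chronic hypoxia. Uniformly placed capillaries at a 1–3% vascular
fraction leave almost no tissue beyond the ~100 µm oxygen diffusion
range and produce an implausibly well-oxygenated map. The default was
fixed once, by scanning the clustering intensity and keeping the value
whose steady-state oxygenation statistics (class fractions at the 1.0%
and 3.2% vascular-fraction endpoints, and the upper range of per-ROI
median pO₂) best match values reported for real prostate-tumor ROIs.
It was not adjusted afterwards. What a passing oxygenation test shows
is therefore that the solver plus this calibrated geometry reproduce
ROI-level hypoxia statistics; it does not show that any individual
synthetic map is a faithful stand-in for a particular histology slide —
in particular, the most avascular synthetic ROIs are more deeply anoxic
(median pO₂ well below 0.5 mmHg) than the least oxygenated real ROI we
emulate, because real slides retain isolated vessels that the clustered
process concentrates elsewhere.

## 2. Tissue oxygenation

Oxygen tension `P` (mmHg) obeys

∂ₜP = ∇·(D_O₂ ∇P) − M₀ · P / (P + P₀)

with wall flux J_O₂ = L_O₂ (P_ie − P). Parameters
(`oxygen_params()`):

| parameter | meaning | default | units |
|---|---|---|---|
| `L_O2` | vessel-wall O₂ permeability | 4.1e-2 | cm s⁻¹ |
| `D_O2` | O₂ diffusivity | 2.0e-5 | cm² s⁻¹ |
| `P_ie` | intraerythrocyte pO₂ | 40 | mmHg |
| `M0` | max consumption rate | 15 | mmHg s⁻¹ |
| `P0` | Michaelis–Menten coefficient | 2.0 | mmHg |

These are standard literature values for tumor tissue; `M0 = 0` is
allowed as the analytic zero-consumption limit (the field then relaxes
to `P_ie` exactly).

**Solver.** The quasi-steady solution is found by damped Picard
iteration on the nonlinear steady problem: the Michaelis–Menten rate is
frozen at the current iterate, giving a symmetric positive-definite
5-point system (Laplacian + Robin diagonal + frozen consumption
diagonal) solved by sparse Cholesky; the symbolic factorization is
computed once and only the numeric factor is refreshed. Because the
system matrix is an M-matrix with a non-negative right-hand side, every
iterate satisfies 0 ≤ P ≤ P_ie (discrete maximum principle).

**Stationarity criterion.** The published convention this follows —
"temporal variations below 0.1% per second" — does not state its
normalization. We evaluate the PDE right-hand side at the current
iterate (which *is* ∂ₜP) and declare convergence when
max |∂ₜP| / max(P, P₀) ≤ `criterion` (default 1e-3 s⁻¹) over tissue
pixels. The `P₀` floor prevents division blow-up in anoxic pixels.
Non-convergence within 200 iterations is an error carrying the last
residual. Damping halves the step when the residual rises (down to
θ = 1/8).

**Wall-flux discretization.** The Robin coefficient uses the wall
permeability in series with the half-cell diffusion resistance,
`L_eff = 1/(1/L + h/2D)`, a finite-volume correction without which the
wall flux converges only first-order in `h` (the refinement test —
median pO₂ changing < 5% when the pixel size halves on a fixed
layout — fails without it at these permeabilities).

**Segmentation.** Classes follow the McKeown bands with half-open
intervals `[lower, upper)`: a pixel at exactly 3 mmHg is pathological,
at exactly 15 mmHg physoxic. Tensions above 40 mmHg (possible in the
first cell ring around a vessel) are folded into physoxia, since no
class is defined above 40. Vessel pixels are labelled `vessel` and
excluded from class fractions, which therefore sum to 1 over tissue.
Medians use R's even-count midpoint convention.

## 3. Arterial input function and calibration

`aif_model()` is a sum of decaying exponentials
C_v(t) = scale · Σ aᵢ exp(−kᵢ t), by default biexponential: 90% of the
peak clearing with a 10-minute half-life (distribution) and 10% with a
6-hour half-life (clearance) — generic small-molecule PSMA-ligand
plasma kinetics standing in for an unpublished whole-body
pharmacokinetic curve. A tabulated AIF (`load_aif_table()`) is
interpolated linearly with zero extrapolation beyond the last sample,
supporting future image-derived input functions.

**Tracer-limit amplitude.** The default peak is 1e-4 nmol/ml, far below
both the receptor density (R₀ ≈ 4.1e-2 nmol/ml) and the dissociation
constant (k_off/k_on = 1e-3 nmol/ml). In this regime receptor occupancy
stays low and every downstream field is *linear* in the injected
amount, so the shape of the spatial distribution is independent of the
(unknown) absolute molar amplitude — the most robust choice when only
the dose endpoint constrains the input. At substantially higher molar
amplitudes the model crosses into receptor saturation, uptake becomes
capacity- rather than supply-limited, and the vascular-fraction
dependence of the dose flattens; users exploring that regime can raise
`amplitudes` directly.

**Decay bookkeeping.** Physical decay is applied in the tissue
equations (all three pools) and *not* inside the AIF by default;
vascular decay is considered folded into the fitted clearance rates.
Setting `apply_physical_decay = TRUE` multiplies the AIF by
exp(−λ_dec·t) for users who fit decay-free plasma curves, at the cost
of that interpretation.

**Injected-activity calibration.** `calibrate_injection()` scales the
injected *activity* at fixed molar kinetics (the specific-activity
dial) so the domain-mean dose at the horizon equals the target
(default 10 Gy at 20 days). Dose is exactly linear in this scale, so
the calibration is `target / mean_dose(unit scale)` with a verification
evaluation; in an ensemble the calibration is performed once, on the
ROI closest to the median vascular fraction, and applied globally
(per-ROI calibration is available by calibrating each config
separately). We deliberately do not calibrate by scaling the molar
concentration: through saturable binding that couples the chemistry to
the dose target and makes "reaching 10 Gy" silently change the
transport regime.

## 4. Ligand transport

The three-compartment system (concentrations in nmol/ml; Cᵢ and C_b per
ml interstitium, C_int per ml cellular volume):

* ∂ₜCᵢ = ∇·(D ∇Cᵢ) − ∇·(v R_f Cᵢ) − k_on Cᵢ (R₀ − C_b) + k_off C_b − λ Cᵢ, wall flux J_v = L_v (C_v − Cᵢ)
* ∂ₜC_b = k_on Cᵢ (R₀ − C_b) − (k_off + k_int + λ) C_b
* ∂ₜC_int = k_int C_b · FVᵢ/FV_c − (k_rel + λ) C_int

Defaults (`ligand_params()`): L_v = 3.3e-4 cm/s, D = 8.7e-7 cm²/s,
R_f = 1, R₀ = 4.089e-2 nmol/ml, k_on = 0.77 ml nmol⁻¹ s⁻¹,
k_off = 7.7e-4 s⁻¹, k_int = 1.67e-5 s⁻¹, k_rel = 2.67e-6 s⁻¹,
FVᵢ = 0.39, FV_c = 0.61; λ_dec = 1.197e-6 s⁻¹ (¹⁷⁷Lu, t½ = 6.70 d) or
8.087e-7 s⁻¹ (²²⁵Ac, t½ = 9.92 d). The ¹⁷⁷Lu half-life is the older
literature value consistent with the decay constant above (the modern
6.647 d would give 1.207e-6 s⁻¹). The `FVᵢ/FV_c` factor makes
binding→internalization exactly mass-conservative under this volume
bookkeeping; released internalized ligand leaves the system
(degradation), as the equations state. Convection is off by default
(`velocity = NULL`) because no interstitial-pressure model is included;
a user-supplied velocity field is advected with first-order upwinding.

**Emergent transport regime.** With these constants the free ligand is
strongly retarded by reversible binding (effective diffusivity
D/(1 + R₀/K_d) ≈ D/42) and is removed from the mobile pool by
internalization after ≈ 1 day of cycling, giving an intrinsic
penetration scale of a few hundred µm from the vessels over a 20-day
horizon. This is the model's answer given the published kinetic
parameters; it is *less* heterogeneous than the activity distributions
implied by some reported microscale dosimetry, which is worth keeping
in mind when comparing dose-heterogeneity statistics (§6).

**Numerics.** Each step advances diffusion, wall flux, binding, and
decay *together* in one semi-implicit solve: the binding conductance
g = k_on (R₀ − C_b) is the only lagged quantity (receptor occupancy
evolves over hours–days), C_b⁺ and C_int⁺ are linear given Cᵢ⁺ and are
eliminated analytically, leaving a single SPD sparse system for Cᵢ⁺.
The extra diagonal is strictly positive, so the step is an M-matrix
solve: unconditionally stable and positivity-preserving. Avoiding
operator splitting here is essential, not cosmetic — the perivascular
boundary layer is set by the stiff balance of diffusion against wall
flux and binding, and splitting those terms makes ligand penetration
step-size dependent (an error of tens of percent at practical step
sizes, found and eliminated during development). Second-order accuracy
comes from Richardson extrapolation (each step computed at full and
half step size, `2·y_hh − y_full`), with a per-pixel fallback to the
un-extrapolated value wherever extrapolation would leave the physical
cone; wall-influx and decay-loss bookkeeping is combined under the same
per-pixel selection, so the global mass budget (influx − losses −
residual) closes to well under 0.5%. C_b is additionally asserted
≤ R₀ every step.

The default output grid is 60 log-spaced points from 30 s to 20 days
(dense early for the AIF distribution phase). At this density the
time-integrated activity changes by < 0.1% when the internal step is
halved; the `n_substeps` argument provides further refinement (the
single-voxel comparison against a stiff ODE solver uses a 400-point
grid with 8 substeps and agrees to 1e-4 of each compartment's scale).

**Time-integrated activity.** Ã per voxel is λ_dec ∫ N(t) dt with
N(t) the number of labelled molecules
(`[FVᵢ(Cᵢ+C_b) + FV_c·C_int] · V_voxel · 6.022e14`), integrated by
trapezoid on the solution grid.

## 5. Dosimetry

Dose is the discrete convolution of Ã with a voxel S-value kernel
(FFT-based for the large β kernel, direct shifted accumulation for the
compact α kernel; both paths agree with a brute-force sum to 1e-8).
The domain is zero-padded: activity outside the ROI is zero and energy
may leak off the edges, consistent with simulating an isolated
2-D section one voxel thick.

**Bundled kernels** are approximate analytic surrogates for externally
computed S-value tables (which can be supplied as CSV:
`d_offset_i, d_offset_j, S_Gy_per_decay`):

* ¹⁷⁷Lu: mean β energy 0.1335 MeV/decay (photons neglected), spread
  with a scaled point-kernel whose annular energy falls exponentially
  with attenuation length Rs/9 ≈ 180 µm (half the energy within
  ~125 µm, 90% within ~400 µm), truncated at the ≈1.6 mm range.
* ²²⁵Ac: the full decay chain's α energy, ≈27.5 MeV per parent decay,
  deposited with a linear radial falloff within the ≈50 µm α range.
  Daughters are assumed to decay at the parent decay site (no
  recoil/daughter migration), matching the transport model's
  parent-only simulation.

Both kernels are normalized so that kernel sum × voxel mass equals the
energy per decay (all emitted energy absorbed in an infinite medium),
are maximal at the origin, and are radially non-increasing. If the
support is below one voxel, all energy is local.

**DTH.** For each oxygenation class the cumulative dose-to-tissue
histogram gives the fraction of that class's pixels receiving at least
each threshold (1 at 0 Gy, monotone non-increasing); empty classes are
omitted with a warning. `fraction_receiving()` returns the exact,
unbinned value at one threshold (used for "fraction of hypoxic tissue
at the 10 Gy target" summaries).

**Dose–oxygenation regression.** `dose_oxygen_regression()` is
ordinary least squares of per-ROI mean dose on log₁₀ median pO₂
(`stats::lm`), refusing fewer than 3 ROIs or non-positive medians.

## 6. Radiobiology

Survival parameters (Table defaults of `lq_params()`): physoxic
α = 0.15 Gy⁻¹, β = 0.048 Gy⁻², D₀ = 0.7 Gy; radiobiologically hypoxic
α = 0.107 Gy⁻¹, β = 0.024 Gy⁻², D₀ = 1.18 Gy. ¹⁷⁷Lu uses the
linear-quadratic model, ²²⁵Ac the log-linear high-LET form (D₀ = dose
for 37% survival). Hypoxic parameters are never more radiosensitive
than physoxic ones, enforced at construction.

Only the two anchor classes have published parameters; the two
intermediate classes are covered by the default `linear_in_pO2` mode,
interpolating α, β, and 1/D₀ linearly in the local oxygen tension
between anchors at 3 and 15 mmHg (clamped outside). Interpolating 1/D₀
rather than D₀ keeps the log-kill rate linear in pO₂. A `class_step`
mode (anchor values switching at 3 mmHg) is provided for sensitivity
analysis; the published description is ambiguous between the two, so
both are first-class and the difference is a one-line config change.
Survival maps report mean/sd overall and per class; P_S = 1 exactly at
zero dose, and underflows to 0 at extreme doses (the mathematical range
is (0, 1]).

## 7. Pipeline, reproducibility, and problem sizes

`run_roi()` executes map → oxygenation → segmentation → transport → Ã →
dose → DTH → survival for each nuclide; both nuclides share the
identical vessel map, oxygen field, and AIF shape, differing only in
decay constant and kernel (the matched-ROI design). `run_ensemble()`
spans vascular fractions (default 10 ROIs evenly over 1.0–3.2%, one
seed each), calibrates once on the mid-vascularity ROI, and fits the
dose–oxygenation regression per nuclide, continuing past individual ROI
failures. Reports are deterministic given (config, seed); artifact
files embed a hash of the YAML-serialized config.

Problem sizes are the package's own scaling choices: the default grid
is 400 × 400 at 4 µm; the acceptance script runs the same 1.6 mm extent
at 8 µm (200 × 200, ~6 min single-core) and the test suite at 12.5 µm
(128 × 128), where the grid-refinement checks above bound the
discretization effect on the reported statistics.

## 8. Known limitations

* **2-D slab.** Diffusion, dosimetry, and vessel supply are in-plane
  only; out-of-plane vessels and cross-fire are absent, so distances to
  the nearest vessel (and hypoxic fractions) are systematically
  overestimated relative to 3-D tissue.
* **Chronic hypoxia only.** Vessel geometry and permeabilities are
  static; acute (perfusion-fluctuation) hypoxia, angiogenesis, vascular
  remodeling, and HIF-1–mediated response are out of scope.
* **Kernels are surrogates.** The bundled S-value kernels reproduce
  per-decay energy, range, and monotone radial falloff, not any
  specific published table; microdosimetric detail (cell geometry,
  spectrum structure) needs external tables via the CSV loader.
* **Single ligand species.** No labelled/unlabelled competition,
  receptor turnover, or interstitial-pressure-driven convection
  (velocity field must be supplied externally).
* **Homogeneous tissue.** Uniform receptor density, cellularity, and
  diffusivity outside vessels; real tumors violate all three.
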