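---
title: "Methods: simulating and quantifying holmium-microsphere distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying holmium-microsphere distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hodosim)
```

## The problem

In transarterial radioembolisation (TARE), 30 µm holmium-loaded
microspheres are injected into the hepatic artery (HA) and lodge in the
liver's arterioles. How evenly they distribute — and how strongly the local
deposition follows local perfusion — depends on the HA blood flow rate.
`hodosim` implements the quantitative analysis chain used to study this in
ex vivo machine-perfused porcine livers (DCE-MRI perfusion rates,
T2\*-based fictive dose maps, dose-volume homogeneity indices, micro-CT
vessel segmentation, perfusion–deposition correlation) together with a
fully synthetic phantom and deposition simulator so that every stage can be
exercised and tested with known ground truth.

Three HA flow conditions are modelled: 0.02 (low), 0.15 (medium) and 0.22
(high) mL/min/g liver tissue, with portal-vein flow fixed at exactly three
times the HA flow. The low condition is an extreme; the other two span the
clinically representative range.

## The phantom and the deposition model

`build_liver_phantom()` generates a smooth, seed-dependent liver envelope
(a randomly perturbed ellipsoid) partitioned into the five porcine lobes
(left lateral, left medial, right medial, right lateral, caudate) by an
additively weighted nearest-seed rule whose weights are iterated until the
lobe volume fractions match their targets (defaults 0.30/0.20/0.20/0.22/0.08).

`grow_arterial_tree()` gives each lobe a space-filling binary tree by
recursive 2-means bisection of the lobe's voxel cloud. Child radii follow a
Murray-type rule $r_\mathrm{parent}^3 = \sum_c r_c^3$ with flow fractions
$f_c \propto r_c^3$ (equivalently $f_c$ = the child's share of downstream
voxels), and terminal territories are the nearest-terminal Euclidean
partition of the lobe.

`simulate_deposition()` routes packets of microspheres (default $10^4$ per
fraction; a 250 mg fraction is ≈ $1.26\times10^7$ spheres, far beyond
per-sphere simulation need, and packet-scale binomial noise already
dominates voxel statistics) from a common root. The central abstraction is
a *mixing* parameter $m \in [0,1]$: how completely spheres homogenise with
blood before a bifurcation. At every bifurcation — including the root split
into lobes — a packet chooses child $c$ with probability

$$p_c = m\, f_c + (1-m)\, \frac{f_c^\gamma}{\sum_k f_k^\gamma},$$

so a well-mixed suspension follows flow exactly while a poorly mixed one is
biased along dominant streamlines into high-flow branches ($\gamma = 3$ by
default). Before each bifurcation the packet lodges in the current segment
with probability $\lambda (1-m) e^{-g/\tau_g}$ (generation $g$; defaults
$\lambda = 0.35$, $\tau_g = 2$) — proximal, large-vessel trapping that
dominates at poor mixing; packets reaching a terminal lodge there. Routing
is performed with binomial/multinomial draws, which is distributionally
identical to independent per-packet walks and makes mass conservation exact
by construction.

The mixing ↔ flow mapping (low → 0.25, medium → 0.65, high → 0.90,
interpolated monotonically for custom flows) is an explicit, named free
parameter: no quantitative mixing law is available from ex vivo data, so it
is calibrated only against qualitative homogeneity bands (below), and none
of $\gamma, \lambda, \tau_g$ or the mixing map should be read as a measured
quantity.

Lodged mass is rasterised to a concentration map (mg/mL): terminal mass is
spread over the terminal's territory with a within-territory density
gradient $w \propto e^{-d/\ell}$ (distance $d$ to the feeding arteriole,
$\ell$ = `territory_tau_mm`, default 1.5 mm) and blurred with a Gaussian of
1 voxel; non-terminal mass is painted along the segment centreline. Total
in-liver mass is rescaled to conserve the delivered mass exactly per
fraction. The gradient is the second named free parameter: it supplies the
capillary-scale heterogeneity a voxelised territory model otherwise lacks,
and its default was chosen so the simulated homogeneity indices fall in the
qualitative bands observed ex vivo (≈ 3.5–5 at low and ≈ 1.5–2.5 at high
flow); those bands are calibration targets, not measurements.

## Image synthesis

*Multi-echo T2\*.* The magnitude signal is
$S(TE) = S_0 e^{-(R_2^{*0} + r_2^* C)\,TE}$ with baseline
$R_2^{*0} = 35\ \mathrm{s^{-1}}$, relaxivity $r_2^* = 90\
\mathrm{s^{-1}\,mL/mg}$ at 1.5 T and the 10-echo protocol
$TE = 1.7 + 1.35k$ ms. Rician noise (the correct magnitude-MR model) is
applied per echo. The relaxivity is not separately identifiable from the
study's printed values; synthesis and analysis share the constant, and a
deliberately mis-specified analysis relaxivity biases concentrations
linearly (config-exposed for sensitivity analysis).

*DCE.* Each lobe's enhancement is prescribed directly in
percent-enhancement (PE) domain, $PE_l(t) = A_l\,\sigma((t-t_0)/\tau)$ with
logistic $\sigma$, amplitude $A_l$ proportional to the lobe's ground-truth
perfusion rate, and the signal derived by inverting the printed PE
convention: $S_l(t) = S_0 / (1 - PE_l(t)/100)$. Prescribing PE rather than
signal makes the analytic maximum PE slope exactly $A_l/(4\tau)$ — exactly
proportional to perfusion — and makes all lobes' PE curves scalar multiples
of one shape, so the sliding-window slope estimator (linear in the data)
recovers *relative* perfusion exactly on noiseless input regardless of its
discretisation bias. Acquisition follows the study protocol: 200 frames at
0.86 s (duration 171.14 s). Optional reduced-perfusion lobes (delayed,
damped wash-in, as occasionally observed) are off by default because their
impact on relative flow was minimal.

*Micro-CT.* A cubic sample (≤ 20 mm, the physical tissue-block size;
default 5 mm at desk scale) at 30 µm voxels: Gaussian parenchyma
(N(40, 15) HU) and bright cylinders (≥ 600 HU) for microsphere-filled
lumina, with radii drawn from the lobe's tree segments weighted by
deposited mass — so poor mixing, which loads proximal large segments,
yields visibly larger filled calibres.

## Analysis stages

*R2\* mapping* (`fit_r2star`): per-voxel weighted least squares on
$\ln S$ vs $TE$ with weights $\propto S^2$ (the first-order variance
weighting of log-transformed magnitude data); echoes at or below the noise
floor are excluded, voxels with < 3 usable echoes are flagged invalid
(never zeroed), and R2\* is clipped to [0, 2000] s⁻¹ as a signal-void
guard. Log-linear WLS was chosen over nonlinear LS as deterministic, fast
and unbiased to well under 2 % at the SNR of interest (SNR₁ = 50).

*Concentration and dose* (`concentration_map`, `dose_map`):
$C = \max(0, \Delta R_2^*)/r_2^*$ from pre/post maps (noise-induced
negative deltas are clamped and counted in QC); the fictive dose follows
the ¹⁶⁶Ho local-deposition model, $D = k_\mathrm{Ho}\, C\,
\mathrm{SA}/\rho$ with fictive specific activity SA = 12 MBq/mg, dose
factor $k_\mathrm{Ho} = 15.87$ Gy·kg/GBq and tissue density
$\rho = 1.04$ g/mL. These constants reproduce both printed dose-limit
conversions to two decimals (60 Gy ↔ 0.33 mg/mL; 300 Gy ↔ 1.64 mg/mL);
they are jointly, not individually, constrained by those correspondences
and are all config-exposed.

*Perfusion* (`analyze_perfusion`): lobe time-intensity curves, the printed
PE transform $PE = 100 (S_1 - S_0)/S_1$ — note the *post-injection*
denominator; the conventional $S_0$ form is available behind a flag because
the printed convention may be deliberate or a typo, and the package pins
the printed form by default — then the maximum wash-in slope by
sliding-window (5-frame ≈ 4.3 s) regression inside a wash-in window from
the last frame below 5 % to the first frame above 95 % of the curve
maximum (bounds config-exposed; the study does not state them). Flat
curves are flagged "non-enhancing" with slope 0.

*Homogeneity* (`homogeneity_index`): $HI = (D_{2\%} - D_{98\%}) /
D_\mathrm{mean}$ with $D_{p\%}$ = dose exceeded by exactly $p$ % of the
masked volume, i.e. the $(100-p)$th percentile with linear interpolation
between order statistics (the radiotherapy DVH convention; `quantile`
type 7). All in-mask voxels enter, zero-dose voxels included — the study
computed whole-organ maps including cold lobes, and whether it restricted
to perfused tissue is unknown, so whole-mask is the default. Lower HI =
more homogeneous; HI is scale-invariant.

*Association* (`correlate_perfusion_deposition`): lobe microsphere counts
from concentration (count = mass × 1/(ρπd³/6) ≈ 5.05×10⁴ per mg — the
study's count conversion is not printed; this assumption is documented,
not asserted), Pearson's r with a two-sided t-test (reported, never used
as a gate), and the printed interpretation bins (boundaries upward;
r ≥ 1 − 10⁻⁹ counts as perfect; negative r is reported signed and
labelled out-of-bin rather than absolute-valued, since the printed bins
cover [0, 1] only).

## Numerical and design notes

- **Geometry.** 0-based voxel indexing, (x, y, z) axis order,
  voxel-centre coordinates; NIfTI affines are respected on I/O; multi-echo
  and dynamic series are 4-D NIfTI plus a JSON sidecar for echo times /
  frame interval (NIfTI has no standard field for them). Phantom series
  are born co-registered; registration of real data is out of scope, and
  lobe ROIs are assumed co-registered across series.
- **Randomness.** All stages draw from named substreams of one top-level
  seed (`substream_seed`), so a pipeline run is a pure function of
  (config, seed); repeated runs are byte-identical.
- **Micro-CT radii.** Components are labelled at 26-connectivity
  (standard for thin tubular structures); the per-component radius is the
  maximum Euclidean distance to background, computed by a chamfer
  propagation bounded above and refined exactly by brute force on the
  near-maximal voxels.
- **Degenerate inputs.** Empty lobes yield flagged NaN summary rows (the
  run continues) but are an error where a curve is required; an all-zero
  dose map leaves HI undefined (flagged); capacity overflow beyond a lobar
  root raises a "stasis" error (unreachable at default, effectively
  unbounded, capacity).
- **Whole-organ vs lobe HI.** Pooling lobes adds between-lobe variance, so
  the whole-liver HI exceeds the volume-weighted mean of single-lobe HIs
  on low-flow phantoms. It does not dominate *every* single lobe: the lobe
  holding the proximal centreline deposit can be internally more
  heterogeneous than the whole organ.

## Desk-scale problem sizes

The package's tests and examples run a ~240 mL phantom (24×24×16 voxels at
4 mm, ≈ 1/13 of a 2.6 L porcine liver at full scale) with 5 tree
generations (16 terminals per lobe), and scale the administration schedule
by liver volume so the administered concentration trajectory in mg per mL
liver matches the study schedule (5 × 250 mg, optionally + 4 × 1000 mg,
into ≈ 3.1 L). Directional claims (HI decreasing and perfusion–deposition
r increasing with mixing; proximal mass fraction and filled-vessel calibre
larger at low flow; HI trajectories flattening beyond ≈ 1 mg/mL) are
evaluated over 10 seeds per level at this scale.

## What passing tests do and do not show

The phantom emulates: five-lobe anatomy with realistic volume fractions,
flow-proportional vs streamline-biased transport, proximal trapping at
poor mixing, territory-scale dose heterogeneity, Rician/Gaussian
measurement noise, and the acquisition timing of the study protocols. It
does **not** emulate computational fluid dynamics, pulsatile flow,
portal-vein transport (PV flow enters only as condition metadata and DCE
baseline physiology), catheter-tip position effects, vasospasm, liver
deterioration over perfusion time, or scanner artefacts
(B0 inhomogeneity, partial volume, registration error). Agreement of the
pipeline with phantom ground truth therefore validates the *analysis
chain* and the simulator's internal consistency — it does not re-derive
the ex vivo measurements, whose headline values (r = 0.611/0.977/0.951;
HI ranges 3.68–4.72 / 2.01–2.66 / 1.60–2.36) serve here only as
qualitative calibration bands and directional targets.

```{r example, eval = FALSE}
# A complete run at desk scale:
cfg <- pipeline_config(
  seed = 7,
  phantom = list(shape = c(24L, 24L, 16L)),
  tree = list(generations = 5L),
  condition = list(name = "high"),
  outdir = "run_high")
report <- run_pipeline(cfg)
report$summary$final_dose_stats
report$summary$pearson_r
```
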