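# hodosim

Simulation and MRI-based dosimetry of holmium-microsphere distribution in
machine-perfused livers.

## What this is for

In transarterial radioembolisation (TARE), radioactive 30 µm
holmium-loaded microspheres are delivered through the hepatic artery (HA)
and lodge in the liver's arterioles. A central question for treatment
planning is how the HA blood flow rate shapes the deposition pattern: does
a well-perfused lobe receive proportionally more spheres, and how
homogeneous is the resulting absorbed dose? `hodosim` implements the full
quantitative analysis chain for studying this in ex vivo machine-perfused
porcine livers under MRI, plus a synthetic test bed:

- a five-lobe liver phantom with space-filling arterial trees and a
  flow-rate-dependent microsphere **deposition simulator** (mixing-biased
  routing, proximal lodging at poor mixing) with known ground truth;
- synthesis of **multi-echo T2\*-weighted**, **DCE-MRI** and **micro-CT**
  images from that truth (Rician/Gaussian noise, the study's acquisition
  timing: 10 echoes at TE = 1.7 + 1.35k ms; 200 frames at 0.86 s);
- voxel-wise **R2\* mapping** (weighted log-linear fits), holmium
  **concentration** maps (ΔR2\*/r₂\*) and **fictive dose** maps
  (D = k·C·SA/ρ with fictive specific activity 12 MBq/mg);
- **dose statistics**: D2%, D98%, Dmean and the homogeneity index
  HI = (D2% − D98%)/Dmean (lower = more homogeneous), plus
  HI-versus-cumulative-mass trajectories;
- **perfusion rates** from DCE time-intensity curves via the percent
  enhancement PE = 100·(S₁ − S₀)/S₁ and the maximum wash-in slope;
- **micro-CT segmentation** at the 350 HU threshold with per-vessel
  radius estimates;
- **perfusion–deposition correlation** (Pearson r with the standard
  interpretation bins) and hemodynamic worked-example utilities.

Audience: physicists and image analysts working on Ho-TARE dosimetry,
machine-perfusion experiments, or validation of voxel dosimetry pipelines.

## Worked example

A desk-scale phantom (~240 mL liver, 4 mm voxels) under the high-flow
condition (0.22 mL/min/g HA flow, portal-vein flow 3× that, mixing 0.90):

```r
library(hodosim)

lab   <- build_liver_phantom(shape = c(24, 24, 16), spacing = c(4, 4, 4), seed = 7)
trees <- lapply(1:5, function(l)
  grow_arterial_tree(lab$labels == l, lab$spacing, generations = 5, seed = 7 + l))
truth <- simulate_deposition(lab, trees, fraction_schedule(),
                             flow_condition("high"), seed = 7)
truth
#> <phantom_truth> high condition (mixing 0.90), 5 fractions, 1250 mg delivered
#>   lobe deposited mass (mg): 397, 253, 244, 263, 93

homogeneity_index(dose_map(truth$true_concentration[[5]]), mask = lab$labels > 0)
#> <dose_stats> D2% 2.22e+03 Gy, D98% 187 Gy, Dmean 966 Gy, HI 2.11 (n=3701)

dce  <- synthesize_dce(truth, noise_sd = 10, seed = 7)
perf <- analyze_perfusion(dce, lab)
correlate_perfusion_deposition(
  perf, microsphere_counts(truth$true_concentration[[5]], lab))
#>   lobe relative_perfusion    count relative_count
#> 1    1         0.29668701 20511317     0.32476854
#> 2    2         0.20584569 12751082     0.20189588
#> 3    3         0.19708780 12345393     0.19547235
#> 4    4         0.21588534 13239257     0.20962546
#> 5    5         0.08449417  4309674     0.06823777
#> Pearson r = 0.996 (p = 0.000262), very strong correlation
```

The HI of ~2.1 sits in the homogeneous (high-flow) regime, and deposition
tracks perfusion almost perfectly — repeat with
`flow_condition("low")` (0.02 mL/min/g, mixing 0.25) and the HI rises to
~3.5–4 while the correlation degrades, the flow-dependence the simulator is
built to reproduce. Clinical reference points computed by the same code:

```r
round(concentration_for_dose(60), 2)        # 0.33 mg/mL at the 60 Gy whole-liver limit
round(concentration_for_dose(300), 2)       # 1.64 mg/mL for a 300 Gy single-lobe dose
flow_to_velocity(32, 0.6)$cm_per_s_int      # 188 cm/s injection velocity (0.6 mm catheter)
```

The full chain — phantom → deposition → image synthesis → R2\* fitting →
dose maps → DCE analysis → metrics → correlation, with all NIfTI volumes,
CSV tables, a JSON summary and a run log — is one call:

```r
report <- run_pipeline(pipeline_config(
  seed = 7,
  phantom = list(shape = c(24L, 24L, 16L)),
  tree = list(generations = 5L),
  condition = list(name = "high"),
  outdir = "run_high"))
```

Runs are pure functions of (config, seed): the same call twice produces
byte-identical summaries. See `vignettes/hodosim-methods.Rmd` for the
model, its free parameters and their calibration, and what the synthetic
tests do and do not demonstrate.

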