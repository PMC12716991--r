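# trogomech

Quantitative analysis of the macrophage decision between **trogocytosis**
(nibbling sub-micrometre membrane "bites" off a target) and **phagocytosis**
(complete engulfment). The package is for quantitative immunologists and
membrane biophysicists who quantify these behaviours with three-channel flow
cytometry, measure target cortical or membrane tension by micropipette
aspiration, and want to test the mechanical picture in which the target's
deformability — not a dedicated signalling pathway — selects the behaviour.

## The model

Antibody (IgG) on the target engages macrophage Fcγ receptors and triggers
active cytoskeletal stresses at the interface. Taking the normal stress to
scale with antibody surface density, σ(ρ_AB) = α·ρ_AB, and balancing it
against the target cortical tension γ_t,

    σ(ρ_AB) · R_min² ≈ γ_t · R_min   ⟹   R_min ≈ γ_t / σ(ρ_AB),

R_min is the smallest deformation ("bite") the macrophage can pinch off.
When R_min is small compared with the interface size R (~1 µm) the
macrophage trogocytoses; when R_min ≳ R it can only engulf the whole target;
below an engagement density ρ_engage (~10² molecules/µm²) nothing happens.
Setting R_min = R gives a critical antibody density proportional to tension,
ρ_crit = γ_t/(α·R), and a switch tension γ_switch = σ·R. At σ = 100 Pa these
give bite sizes of 0.1–1 µm across γ_t = 10⁻²–10⁻¹ mN/m and a behavioural
switch near 0.1 mN/m.

Around this core the package implements the full measurement pipeline:

* three-channel cytometry gating (cytosol marker / target-volume marker /
  surface-IgG marker) into phagocytosis, trogocytosis or neither, with
  efficiencies as percentages of macrophage-positive events;
* Young–Laplace tension from aspiration records,
  γ = ΔP / (2(1/R_pipette − 1/R_cell));
* MESF bead calibration converting fluorescence to molecules of IgG per µm²;
* the decreasing sigmoid y = a(1 − 1/(1 + e^{−(x−ρ_crit)/d})) fitted by
  Levenberg–Marquardt, with case-resampling bootstrap CIs on ρ_crit and an
  OLS fit (with bootstrap envelope) of ρ_crit against tension;
* the behaviour phase diagram over (ρ_AB, γ_t);
* seeded synthetic generators for every input, so the whole pipeline runs
  and is tested without instrument data.

## Worked example

```r
library(trogomech)

# synthetic coculture: 20% phagocytosing, 60% trogocytosing macrophages
ev  <- generate_coculture_events(coculture_config(n_events = 1e5, seed = 1))
thr <- derive_thresholds(generate_control_events(1e5, seed = 2))
compute_efficiencies(classify_events(ev, thr))
#> Macrophage events: 100000
#>   phagocytosis: 20065 events, efficiency 20.07%
#>   trogocytosis: 59961 events, efficiency 59.96%

# low-tension vesicles measured by aspiration (truth 0.26 mN/m)
asp <- generate_aspiration_series(true_tension = 0.26, pipette_radius = 2.5,
                                  cell_radius = 7.5, pressure_noise_sd = 5,
                                  n = 15, seed = 3)
gamma <- tension_from_aspiration(asp$dP_suction_Pa, asp$R_pipette_um,
                                 asp$R_cell_um)
summarize_tensions(gamma, rep("guv_low", 15))
#>     group  n mean_mN_per_m sd_mN_per_m frac_below_cutoff frac_above_cutoff
#> 1 guv_low 15     0.2582131 0.007381882                 1                 0

# critical antibody density from a noisy titration (truth: a 80, rho 500, d 100)
titr <- generate_titration(titration_config(noise_sd = 4, seed = 4))
bootstrap_rho_crit(titr, n_boot = 1000, seed = 5)$fit
#> Sigmoid fit (decreasing), 24 points:
#>   plateau a  : 82.27 %
#>   rho_crit   : 503.7 molecules/um^2  (95% CI 480.9-519.4)
#>   width d    : 104 molecules/um^2
#>   RSS 275.1, converged: TRUE

# the mechanical predictions and the phase diagram
r_min(0.1, 100)                 # 1 (um): largest predicted bite size
predict_switch_tension(100, 1)  # 0.1 (mN/m): behaviour switch at 100 Pa
build_phase_diagram()
#> Phase diagram: 100 x 100 grid (tension x antibody density)
#>   rho_ab  in [10, 1e+04] molecules/um^2
#>   gamma_t in [0.001, 10] mN/m
#>   cells: no_engagement 3300, phagocytosis 2688, trogocytosis 4012
```

The gated efficiencies land within sampling error of the generating 20%/60%
mixture, the aspiration estimate recovers the 0.26 mN/m ground truth, the
sigmoid fit recovers (a, ρ_crit, d) within its confidence interval, and the
phase diagram partitions the (density, tension) plane into the three
behaviours with the proportionality boundary ρ_crit(γ_t) between bites and
engulfment.

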