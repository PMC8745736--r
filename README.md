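# petkin

Analysis toolkit for engineering PET-hydrolysing enzymes (PETases,
EC 3.1.1.101). Directed-evolution campaigns against poly(ethylene
terephthalate) generate a characteristic mix of data — docked ligand poses,
per-residue binding-energy decompositions, conservation rates, 96-well
pH-indicator screens, turbidity traces on nanoparticle suspensions, CD
melts, residual-activity time courses and bulk bioconversion curves — and
petkin turns each of them into parameters with units, uncertainties and
explicit quality flags. A seeded synthetic-data generator reproduces the
statistical structure of every assay, so the whole pipeline is testable
end to end without instrument output.

## What it computes

The kinetic core is the heterogeneous-catalysis model for enzymatic erosion
of polymer nanoparticles. The blank-corrected relative turbidity

    τ/τ0 = |OD600 − OD600°|_t / |OD600 − OD600°|_0

declines such that √(τ/τ0) is linear in time after a short lag; the initial
rate v = −d(τ/τ0)^½/dt saturates with enzyme concentration [E] by a
Langmuir-type adsorption law

    v([E]) = k_τ · K_A · [E] / (1 + K_A · [E])

yielding the maximal rate k_τ (min⁻¹) and the adsorption equilibrium
constant K_A (mL mg⁻¹). Around that core:

* `fit_melting_curve()` — two-state Boltzmann melt fits (T_m, width) with
  linear baselines; `fit_inactivation_decay()` — first-order inactivation
  constants and half-lives; `stability_report()` — ΔT_m and labeled
  fold-changes against a reference variant.
* `absorbance_to_concentration()`, `depolymerization_yield()`,
  `convert_specific_rate()`, `analyze_bioconversion()` — Beer–Lambert
  product quantification, molar/mass yields and specific rates with
  explicit molar-mass conventions.
* `score_plate()`, `summarize_library()` — control-anchored relative
  activities (negative control = 0%, parent = 100%) for phenol-red
  screening plates, hit calling by pooled-control-SD margins.
* `degenerate_codon_profile()`, `library_coverage()` — NNK/NNS/NNN codon
  statistics and exact library-coverage probabilities.
* `filter_competent_poses()`, `cluster_poses()`, `select_ssm_positions()` —
  geometric catalytic-competence filtering of docked poses, leader
  clustering by ligand RMSD, and site-saturation-mutagenesis position
  selection from binding-energy hotspots, conservation filtering and
  reasoned exclusions.
* `simulate_*()` — seeded generators for all of the above, exact at zero
  noise.

See `vignettes/petkin-methods.Rmd` for the models, defaults and numerical
choices.

## Worked example

Simulate a triplicate rate-versus-[E] experiment at 2% instrument noise for
a variant with k_τ = 0.124 min⁻¹ and K_A = 75.38 mL mg⁻¹, then refit:

```r
library(petkin)

cfg <- sim_config(seed = 20, noise_sd_rel = 0.02)
gt  <- kinetic_truth(k_tau = 0.124, K_A = 75.38)
ex  <- simulate_kinetic_experiment(gt, cfg, replicates = 3)
rates <- lapply(ex$traces, function(tr)
  estimate_initial_rate(compute_relative_turbidity(tr)))
fit_langmuir_kinetics(rates)
#> Langmuir kinetic fit (n = 18):
#>   k_tau = 0.1235 +/- 0.00056 1/min
#>   K_A   = 76.03 +/- 1 mL/mg
#>   R2    = 0.9996
```

Both generating parameters are recovered within one standard error: the
maximal erosion rate 0.1235 ± 0.0006 min⁻¹ and the adsorption constant
76.0 ± 1.0 mL mg⁻¹ (truth 0.124 and 75.38). Stability and screening work
the same way:

```r
fit_melting_curve(simulate_melt(55.3, 2, cfg = cfg))
#> Two-state melt fit: T_m = 55.53 +/- 0.095 C (width 2.06 C, R2 = 0.9982)

fit_inactivation_decay(simulate_decay(2.46, c(0, 1/6, 1/3, 0.5, 2/3, 1), cfg))
#> First-order inactivation: k_in = 2.52 +/- 0.037 1/h, half-life 0.275 h

depolymerization_yield(4.2, 5.2, "mass")
#> Depolymerization yield (mass basis): 80.8%

convert_specific_rate(52.3, 166.13)  # uM/ug/day -> g_TAeq/L/g_enzyme/h
#> [1] 362.025

library_coverage(degenerate_codon_profile("NNK"), 94)
#> Coverage at n = 94 clones: E[fraction seen] = 0.9691, P(all seen) = 0.5197
#> Clones for 95% confidence on the rarest amino acid: 95
```

A T_m of 55.53 ± 0.10 °C against a simulated 55.3, an inactivation
constant of 2.52 ± 0.04 h⁻¹ against 2.46 (half-life 17 min), an 80.8%
mass-basis depolymerization yield, and the NNK arithmetic: 94 clones see
97% of amino acids on average but all 20 only about half the time — 95%
confidence on the rarest amino acid needs 95 clones.

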