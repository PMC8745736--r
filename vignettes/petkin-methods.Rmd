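---
title: "Models and methods behind petkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind petkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

petkin implements the quantitative backbone of a semi-rational evolution
campaign for PET-hydrolysing enzymes (PETases, EC 3.1.1.101): choosing
site-saturation mutagenesis (SSM) positions from docking, binding-energy and
conservation data; sizing NNK libraries; normalizing pH-indicator screening
plates; and characterizing variants by turbidimetric kinetics on polymer
nanoparticles, thermal stability and bulk bioconversion. The exported R
functions are the interface; every assay also has a seeded simulator so the
whole pipeline can be validated end to end without instrument data.

## Turbidimetric kinetics on nanoparticle suspensions

Enzymatic PET hydrolysis is a surface-erosion process. For a suspension of
nanoparticles monitored by OD600, the blank-corrected, normalized turbidity

$$\tau/\tau_0 = \frac{|OD_{600} - OD_{600}^\circ|_t}{|OD_{600} - OD_{600}^\circ|_0}$$

tracks the remaining particle volume (`compute_relative_turbidity()`; the
first element is exactly 1 by construction, and a trace whose initial
blank-corrected signal is zero is rejected as degenerate). For erosion of
monodisperse spheres the *square root* of $\tau/\tau_0$ decays linearly in
time, so the observable rate is $v = -\,d(\tau/\tau_0)^{1/2}/dt$ in the
linear region after a short mixing/settling lag.

Because catalysis requires adsorption of the enzyme to the particle surface,
$v$ saturates in enzyme concentration $[E]$ according to a Langmuir-type
rate law:

$$v([E]) = \frac{k_\tau\, K_A\, [E]}{1 + K_A\,[E]}$$

with $k_\tau$ (min^-1^) the maximal square-root-turbidity decline at surface
saturation and $K_A$ (mL mg^-1^) the adsorption equilibrium constant
(`langmuir_rate()`, `fit_langmuir_kinetics()`). The law is monotone in
$[E]$, bounded by $k_\tau$, and passes through $k_\tau/2$ at
$[E] = 1/K_A$ — identities the test suite checks directly.

Numerical choices:

* **Window selection.** "Linear region" is made reproducible as: all
  contiguous windows of at least 5 points starting after the configured lag
  (default 1.5 min, the midpoint of the 1–2 min transient) are scored by
  least-squares $R^2$ on $(t, \sqrt{\tau/\tau_0})$; the earliest start with a
  window reaching $R^2 \ge 0.98$ wins, and at that start the window
  maximizing $R^2$ (ties to the longer window) is used. On an exact trace
  this reproduces the generating slope to better than 0.1% and stops
  exactly where the suspension clears. Without any qualifying window the
  globally best window is used; negative slopes are clamped to zero with a
  flag, never silently.
* **Fitting.** Levenberg–Marquardt (via minpack.lm) on
  $\log k_\tau, \log K_A$, which enforces positivity without constraints;
  initialized at $k_\tau = \max v$ and $K_A = 1/[E]_{\text{half-max}}$.
  Standard errors come from the Jacobian-based covariance at the optimum,
  delta-transformed back from the log scale; $R^2 = 1 - SS_{res}/SS_{tot}$
  is the usual nonlinear regression coefficient.
* **Weighting.** Uniform by default; `weights = "sd"` uses $1/\mathrm{sd}^2$
  when replicate SDs are supplied. Replicate-mean versus replicate-level
  weighting is not identifiable from published summary fits, so both inputs
  are accepted.
* **High-concentration deviation.** Above roughly a monolayer of adsorbed
  enzyme the Langmuir picture fails and measured rates fall below the
  curve. Such points are only removed through the explicit
  `exclude_above` argument and are echoed in the fit object — never
  dropped silently.

## Thermal stability

`fit_melting_curve()` models a CD melt at 222 nm as a two-state Boltzmann
sigmoid between linear folded/unfolded baselines,
$y(T) = b_f(T) + \left(b_u(T) - b_f(T)\right)/\left(1 + e^{(T_m - T)/w}\right)$,
with $T_m$ the inflection point and $w$ the transition width. A two-state
sigmoid (rather than a van 't Hoff $\Delta H$ parameterization) was chosen
because it has the fewest parameters and is stable on noisy ramps; $T_m$
estimates are invariant under affine transforms of the signal axis, so the
choice of ellipticity units is immaterial. Baselines are initialized from
the outer 15% of the ramp, the width is log-parameterized, and a ramp whose
baseline-corrected amplitude is within four residual SDs of zero — or whose
fitted midpoint escapes the ramp — is rejected as "no transition detected".

`fit_inactivation_decay()` fits first-order activity loss
$a(t) = e^{-k_{in} t}$ to a time course normalized to $a(0) = 1$. The
log-linear slope is only the initializer; the primary fit is the direct
nonlinear one, which avoids the bias log-transformed noise introduces.
Points below a 1% detection floor are excluded; a constant series returns
$k_{in} = 0$ with `half_life = Inf` and a `stable` flag rather than a
number. `stability_report()` then tabulates $\Delta T_m$ against a
designated reference and fold-changes of $k_{in}$ in both directions,
labeled, since "x-fold more stable" and "x-fold faster inactivation" are
reciprocal claims that are easy to confuse.

## Bioconversion quantification

Soluble aromatic hydrolysis products (MHET, TPA, BHET) absorb at 240 nm and
are quantified jointly by Beer–Lambert conversion with
$\varepsilon_{240} = 13.8\ \mathrm{mM^{-1} cm^{-1}}$
(`absorbance_to_concentration()`); the single-wavelength assay cannot
resolve the product species, so they are treated as one aromatic-equivalent
pool. Depolymerization yield is reported on either basis: molar (products
in mM over theoretical repeat units, using a configurable repeat-unit mass
defaulting to 192.17 g mol^-1^ for C~10~H~8~O~4~) or mass (degraded over
initial mass). Yields above 100% are flagged, not clamped, since they
indicate an inconsistent input rather than chemistry. Note that published
molar yields depend on the (often unstated) molar basis: 10.6 mM of
products on 9 mg mL^-1^ PET is 22.6% with the repeat-unit mass used here,
while the source literature for this assay reports ~26% without stating its
basis; petkin makes the constant explicit rather than forcing agreement.
`convert_specific_rate()` converts µM~products~/µg~enzyme~/day (volume
basis 1 mL, i.e. mol g^-1^ day^-1^) to g L^-1^ g~enzyme~^-1^ h^-1^ by
multiplying with a product-equivalent molar mass (default TPA,
166.13 g mol^-1^) and dividing by 24.

## Plate screening

The phenol red (PSP) assay reports hydrolysis as acidification: more active
wells end up with *lower* A540. `score_plate()` anchors every well to the
on-plate controls,

$$\mathrm{activity\,\%} = \frac{\bar A_{neg} - A_{well}}{\bar A_{neg} - \bar A_{parent}} \times 100,$$

so empty-vector wells score ~0%, parent wells ~100%, and improved clones
extrapolate beyond 100%. The score is invariant to common gain/offset
changes of the reader and strictly monotone in acidification. The real dye
response is sigmoidal in pH; between the control anchors a linear map is
used because the assay provides no calibration points to fit anything
richer. Hits are wells exceeding 100% by more than `margin` (default 2)
pooled control SDs on the activity scale — the published protocol re-screens
hits but states no numeric threshold, so the margin is explicit and
tunable. Control aggregation is the mean (median available for
robustness); compromised wells are excluded via the layout role `empty`,
never imputed. `summarize_library()` reports the fractions of clones below
and above the parent band and a top-k ranking.

## NNK library mathematics

`degenerate_codon_profile()` expands any IUPAC degenerate codon
exhaustively and translates it with the standard genetic code (table 1; the
expression host is *E. coli*): NNK gives 32 codons, all 20 amino acids and
a single stop (TAG). `library_coverage()` treats clones as independent and
codon-unbiased (primer synthesis bias is out of scope): the expected
fraction of amino acids seen in $n$ clones is
$\overline{1 - (1-p_{aa})^n}$, the probability that *all* are seen comes
from inclusion–exclusion grouped by distinct codon multiplicity (exact and
cheap: the number of terms is the product over multiplicity classes, not
$2^{20}$), and `clones_for_target` is the smallest $n$ at which the rarest
amino acid appears with the requested confidence — for NNK at 95%, 95
clones. Stop codons stay in the per-draw probability space but are not
coverage targets: a stop at the randomized position is a non-variant.

## Hotspot selection

`filter_competent_poses()` encodes the geometric pre-condition for serine
hydrolase attack on a docked polymer chain: a pose is catalytically
competent when, for at least one flagged ester group, the ester carbon lies
within 4 Å of the catalytic serine Oγ *and* the carbonyl oxygen lies within
4 Å of the backbone amide N of both oxyanion-hole residues (strict `<`, per
the stated rule). Atoms are located by PDB names (`OG`, `N`) and
configurable residue numbers (defaults 160 and 87/161 in mature-protein
numbering, i.e. with the secretion signal removed); a missing atom is an
error naming residue and atom, never a silent skip.

`cluster_poses()` is greedy leader clustering in docking-score order:
the best unassigned pose seeds a cluster and poses within the RMSD
threshold (default 1 Å) join it. RMSD is computed over ligand heavy atoms
*without* superposition, because docked poses share the receptor coordinate
frame — superposing would erase exactly the rigid-body differences the
clustering is meant to see.

`select_ssm_positions()` combines three criteria with fixed edge
semantics: hotspot when the mean per-residue binding free energy
contribution is $\le -1$ kcal mol^-1^ (inclusive, as the threshold is
stated with $\le$), conserved when the per-site relative evolutionary rate
is $< 1.2$ (exclusive; 1.2 is the sequence-average rate), and excluded only
through a user-supplied list in which every entry must carry a reason
string — prior-knowledge exclusions are an auditable input, never
hardcoded. Selection is `hotspot & !conserved & !excluded`, deterministic,
order-independent, and monotone in the energy threshold. Running the
docking, MD, MM-PBSA or Rate4Site computations themselves is out of scope;
the module consumes their tabular and coordinate outputs (or the synthetic
equivalents below).

## The synthetic-data generator

Each `simulate_*()` function draws from a single RNG stream seeded by its
`sim_config()` (seed recorded in all written metadata), and with
`noise_sd_rel = 0` reproduces its closed form to machine precision — that
exactness is what lets round-trip tests pin fitting code to analytic
ground truth.

* **Turbidity** (`simulate_turbidity()`): after the lag,
  $(\tau/\tau_0)(t) = \max(0, 1 - v\,(t - t_{lag}))^2$ with $v$ from the
  Langmuir law; OD600 is blank + $\tau_0 \cdot \tau/\tau_0$. Defaults: 10 s
  sampling, 20 min duration, 1.5 min lag, initial OD 0.45 over a 0.05
  blank (typical for ~94 µg mL^-1^ nanoparticles). The standard
  concentration grid 0.002–0.08 mg mL^-1^ spans the published assay range.
* **Melt** (`simulate_melt()`): the same Boltzmann model the fitter uses,
  default 30–75 °C in 0.5 °C steps.
* **Decay** (`simulate_decay()`): exponential loss, renormalized so the
  t = 0 reading is exactly 1, as the assay defines 100%.
* **Plates** (`simulate_plate()`): control wells at nominal means (0.80
  negative, 0.40 parent) and samples on the linear activity→A540 map.
* **Hotspot fixtures** (`simulate_hotspot_fixtures()`): a minimal receptor
  carrying the catalytic machinery at fixed synthetic coordinates, ligand
  poses jittered (±0.15 Å per coordinate) around a competent template —
  ester carbon 3.5 Å from Oγ — or translated 5 Å away per non-competent
  cluster, plus energy/conservation tables copied from the scenario. The
  geometry is constructed, not physical: it controls distances and RMSDs,
  nothing else.

Noise is additive Gaussian with SD proportional to the local model value
(default 2% relative, matching typical plate-reader/spectrophotometer
repeatability), except for melts, where the SD is proportional to the
folded–unfolded dynamic range — a purely proportional model would assign
zero noise to a baseline at zero ellipticity. Published work in this area
reports only replicate SDs, so these magnitudes are chosen, not matched;
passing recovery tests therefore demonstrates correctness of the estimators
under the stated noise model, not robustness to every real-data pathology
(baseline drift, particle sedimentation at long times, Mie-scattering
nonlinearity, pH-sigmoidal dye response, adsorption beyond a monolayer at
high enzyme loads — all deliberately outside the generators).

## Problem sizes and determinism in the test suite

The suite validates parameter recovery with 200-seed ensembles for the
one-parameter decay fit and 60–200 seeds for the two-parameter Langmuir
fit at 5% relative noise (triplicate rate datasets, six concentrations) —
ensembles large enough to make median-error assertions stable while
keeping the default run near a few seconds. Monte-Carlo cross-checks of
the coverage mathematics use 2×10^4^ seeded draws and a 3-SD band.
`scripts/acceptance.R` re-runs the full noise-free turbidimetric pipeline
for the three published parameter sets and one noisy melt recovery, taking
its single seed from the command line.

## Known limitations

* The turbidimetric model assumes monodisperse, non-sedimenting particles
  and ignores scattering physics; it is a kinetic summary, not an optical
  model.
* Two-state melts only; no reversibility check, scan-rate correction or
  unfolding thermodynamics.
* A240 quantification cannot speciate products; yields inherit the
  repeat-unit-mass convention.
* Pose competence is purely geometric; it does not score energetics or
  near-attack conformers beyond the distance rule.
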