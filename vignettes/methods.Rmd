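---
title: "Resolving conformational states from SAXS ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving conformational states from SAXS ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models each
stage implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.  It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The measurement model

A solution SAXS experiment records the azimuthally averaged intensity
I(q), q = 4π sin(θ)/λ, of a sample and of its matched buffer.  The net
macromolecular signal is

I_net(q) = I_sample(q) − t · I_buffer(q),

where t is close to, but not exactly, 1 because the sample attenuates
the beam slightly differently from the buffer.  `subtract_buffer()`
solves for t from the assumption that a dilute macromolecule contributes
less than the noise (|I/σ| < 1) somewhere within the high-q window
(default 0.1–0.7 Å⁻¹): t is initialized on the top of the window, points
with detectable coherent signal are excluded — both per point at 1σ and
via a 9-point running mean, which sees structure well below the
per-point noise — and t is re-solved on the signal-free set.  The
reported `window_residual_sigma` is the error-weighted mean net
intensity over that set, in σ units.  On the generator's default
conditions this recovers a planted t = 0.97 with ≈0.2% mean bias and
under 2% scatter per exposure (the oracle construction with signal
below 1% of buffer recovers it within 1%); both are computed in
`test-synthetic_data.R` and the acceptance script.

Frame averaging (`average_frames()`) compares each exposure with the
elementwise median curve by reduced χ², rejecting frames above the
upper-α χ² quantile (α = 0.01).  The median reference was chosen over a
leave-one-out mean because with few frames a single aberrant frame
contaminates every leave-one-out mean and all frames get rejected
(masking); the median is immune to a minority of bad frames.

Intensity calibration follows the known-MW protein-standard convention:
after `calibrate_intensity()`, the extrapolated I(0) reads as molecular
weight in Da.

## 2. Invariants

**Guinier.** ln I is fitted against q² by weighted least squares over a
window iterated so that qmax·Rg ≤ 1.3 (configurable).  On exact
Guinier-form input the fit is exact to machine precision.  On a hard
sphere the 1.3-window itself biases the apparent Rg upward by ~1.7%;
this is a property of the Guinier approximation, not of the
implementation, so sphere-oracle checks use a 2% band and the
cross-module consistency check (Guinier-of-Debye-curve against the model
geometry) uses a tighter window (qmax·Rg ≤ 0.8), where the truncation
bias falls below 0.5%.  `auto_range` trims a leading run of positive
residuals, the signature of aggregation upturns.

**P(r).** The pair-distance distribution solves the Tikhonov-regularized
weighted least squares through I(q) = 4π ∫ P(r) sinc(qr) dr, with
P(0) = P(Dmax) = 0 pinned, a second-difference smoothness penalty, and
α chosen at the L-curve corner when not supplied.  P(r) is not
constrained to be positive by default — negative excursions are
informative about mis-assigned Dmax and about flexibility — with an
optional iterated-truncation positivity mode.  When Dmax is unknown it
is scanned: the fit χ² drops steeply while the support is too small and
plateaus once the true support is covered, so the smallest Dmax
reaching the plateau (within 20% + 0.05 of the minimum χ²) is taken.
The grid is 201 r-points (101 during the scan).

**Molecular weight.** Three estimators are reported: calibrated I(0)
(Da); the Porod route Vp = 2π² I(0)/Q with Q = ∫q²I dq over
(0, 0.25 Å⁻¹], the integrand completed below qmin with the Guinier form
and corrected for a constant background fitted as I = K/q⁴ + B at high
q (for point-bead models that constant is exactly the self-scattering
plateau, which is why the correction matters), and MW = Vp/1.6 Da; and
the volume-of-correlation route Vc = I(0)/∫qI dq (integrated to the
protein-convention 0.3 Å⁻¹), QR = Vc²/Rg, MW = QR/0.1231.  The
constants are recorded in the output for auditability.  A caveat the
tests encode: the 0.1231 constant is an empirical calibration against
real protein scattering; on uniform-density toys (and even on an
analytic sphere) the absolute Vc mass reads 20–40% low, so toy-based
checks of that estimator are ratio-based (oligomer number), where the
constant cancels.

## 3. Scattering from coordinate models

Models are Cα-level beads with unit weights — justified because SAXS
cannot resolve the internal structure of a small domain, only its
occupied volume.  The Debye sum

I(q) = Σᵢⱼ wᵢwⱼ sinc(q·rᵢⱼ)

is evaluated exactly for small models and via a distance histogram
above 300 beads (bin width 0.5 Å).  Each bin carries its mass-weighted
mean distance and variance, and the in-bin spread enters through the
second-order term of the sinc Taylor expansion; this keeps the
histogram within 0.2% of the exact double loop (in practice ~0.01%).
An optional Gaussian bead form factor, I(q) × exp(−(q·σ_b)²), provides
the realistic high-q decay of finite-size residues; the analysis
convention is σ_b = 0 (point beads), while the synthetic-data generator
uses σ_b = 3 Å so that its simulated curves decay like real protein
data — without it, the point-bead self-term plateau leaves spurious
signal throughout the transmission window.  Pools fitted against
simulated data use the generator's σ_b for consistency.

`fit_scale()` solves scale and additive constant in closed form by
weighted least squares; the additive constant is fitted by default
(whether the original analyses did is unknowable from the published
record; the choice is recorded in every output).  The reduced χ² uses
n − 2 (or n − 1) degrees of freedom and calibrates to 1.0 ± 0.15 on
self-noise.

NSD superposition follows the standard definition — the symmetric mean
over both directions of nearest-neighbour squared distances, each
normalized by that model's mean nearest-neighbour spacing, square-rooted
— minimized over principal-axis alignments (all proper sign
combinations), the mirror image (scattering is inversion-blind), and a
local Nelder-Mead refinement.

## 4. Conformer pools and rigid-body fitting

Flexible segments are sampled as self-avoiding random walks with a
fixed Cα virtual bond of 3.8 Å and a 3.0 Å exclusion distance; bridging
segments are closed onto the far anchor by cyclic coordinate descent
(CCD), which preserves bond lengths exactly and converges to <0.5 Å
closure.  Walk statistics sit between the freely jointed chain and the
fully self-avoiding Flory limit (mean-square end-to-end distance
inflated above n·b² but below the n^(1/5) swelling), as expected for a
partially excluded chain; the exact inflation depends on the exclusion
radius and is checked as a band, not a point value.

`build_pool()` re-samples every flexible segment per member; mobile
blocks are re-attached at the walk end with a random orientation and
clash-checked.  Because only the flexible segments and their mobile
blocks move, the rigid-part pair histogram is computed once and each
member costs only the moving-internal and moving-versus-fixed pairs —
this is what makes pools of thousands of ~1000-bead members practical
in pure R.  Pools record per-member Rg and theory curves on a shared q
grid and are exactly reproducible under a seed.

`rigid_body_fit()` anneals over mobile-body poses (rotations ≤ 15°,
translations ≤ 5 Å, segment re-sampling) with geometric cooling,
scoring fit χ² plus clash and chain-continuity penalties; the
continuity check applies to the junction bonds at segment boundaries
(domain interiors are rigid bodies with no chain geometry at this
resolution).  P2 assemblies search the monomer pose against a fixed
two-fold axis and score the generated dimer, which is exactly symmetric
by construction.

## 5. Ensemble selection and state populations

The genetic algorithm selects a fixed-size multiset (default 20,
repeats allowed — the ensemble-optimization convention) from the pooled
members: fitness is the reduced χ² of the average member curve fitted
to the data; operators are elite carryover (10%), rank-weighted parent
selection, uniform crossover and per-gene mutation (rate 0.1) swapping
a member for a random draw.  Elitism makes the best-so-far fitness
non-increasing, and a fixed seed reproduces the full trajectory.  With
multiple pools of different oligomeric mass, member curves are first
normalized to I(0) ∝ mass (equal mass concentrations under the
calibrated-I(0) convention: an n-mer scatters n-fold per unit mass).

The selected-ensemble Rg histogram is decomposed into k = 1..3
Gaussians by Levenberg-Marquardt least squares with BIC model
selection; starting centers come from smoothed local maxima.  The
field's visual "flat-top" judgment is operationalized as an
equal-height, split-center double-Gaussian sub-fit: an adjacent pair
(or a single broad component) that the 4-parameter double Gaussian
describes with lower BIC is reported as one `double_gaussian` peak,
its FWHM measured numerically at half maximum of the summed pair.
Areas are integrated analytically and reported as percent fractions.

## 6. Shape reconstruction (deliberately light)

`reconstruct_shape()` is a single-phase dummy-bead annealer: beads on a
cubic lattice (spacing = bead diameter, default radius 3 Å) inside a
sphere of diameter Dmax are flipped to minimize fit χ² plus a
connectivity penalty (extra components) and a looseness penalty
(occupied beads with fewer than 3 occupied neighbours).  P2 runs flip
mirror pairs, so the output is exactly symmetric.  Intensities update
incrementally per flip.  This module is validated at shape level — Rg,
NSD to an ideal bead shape, principal-axis ratios — never at bead-level
identity with the reference reconstruction tools, which use finer
lattices and longer schedules.  `average_shapes()` aligns runs onto the
lowest-mean-NSD member (inversion-corrected), accumulates snapped
occupancies, keeps cells present in half the runs and trims to the
median run volume.

## 7. The synthetic-data generator

The generator is the package's stand-in for the study's raw data and
defines its study conditions:

* **Toy proteins.** Domains are compact random-growth globules at
  170 Å³/residue (≈1.55 Å³/Da) — the effective density protein SAXS
  reports via Porod volumes, chosen so the Porod MW chain is consistent
  on the toys; the growth spacing (≈4.55 Å) follows from that density.
  The default architecture mirrors a six-domain exchange factor
  (79/110/130/130/130/300 residues) with a 15-residue N-terminal tether
  and a ~5-residue hinge after the third domain.
* **Two states.** The closed conformer packs domains to minimize Rg;
  the extended conformer is the same assembly with the post-hinge block
  rotated about the hinge to a clash-free pose targeting ΔRg = 5.5 Å —
  the scale of a hinge-opening intermediate — and the hinge linker
  re-bridged.  The realized gap is 5.4–5.8 Å across seeds.
* **Mixtures and noise.** Curves are equal-mass-convention mixtures of
  component Debye curves (I(0) = component mass in Da), a smooth buffer
  b₀e^(−q/0.2) + b₁ scaled so signal/buffer ≈ 0.1 at q = 0.2 Å⁻¹
  (typical dilute protein on a lab camera), a planted transmission
  t = 0.97, and independent Gaussian counting noise
  σ(q) = √(I_total·exposure)/exposure on sample and buffer — giving
  I(0)/σ ≈ 300, so the true model fits its own data at χ² ≈ 1.
* **Scenarios.** `apo_two_state` (85/15 closed/extended),
  `dimer_equilibrium` (a contact P2 dimer of the extended conformer —
  axis placed along the thinnest principal direction at the smallest
  clash-free offset, giving a dimer/monomer Rg ratio ≈ 1.3 — with 10%
  compact monomer by mass), and `ternary` (the extended conformer
  docked with a 167-residue partner globule).

What the generator does **not** emulate: detector smearing,
inter-particle structure factors and crowding artifacts, solvation-layer
contrast (experimental Rg includes a hydration shell; model-to-data Rg
comparisons therefore carry ±2% slack), radiation damage, or atomic
surface detail (hence the Vc caveat of §2).  Passing tests demonstrate
that the algorithms recover what they claim under these conditions; on
real data the additional effects above add systematic error the tests
do not measure.

## 8. Problem sizes and determinism

The validation suite runs two-state recovery over 20 replicates against
pools of 2000 members per template (a scaled version of the classic
10,000-member pools; at these pool sizes the recovered fractions
stabilize well within the quantization of a 20-member ensemble).  Each
replicate averages three GA runs at the default 500 generations — the
repeated-runs convention — and assigns each selected member to a state
by Rg interval, with the boundary halfway between the two pool medians;
because the free-tether pools overlap in Rg, pool identity is not an
observable, but the Rg interval is.  The replicate-to-replicate scatter
of the recovered fraction at the study's noise level is about 7
percentage points (one sigma): the mean over 20 replicates recovers the
planted fraction to within ~2 points, while single unlucky noise draws
can deviate by ~15 points with the GA fully converged (identical chi2
across seeds) — an identifiability limit of the measurement, not an
optimizer failure.  Shape reconstructions use 3000–10,000 annealing
steps.  Every stochastic routine takes an explicit
seed; identical seeds reproduce identical pools, fits and reports.

## 9. Known limitations and open choices

* The hinge span of the emulated system is given inconsistently across
  the source record (348–352 / 348–351 / 347–353); the generator keys
  the hinge off its domain architecture rather than absolute residue
  numbers, and spans are configurable.
* The four-representative-hinge-angle device used in the original
  analyses is subsumed here by the single hinge-opened template whose
  NTD is re-sampled per member; a k-means sub-template selection was
  considered and dropped as adding a layer without changing what the
  recovery tests measure.
* Dmax scanning uses the χ²-plateau knee, not Bayesian evidence; the
  simpler scan is recorded in the report output.
* A published "negative Debye function" data-quality metric has no
  unambiguous definition in the available record and is not
  implemented; the unconstrained-P(r) convention it motivates is.
* GA hyperparameters of the original ensemble runs are unpublished;
  the defaults above follow the ensemble-optimization literature and
  are reported in every output (`ga_params`).
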