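# saxsens

Small-angle X-ray scattering (SAXS) measures the rotationally averaged
intensity I(q) of a macromolecule in solution.  For multi-domain proteins
with flexible linkers — exchange factors, kinases, scaffolds — a single
rigid model rarely explains the data: the molecule lives as an ensemble of
conformations, and the measurable signature of that ensemble is the shape
of its radius-of-gyration (Rg) distribution.  `saxsens` is an R package
plus analysis workflow for resolving such conformational states from 1D
SAXS curves, built around the study design used for the cAMP-regulated
exchange factor EPAC1: a compact autoinhibited state in equilibrium with a
hinge-extended intermediate, a ligand-induced dimer, and a rigid ternary
effector complex.

The workflow covers, end to end:

* **Reduction** — reading/writing 3-column `.dat` curves, frame averaging
  with median-based outlier rejection, buffer subtraction with a
  differential-transmission solve (the scale *t* on the buffer is fitted so
  that the net signal in the high-q window 0.1–0.7 Å⁻¹ is statistically
  zero), and calibration of I(0) to molecular weight in Da.
* **Model-free invariants** — iterative Guinier fit
  (ln I = ln I₀ − q²Rg²/3 with qmax·Rg ≤ 1.3), Tikhonov-regularized
  indirect Fourier transform for P(r) and Dmax (positivity optional, off
  by default), and three molecular-weight estimators: calibrated I(0),
  the Porod invariant (Vp = 2π²I₀/∫q²I dq, MW = Vp/1.6), and the
  volume of correlation (Vc = I₀/∫qI dq, QR = Vc²/Rg, MW = QR/0.1231).
* **Coordinate models** — Cα-bead models read from PDB (via `bio3d`),
  Debye-formula scattering I(q) = Σᵢⱼ wᵢwⱼ sin(qrᵢⱼ)/(qrᵢⱼ) with a
  histogram acceleration accurate to <0.2%, two-fold (P2) symmetry,
  and normalized-spatial-discrepancy (NSD) superposition with inversion
  correction.
* **Conformer pools and fitting** — self-avoiding linker sampling
  (tethered and CCD-closed bridging), pool generation from rigid
  templates with flexible segments, simulated-annealing rigid-body
  fitting, and a simplified dummy-bead shape reconstruction with
  multi-run NSD averaging.
* **Ensemble selection** — an EOM-style genetic algorithm that picks a
  sub-ensemble (default 20 members, repeats allowed) from one or more
  pools so that the mass-weighted average curve fits the data, followed
  by Gaussian decomposition of the selected Rg distribution into state
  populations (center, FWHM, % area; flat-top peaks reported as
  equal-height double Gaussians).
* **Synthetic data** — a generator of toy multi-domain proteins,
  two-state mixtures, monomer/dimer equilibria and noisy sample/buffer
  pairs with recorded ground truth, so every stage is testable without
  external downloads.

## Worked example

```r
library(saxsens)

# a two-state ground truth: 85% compact, 15% hinge-extended
truth <- make_scenario("apo_two_state", params = list(f = 0.85), seed = 7)
radius_of_gyration(truth$components$closed)    # 38.4 A
radius_of_gyration(truth$components$extended)  # 44.0 A

# simulate a sample/buffer pair and run the whole pipeline
report <- run_pipeline(list(
  seed = 5,
  scenario = list(name = "apo_two_state", params = list(f = 0.85)),
  ensemble = list(enabled = TRUE, n_members = 400, generations = 150)))
print(report)
```

```
== SAXS pipeline report ==
  data         ok
  subtract     ok
  invariants   ok
  ensemble     ok
Rg = 40.9 +/- 0.1 A | Dmax = 109 A | MW(Porod/Vc) = 142/105 kDa
Ensemble chi2 = 0.91
Rg peak decomposition:
  Rg 39.1 [5.8] {100%}  (gaussian)
```

The fitted buffer transmission (`report$subtracted$meta$transmission`,
0.963) recovers the planted 0.97 mismatch, the apparent Rg of 40.9 A
sits between the two planted conformers as a mixture should, and the
selected pool weights (`report$ensemble$fit$pool_weights`: 90% compact,
10% extended) recover the planted 85/15 split to within the
quantization of a single 20-member ensemble.  At this demonstration
scale (400-member pools, one GA run) the Gaussian decomposition of a
20-member histogram reports one broad state; the acceptance study below
— 2000-member pools, 20 replicates, three GA runs each — resolves the
two states and their centers to ~0.01 A.  All numbers are what the code
prints for these seeds; Rg values are properties of the generated toy
protein, not of any real molecule.

The numbered scripts under `analysis/` run the same study as a
sequence — simulate, invariants, shape reconstruction, ensemble
selection, report — writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_invariants.R
Rscript analysis/03_shape.R
Rscript analysis/04_ensemble.R
Rscript analysis/05_report.R
```

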