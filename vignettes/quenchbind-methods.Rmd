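---
title: "Methods: fluorescence-quenching binding analysis and structural descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence-quenching binding analysis and structural descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

# The problem

Human serum albumin (HSA) is the main small-molecule carrier of plasma. When
a ligand binds near Trp214 — the single tryptophan of HSA — the protein's
intrinsic fluorescence is quenched, and the dose dependence of that
quenching encodes the binding constant and stoichiometry. `quenchbind`
implements the complete quantitative chain of such a study: titration
spectra handling, inner-filter correction, the double-log binding fit,
synchronous-fluorescence and UV change statistics, site-marker competition,
and the structure-side descriptors (superposition RMSD, radius of gyration,
RMSF, torsion statistics, hydrogen-bond geometry, energy and
frontier-orbital ledgers) used to rationalise the binding. A seeded
synthetic-data module generates every input with known ground truth, so the
whole pipeline is verifiable end to end without instrument data.

# The binding model

The fluorescence read-out follows the double-logarithmic (Hill-type)
quenching equation

$$\lg\frac{F_0 - F}{F} = \lg K_a + n\,\lg [Q],$$

where $F_0$ and $F$ are the peak emission intensities before and after
ligand addition, $[Q]$ is the total added ligand concentration (mol/L), $K_a$
(L/mol) the binding constant and $n$ the number of binding sites. All
logarithms are base 10; $K_a = 10^{\text{intercept}}$, which is the
dimensionally consistent reading of the plotted equation. The fit is
ordinary least squares on the transformed points, unweighted, with $r^2$
reported. Three consequences shape the implementation:

* the ligand-free point ($[Q]=0$) cannot be transformed and is excluded;
* points with $F \ge F_0$ (no quenching) or $F \le 0$ are dropped with a
  logged count — the transform is undefined there;
* $[Q]$ is the *total* added concentration. No free-ligand correction is
  attempted, matching how such plots are constructed in practice.

The synthetic generator inverts the same equation,
$F([Q]) = F_0/(1 + K_a [Q]^n)$, so noiseless simulated titrations are
*exactly* log-linear and parameter recovery is an exact oracle: the fit
must return the planted $(K_a, n)$ to floating-point accuracy.

## Inner-filter correction

Measured fluorescence is attenuated by absorbance at the excitation and
emission wavelengths ($A_1$, $A_2$). The standard multiplicative correction

$$F_{cor} = F_{obs}\, e^{(A_1 + A_2)/2}$$

is applied per addition when absorbance pairs are attached to a series. The
generator applies the inverse attenuation, which makes the round trip an
identity to better than $10^{-12}$ relative — a property the tests enforce.

## Derived spectroscopic statistics

* $\Delta(\%) = (x - x_0)/x_0 \times 100$ for UV (hyperchromic, positive)
  and fluorescence (quenching, negative) endpoint changes.
* $R_{SFQ} = 1 - F/F_0$, the synchronous-quenching ratio at fixed
  $\Delta\lambda$ (15 nm probes tyrosine, 60 nm tryptophan environments).
* Displacement $= 100\cdot F_2/F_1$ against the marker:protein ratio, with
  warfarin marking Sudlow site I and ibuprofen Sudlow site II. The site
  label uses a 10% endpoint-drop threshold: published competition data are
  reported only qualitatively ("decrease" vs "no significant change"), and
  10% separates clear competition from flat curves without reacting to
  noise-level wiggle.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `protein_conc` | 10.8e-6 | mol/L | typical HSA working concentration for these titrations |
| `molar_ratios` | 0, 0.74, 1.48, 2.22, 2.96, 3.7 | — | the five-aliquot addition grid used in the emulated experiment |
| `band_center`, `band_sigma` (emission) | 340, 25 | nm | Trp emission peak position; width chosen as a realistic single-band envelope |
| UV band | 278, 12 | nm | aromatic protein absorption peak |
| synchronous bands | 340 ($\Delta\lambda$=60), 300 ($\Delta\lambda$=15) | nm | Trp / Tyr windows |
| `peak_window` (quenching) | 320–360 | nm | brackets the Trp peak; the result is insensitive to the exact bounds |
| `d_xy_max`, `angle_min` (H-bonds) | 3.5 Å, 110° | | inclusive cutoffs: docking-derived bonds are reported with X–H···Y angles down to ~117°, below the classical 120° |
| `threshold` (site assignment) | 10 | % | see above |

The wavelength grids use a 1.0 nm scanning interval, the interval stated for
the emulated UV scans and a common emission-scan setting.

# The synthetic-data module

Generators are pure functions of (config, seed): identical inputs give
bit-identical outputs, and the caller's RNG state is restored. What they
emulate, and what they do not:

* **Emission titrations** — exact binding-model peaks under a Gaussian band,
  optional inner-filter attenuation, optional multiplicative i.i.d. Gaussian
  noise per wavelength. Real spectra have correlated noise, baseline drift,
  Raman/scatter bands and asymmetric envelopes; none are modelled, so
  passing tests demonstrate correctness of the *analysis chain*, not
  robustness to every instrument artefact.
* **Synchronous / UV series** — constructed so the *endpoint* statistic
  (RSFQ, $\Delta\%$) equals a requested value exactly, with intermediate
  additions following the saturable binding model (synchronous) or a linear
  ramp in addition index (UV, where only the endpoint and a linear blue
  shift are specified). These series validate the read-out pipeline; they
  do not model band-shape changes on complexation.
* **Competition** — $F_2 = F_1(1 - d_{max}\, r/(r + r_{1/2}))$, a saturable
  single-site displacement. The functional form is a modelling choice (no
  published form exists for these curves); it reproduces the two observed
  regimes: a monotone decrease (warfarin-like) and a flat 100% curve
  (ibuprofen-like).
* **Toy trajectories** — a jittered atom cloud plus an explicit three-atom
  subunit whose angle follows `center + amplitude*sin(2*pi*t/period)`
  exactly (the default period of 20 frames makes integer frame times hit the
  extremes exactly, so planted widths are exact), planted hydrogen-bond
  triples realised at their requested geometry, and optional rigid drift.
  These are geometric fixtures, not physical dynamics.

# Structural descriptors

* **Kabsch superposition** is implemented from the SVD of the weighted
  cross-covariance matrix with the determinant sign correction (proper
  rotations only). Tests check rigid-transform invariance at $10^{-9}$ Å and
  equivalence with two independent routes: a grid-plus-refine rotation
  search and the `bio3d` fitting routine.
* **Radius of gyration** uses the standard mass-weighted RMS distance from
  the centre of mass. Descriptions of Rg as "the maximum distance of atoms
  from the centroid" circulate in the applied literature; since the tools
  those analyses cite compute the RMS definition, that is the default here,
  and `rg_def = "max"` provides the literal maximum for comparison.
* **RMSF** is the per-atom RMS deviation from the time-mean position, after
  optional per-frame Kabsch alignment to frame 1 (default), so rigid-body
  motion does not register as flexibility.
* **Torsion statistics**: per-angle range and width on raw values in
  [0°, 180°] (no circular wrapping — the ranges of bound small molecules are
  narrow), and the per-molecule mean width rounded half-away-from-zero to
  integer degrees, the convention that reproduces published "average
  variation" values (mean of {22°, 16°, 20°} → 19°).
* **Hydrogen bonds**: geometry (d(X–H), d(H···Y), d(X···Y), ∠XHY) from one
  coordinate set, which satisfies the law of cosines to $10^{-6}$ Å² by
  construction. Published hydrogen-bond tables from docking software do not
  always satisfy that identity (their distance conventions vary), so such
  tables are treated as inputs, never as geometric oracles.
* **Energy/orbital ledgers**: $E_{binding} = E_{complex} - E_{ligand} -
  E_{receptor}$ (kJ/mol); interaction dominance is the algebraically lower
  of the electrostatic and van der Waals components; $\Delta E_{L-H} =
  E_{LUMO} - E_{HOMO}$ in atomic units (Hartree) per molecule.

# Numerical choices and degenerate inputs

* Peak location ties break toward the smaller wavelength; peak detection is
  invariant under positive intensity rescaling and rigid grid shifts.
* Negative intensities are rejected, not clipped — they indicate instrument
  or parsing faults that should surface, not be hidden.
* Wavelength grids must match exactly across a series; no resampling.
* CSV round trips write numbers with `%.17g`, which is lossless for
  doubles (round trip well below $10^{-12}$ relative).
* `fit_double_log` computes $r^2$ directly from residuals (perfect fits are
  the *expected* case on noiseless data and should not warn).
* Degenerate fits (fewer than 2 usable points, all $F = F_0$) raise
  estimation errors with explicit messages.
* Unknown elements get mass 12.0 amu with a warning; alternate PDB
  locations other than '' or 'A' are skipped.

# Problem sizes

The test suite and the acceptance script run entirely on generated data:
6-addition titrations on 201-point grids, 200-replicate noise studies,
trajectories of 2–50 frames with ≤ 30 atoms, and 1000-triple angle-oracle
sweeps. The full suite completes in well under a minute on one CPU.

# Known limitations

* **The double-log intercept is a long extrapolation.** At micromolar
  ligand concentrations $\lg[Q] \approx -5$, so the intercept (and hence
  $K_a = 10^{\text{intercept}}$) is read ~4.7 decades outside the sampled
  range, amplifying intensity noise roughly twenty-fold. With 1%
  multiplicative spectral noise the median relative error of the recovered
  $K_a$ across 200 seeded replicates is about 6% (CA parameters) and about
  12% (FA parameters) — while $n$, which is the slope, is recovered to
  ~0.7%. This is an intrinsic property of double-log fits at these
  concentrations, worth keeping in mind when comparing published $K_a$
  values: the package reports the realised error honestly rather than
  presenting $K_a$ as noise-robust.
* Each spectroscopic analysis is treated as self-consistent; the package
  does not force agreement between, e.g., fitted $K_a$ values and endpoint
  $\Delta\%$ statistics, which are hard to reconcile quantitatively at the
  stated concentrations.
* No Stern–Volmer temperature analysis, van't Hoff thermodynamics, FRET
  distances, CD deconvolution, docking, force-field evaluation or electronic
  structure — the package analyses the outputs of such computations, it does
  not perform them.
* Mixture (1:1) analyses are limited to $\Delta\%$ and RSFQ summaries; no
  $K_a/n$ is defined for a two-component quencher in this model.
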