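# quenchbind

Quantitative analysis of small-molecule binding to serum albumin from
fluorescence titrations, with companion structure-side descriptors.

When a ligand binds human serum albumin (HSA) near its single tryptophan
(Trp214), the protein's intrinsic fluorescence is quenched. `quenchbind`
turns titration spectra into binding parameters and supports the structural
interpretation of the result. It is written for spectroscopists and
modellers who run ligand–albumin interaction studies and want the whole
number chain — from raw scans to the reported constants — reproducible and
testable.

## What it computes

**Spectroscopy side**

- Inner-filter correction: `F_cor = F_obs · e^((A1 + A2)/2)`, with `A1`,
  `A2` the absorbances at the excitation and emission wavelengths.
- The double-log (Hill-type) quenching fit

  ```
  lg((F0 − F)/F) = lg Ka + n · lg[Q]
  ```

  by ordinary least squares: slope = binding-site number `n`, intercept =
  `lg Ka` (so `Ka = 10^intercept`, L/mol), with `r²`, per-point residuals
  and dropped-point accounting.
- Signed percent changes `Δ(%) = (x − x0)/x0 × 100` for UV hyperchromicity
  and fluorescence quenching endpoints.
- Synchronous-fluorescence quenching ratios `RSFQ = 1 − F/F0` at fixed
  Δλ (15 nm: tyrosine; 60 nm: tryptophan).
- Site-marker competition curves `100 · F2/F1` vs the marker:protein ratio
  and a Sudlow site I/II assignment (warfarin vs ibuprofen markers).

**Structure side**

- Kabsch optimal-superposition RMSD, per-frame RMSD series, mass-weighted
  radius of gyration, per-atom RMSF (with optional alignment), rotatable
  three-atom angle time series with range/width statistics, and
  hydrogen-bond geometry/scanning with distance and angle cutoffs.
- Energy ledgers `E_binding = E_complex − E_ligand − E_receptor` (kJ/mol),
  electrostatic-vs-van-der-Waals dominance, and frontier-orbital gaps
  `ΔE_L-H = E_LUMO − E_HOMO` (a.u.).

**Synthetic data with known truth**

Every input the pipeline consumes can be generated with planted ground
truth: emission/synchronous/UV titrations from the inverted binding model
`F = F0/(1 + Ka·[Q]^n)`, competition series, and toy structures or
trajectories with exactly realised torsion oscillations and hydrogen-bond
geometry. Noiseless recovery is exact by construction, which the test suite
uses as an oracle.

## Worked example

```r
library(quenchbind)

# simulate a six-addition titration at the published CA parameters
cfg <- titration_config(ka = 4.15e4, n = 0.91)   # protein 10.8 umol/L
series <- simulate_titration(cfg)
series
#> <titration_series> emission, 6 additions, ratios 0, 0.74, 1.48, 2.22, 2.96, 3.7, [P]=1.08e-05 mol/L

pts <- quench_points(series, peak_window = c(320, 360))
pts
#>            Q   F0        F
#> 1 7.9920e-06 1000 511.8189
#> 2 1.5984e-05 1000 358.1324
#> 3 2.3976e-05 1000 278.3918
#> 4 3.1968e-05 1000 228.9511
#> 5 3.9960e-05 1000 195.0846

fit_double_log(pts)
#> <binding_fit> Ka = 4.15e+04 L/mol, n = 0.910, r^2 = 1.00000 (5 points, 0 dropped)
```

The five transformed points lie exactly on a line (the generative model is
log-linear), and the fit returns the planted binding constant
`Ka = 4.15e4 L/mol` and site number `n = 0.91`: one ligand per binding site,
association in the 1e4 L/mol range typical of phenolic acids on albumin.
`demo_report(seed = 1)` reruns the entire chain (binding recovery, noise
robustness, RSFQ/UV endpoints, competition, torsion statistics, dominance
labels, orbital gaps) and prints a one-screen summary.

A thin command-line wrapper over the same functions ships in
`inst/cli/quenchbind.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","quenchbind.R",package="quenchbind"))')" \
  simulate --ka 41500 --n 0.91 --out titration.csv
```

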