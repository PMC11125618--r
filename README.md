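# specbind

Spectroscopic analysis of protein–ligand binding in R.

`specbind` is for researchers who characterise how a small molecule (a
pollutant, a drug candidate, a cofactor) binds a protein using steady-state
spectroscopy: fluorescence quenching titrations, UV–Vis absorption, FTIR,
and three-dimensional (excitation–emission) fluorescence. It turns the raw
curves into the constants such studies report — quenching and binding
constants, Förster distances, binding thermodynamics, ligand efficiency,
and secondary-structure composition — with every step testable against
synthetic data of known ground truth.

## The models

**Fluorescence quenching.** A titration of protein fluorescence *F*
against quencher concentration [*Q*] is fit two ways:

- Stern–Volmer: *F*₀/*F* = 1 + *K*~SV~[*Q*] = 1 + *K*~q~τ₀[*Q*]. The slope
  gives *K*~SV~; with the unquenched lifetime τ₀ (≈ 10⁻⁸ s for intrinsic
  protein fluorescence) the bimolecular rate constant *K*~q~ = *K*~SV~/τ₀
  follows. *K*~q~ strictly above the diffusion-limited 2 × 10¹⁰
  L·mol⁻¹·s⁻¹ diagnoses **static quenching** (ground-state complex).
- Double-logarithm: log[(*F*₀ − *F*)/*F*] = log *K*~a~ + *n* log[*Q*],
  giving the apparent binding constant *K*~a~ and binding-site number *n*.

**FRET distance.** From the donor emission spectrum *F*(λ) and the
acceptor molar absorptivity ε(λ) (via Beer–Lambert from an absorbance
spectrum), the overlap integral

J = Σ *F*(λ) ε(λ) λ⁴ Δλ / Σ *F*(λ) Δλ  (λ in cm)

feeds the Förster radius *R*₀⁶ = 8.8 × 10⁻²⁵ *K*² *N*⁻⁴ Φ *J* (cm⁶), and
the transfer efficiency *E* = 1 − *F*/*F*₀ = *R*₀⁶/(*R*₀⁶ + *r*⁶) yields
the donor–acceptor distance *r*. Energy transfer is considered established
when 0.5 *R*₀ ≤ *r* ≤ 1.5 *R*₀ and *r* < 7 nm.

**Thermodynamics.** Van't Hoff analysis of *K*~a~(T) gives Δ*H* (slope of
ln *K*~a~ vs 1/*T*) and Δ*S* (intercept); Δ*G* = −*RT* ln *K*~a~ =
Δ*H* − *T*Δ*S*. The sign pattern of (Δ*H*, Δ*S*) classifies the dominant
force: (+, +) hydrophobic; (−, −) hydrogen bonds / van der Waals; (−, +)
electrostatic. Ligand efficiency from docking is LE = |Δ*G*~binding~| /
*N*~heavy~.

**FTIR secondary structure.** The amide-I region (1600–1700 cm⁻¹) is
baseline-corrected and deconvolved into Gaussian bands; band centres map
to structure classes (1610–1640 β-sheet, 1640–1650 random coil, 1650–1660
α-helix, 1660–1680 β-turn, 1680–1692 antiparallel β-sheet) and band areas
to percentages.

**EEM analysis.** Rayleigh scatter ridges (emission = excitation and
emission = 2 × excitation) are masked; fluorescence peaks are located and
compared between a free-protein and a ligand-treated EEM to quantify
intensity changes and blue/red shifts.

## Worked example

```r
library(specbind)

# a synthetic titration with known ground truth (Ka = 2e6, n = 1, 1% noise)
ts <- genTitration(Ka = 2e6, n = 1, noiseFraction = 0.01, seed = 7)
quenchingAnalysis(ts)
#> Quenching analysis
#>   Ksv = 2.002e+06 L/mol (intercept 1.002, R^2 = 0.9993)
#>   Kq  = 2.002e+14 L/mol/s (tau0 = 1e-08 s) -> static quenching
#>   Ka  = 3.651e+06 L/mol, n = 1.041 (R^2 = 0.9964)

# FRET from overlapping synthetic emission/absorption bands
sp <- genOpticalSpectra(noiseFraction = 0)
fretAnalysis(sp$emission, sp$absorption, F = 870, F0 = 1000)
#> Forster energy transfer
#>   J  = 6.773e-14 cm^3 L / mol
#>   R0 = 3.503 nm (K^2 = 0.6667, N = 1.34, Phi = 0.15)
#>   E  = 0.130, r = 4.809 nm
#>   energy-transfer conditions satisfied

# van't Hoff thermodynamics from binding constants at three temperatures
vantHoffAnalysis(Ka = c(1.6e6, 1.9e6, 2.2e6), temperatures = c(293, 298, 303))
#> Thermodynamics of binding
#>   dH = 23.51 kJ/mol, dS = 199 J/mol/K -> hydrophobic
#>   dG(293 K) = -34.81 kJ/mol
#>   dG(298 K) = -35.8 kJ/mol
#>   dG(303 K) = -36.8 kJ/mol

# ligand efficiency from a docking binding energy
ligandRecord("PFBS", "C4F9O3S", -5.196)
#>   name formula binding_energy_kcal n_heavy        LE
#> 1 PFBS C4F9O3S              -5.196      17 0.3056471

# amide-I deconvolution of a five-band synthetic composite
comp <- genAmideComposite(fractions = c(0.2, 0.15, 0.3, 0.2, 0.15),
                          noiseFraction = 0.005, seed = 2)
ftirSecondaryStructure(comp)
#> Secondary structure (amide-I deconvolution)
#>   beta_sheet         20.01 %
#>   random_coil        15.08 %
#>   alpha_helix        29.94 %
#>   beta_turn          19.98 %
#>   beta_antiparallel  14.99 %
```

Reading the quenching block: *K*~q~ ≈ 2 × 10¹⁴ L·mol⁻¹·s⁻¹ is four orders
of magnitude above the diffusion limit, so the quenching is static; the
fitted *K*~a~ of order 10⁶ L·mol⁻¹ indicates strong binding at a single
site (*n* ≈ 1). The FRET block shows *r* = 4.81 nm, inside
[0.5 *R*₀, 1.5 *R*₀] and below 7 nm, so non-radiative energy transfer
contributes to the quenching. Positive Δ*H* and Δ*S* classify the binding
as hydrophobically driven. A whole study (any subset of stages per
ligand) can be run from a YAML configuration with `runFullStudy()` and
exported with `writeStudyReport()`.

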