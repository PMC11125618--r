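---
title: "Methods: spectroscopic analysis of protein–ligand binding"
author: "specbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectroscopic analysis of protein-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

`specbind` implements the analysis chain used in steady-state
spectroscopic binding studies: fluorescence quenching titrations are fit
for quenching and binding constants, donor–acceptor distances are derived
from spectral overlap, temperature series of binding constants yield the
thermodynamic signature of the interaction, FTIR amide-I spectra are
deconvolved into secondary-structure fractions, and excitation–emission
matrices (EEMs) are compared before and after ligand exposure. This
vignette is the package's account of the underlying models, the choices
made where the method literature leaves room, and the limits of what the
test suite demonstrates.

## Quenching analysis

The Stern–Volmer model, $F_0/F = 1 + K_\mathrm{SV}[Q] = 1 +
K_q\tau_0[Q]$, is fit by ordinary least squares of the intensity ratio on
quencher concentration. Two deliberate departures from a textbook fit:

- **The intercept is left free.** Theory fixes it at 1; constraining it
  would hide instrument drift or dilution errors. A fitted intercept more
  than 5 % from 1 is flagged in the result's notes.
- **A perfectly flat ratio returns $K_\mathrm{SV} = 0$ exactly** rather
  than the least-squares slope's floating-point dust. No quenching is a
  legitimate outcome, not an error.

The lifetime default $\tau_0 = 10^{-8}$ s is the conventional magnitude
for intrinsic (tryptophan) protein fluorescence and is overridable
everywhere it enters. The mechanism call is a strict comparison:
$K_q > 2\times10^{10}$ L·mol⁻¹·s⁻¹ — above the diffusion-controlled
collisional limit — is classified static, the boundary value itself
dynamic.

The double-logarithm binding model, $\log_{10}[(F_0-F)/F] = \log_{10}
K_a + n\log_{10}[Q]$, uses base-10 logarithms with $K_a =
10^{\mathrm{intercept}}$; this is the convention under which binding
constants of order $10^6$ are read directly off the intercept. Points
with $F \ge F_0$ at nonzero $[Q]$ make the logarithm undefined; they are
**dropped with a warning, never clamped**, because clamping to a small
positive value would bias the slope. At least three usable points are
required.

A caveat worth stating plainly: $\log_{10}[Q]$ for a titration in the
$10^{-7}$ M range sits near $-7$ to $-6$, so the intercept at
$\log_{10}[Q]=0$ is an extrapolation of more than six decades. Small
intensity errors therefore translate into large relative errors in
$K_a$ — a property of the double-logarithm method itself, not of this
implementation. Error analysis: the intercept's noise amplification
factor is $|\bar x|/\sqrt{S_{xx}} \approx 7$ for a ten-step titration of
this design, and the per-point noise in the log-ratio is itself amplified
by $(1+K_a[Q])/(K_a[Q])$ at low concentrations. With 1 % multiplicative
intensity noise the median relative error of $K_a$ across replicates is
of order 20 %, as the test suite's recovery property measures. Exact
(noiseless) inversion is recovered to better than $10^{-6}$. The fitted
$n$ and $K_\mathrm{SV}$, which depend on slopes rather than extrapolated
intercepts, are far less sensitive.

## FRET distances

The overlap integral is evaluated as
$J = \sum F(\lambda)\,\varepsilon(\lambda)\,\lambda^4\,\Delta\lambda /
\sum F(\lambda)\,\Delta\lambda$, with both curves linearly interpolated
onto a **shared 1 nm grid** over their common wavelength support and
summed with trapezoidal weights — the discrete-sum form in which the
quantity is conventionally written. Two unit conventions matter:

- $\lambda$ enters **in cm**. Only under this convention does the
  $8.8\times10^{-25}$ prefactor of $R_0^6 = 8.8\times10^{-25} K^2 N^{-4}
  \Phi J$ map an overlap integral of $6.70\times10^{-14}$ cm³·L·mol⁻¹
  onto the reference Förster radius of 3.50 nm; this was verified
  analytically before fixing the convention.
- $\varepsilon(\lambda)$ is computed from measured absorbance via
  Beer–Lambert, $\varepsilon = A/(c\,l)$, with user-supplied
  concentration and path length (default 1 cm), since instruments export
  absorbance, not absorptivity.

Defaults $K^2 = 2/3$ (freely rotating dipoles), $N = 1.34$ (aqueous
biomolecular medium) and $\Phi = 0.15$ (intrinsic protein fluorescence)
are all approximate literature values and all overridable. $E$ should be
taken at a 1:1 donor:acceptor molar ratio; only intensities enter the
code, so this is a documentation contract, not an enforced check.

Degenerate inputs are handled explicitly: disjoint spectra give $J = 0$
with a warning (no overlap is informative, not an error); zero total
emission over the overlap is an error; $E = 0$ implies infinite distance
(error); $E = 1$ returns $r = 0$ with a warning. The validity verdict —
$0.5R_0 \le r \le 1.5R_0$ and $r < 7$ nm — reports every violated
condition, not just a boolean.

The 1 nm grid was validated against a 0.01 nm brute-force quadrature on
randomly drawn Gaussian band pairs; the test suite requires agreement
within 0.1 %.

## Thermodynamics and ligand efficiency

With two temperatures, $\Delta H$ comes from the two-point van't Hoff
relation; with more, from the slope of an ordinary least-squares fit of
$\ln K_a$ on $1/T$ (which reduces to the two-point formula at $n=2$).
$\Delta S$ is taken from the same fit's intercept, and stored
$\Delta G(T)$ values are computed as $\Delta H - T\Delta S$ so that the
Gibbs identity holds exactly in every result object; $\Delta G$ from
$-RT\ln K_a$ is a separate function. Units follow reporting convention:
$\Delta H$, $\Delta G$ in kJ·mol⁻¹, $\Delta S$ in J·mol⁻¹·K⁻¹,
$R = 8.314$ J·mol⁻¹·K⁻¹.

The force classification is the standard sign-pattern rule: $(+,+)$
hydrophobic, $(-,-)$ hydrogen bond / van der Waals, $(-,+)$
electrostatic. The fourth pattern $(+,-)$ has no conventional assignment
and is reported `unclassified`, as are values within $10^{-9}$ of zero
(with a warning) — a deliberate refusal to over-interpret noise-level
thermodynamics.

Ligand efficiency is $|\Delta G_\mathrm{binding}|/N_\mathrm{heavy}$,
reported as a positive magnitude. The formula parser counts non-hydrogen
atoms in a Hill-style formula; for salts the caller must supply the
anion formula, since a counter-ion would inflate the heavy-atom count.

## Amide-I deconvolution

The pipeline is: restrict to 1600–1700 cm⁻¹; subtract the straight line
through the window endpoints (clipping small negative residues, warning
if more than 2 % of the maximum is clipped — a sign of baseline
curvature); detect candidate bands; fit a sum of Gaussians; assign and
integrate.

**Band shape.** Gaussian, the standard choice for amide-I curve fitting;
Voigt or Lorentzian shapes add parameters the data here cannot
discriminate.

**Detection.** Candidates are negative local minima of a Savitzky–Golay
smoothed second derivative (9-point window, order 3, on a uniform
1 cm⁻¹ grid) whose absorbance is at least 1 % of the window maximum — a
Gaussian's second derivative has its minimum exactly at the band centre.
At most eight (the deepest) candidates are kept.

**Fitting.** Bounded Levenberg–Marquardt least squares: centres within
±8 cm⁻¹ of their guesses and inside the window, sigmas in [2, 25] cm⁻¹,
amplitudes non-negative. Three deterministic starts (initial sigma 6, 4,
10 cm⁻¹) are run and the lowest-deviance solution kept: overlapped band
mixtures possess local optima in which one band saturates the width
bound and soaks up several classes' area, and a single start falls into
them often enough to matter.

**Refinement.** Strongly overlapped shoulder bands — a weak band 10 cm⁻¹
from a strong neighbour — can be provably invisible in the smoothed
second derivative (the minima merge). The end-to-end pipeline therefore
inspects the fit residual: while its maximum exceeds 2 % of the window
maximum and lies at least 3 cm⁻¹ from every fitted centre, a band is
added there and the mixture refitted, up to eight bands. The loop is
deterministic. Explicit Fourier self-deconvolution preprocessing is not
performed; detection-plus-residual-refinement fills the same role with
fewer tuning parameters.

**Assignment.** The class windows share endpoints, so a convention is
required: windows are half-open with the boundary going to the
higher-wavenumber class (1640 → coil, 1650 → helix, 1660 → turn, 1680 →
antiparallel; 1692 stays antiparallel). The margins 1600–1610 and
1692–1700 cm⁻¹ carry no established assignment and are excluded from the
percentage base rather than merged into a neighbouring class.
Percentages are band areas ($A\sigma\sqrt{2\pi}$) over the assigned
total, and always sum to 100.

## EEM analysis

First-order Rayleigh scatter lies where emission equals excitation,
second-order where emission is twice the excitation. Both ridges are
masked within a configurable half-width, default 15 nm — three grid
steps at the conventional 5 nm scan increment; the method literature
does not fix this number, so it is exposed as a parameter. Masking is
idempotent and OR-accumulates onto any existing mask.

Peaks are strict 8-neighbour local maxima over unmasked cells. Plateaus
(equal-valued adjacent candidates) collapse to their lexicographically
smallest (excitation, emission) cell so output is deterministic.
Candidates below 5 % of the matrix maximum are discarded: the tail of an
imperfectly masked Gaussian ridge otherwise always produces a spurious
plateau maximum along the mask border. The floor is relative, so peak
positions are invariant under uniform intensity scaling. Sub-grid peak
interpolation is not attempted — reported shifts of a few nm are
meaningful only at or above the grid resolution, and a 1 nm acquisition
grid resolves a 3 nm shift exactly, as the tests demonstrate.

Peak matching between a reference and a treated EEM is nearest-neighbour
in the (excitation, emission) plane with a 20 nm matching radius;
unmatched peaks are flagged, not fatal. Negative emission shifts are
blue shifts (reduced solvent exposure of the fluorophores); intensity
ratios are treated/reference.

## Synthetic data: what it does and does not emulate

Every input class has a generator that is a deterministic function of
its arguments, seed included, with multiplicative Gaussian noise
(photodetector noise scales with signal; default fraction 0.01):

- `genTitration()` uses the forward model $F = F_0/(1 + K_a[Q]^n)$ — the
  exact inverse of the double-logarithm model, so the fit target is
  well-specified. Defaults ($K_a = 2\times10^6$, $n = 1$, ten
  concentrations 0–9 × 10⁻⁷ M) represent a strong binder titrated at
  sub-micromolar levels. Noise spares the $F_0$ reference.
- `genOpticalSpectra()` produces a Gaussian emission band peaking at
  340 nm (tryptophan-like) and a Gaussian absorption band on 300–450 nm.
  The default amplitudes were calibrated once against fine-grid
  quadrature so the default pair's overlap integral lands near
  $6.7\times10^{-14}$ cm³·L·mol⁻¹, i.e. a Förster radius near 3.5 nm.
- `genAmideComposite()` sums one Gaussian per structure class at
  canonical centres (1628, 1645, 1655, 1671, 1686 cm⁻¹) with areas
  proportional to the requested fractions, plus a linear baseline.
  Component sigma defaults to 4 cm⁻¹ (FWHM ≈ 9.4 cm⁻¹), representing
  well-resolved component bands; neither the amide-I literature's wider
  envelope widths nor instrument broadening are modelled.
- `genEEM()` sums 2-D Gaussian blobs (defaults at the two conventional
  protein peaks) and a first-order Rayleigh ridge on a 200–450 nm, 5 nm
  grid.

What passing tests on these generators demonstrates: the estimators
invert their own forward models exactly in the noiseless limit, degrade
gracefully and measurably under realistic noise, and agree with
independent brute-force oracles where one exists. What they do not
demonstrate: robustness to the features of real instrument data that
the generators deliberately omit — inner-filter effects, wavelength-
dependent detector response, scattering backgrounds other than Rayleigh,
curved FTIR baselines, correlated noise, and Lorentzian band character.
Results on real spectra inherit those caveats.

Test problem sizes are the generators' defaults: ten-point titrations
(100 noisy replicates in the recovery property), 151-point optical
spectra with 20 random pairs against the quadrature oracle, 141-point
FTIR composites (50 replicates), and 51 × 51 EEMs (251 × 251 for the
sub-grid shift construction).

## Full-study runner

`runFullStudy()` executes, per configured ligand, whichever stages have
inputs: quenching per temperature, van't Hoff thermodynamics when at
least two temperatures are present, FRET, ligand efficiency, FTIR, and
EEM comparison. Absent inputs skip a stage with a notice; a failing
stage is recorded as an error annotation in the report (and raised as a
warning) so a partial report always exists. All physical constants
(τ₀, K², N, Φ, the scatter half-width) are overridable in the
configuration, because every one of them is an "approximately" from the
method literature. The JSON report contains full-precision numbers and
no timestamps, so identical configuration and inputs give byte-identical
reports; `readStudyReport()` re-parses them losslessly.

## Known limitations

- No combined dynamic-plus-static (sphere-of-action) quenching model,
  and no global fit across temperatures.
- The double-logarithm $K_a$ is intrinsically extrapolation-sensitive
  (see above); confidence intervals are not yet propagated.
- No orientation-factor estimation beyond fixed $K^2$; no
  lifetime-based FRET.
- Enthalpy from van't Hoff assumes $\Delta H$ constant over the
  (narrow) temperature range.
- FTIR band assignment is purely centre-based; bands straddling a
  window boundary contribute all of their area to one class.
- No PARAFAC or other multi-way EEM decomposition, and no Raman scatter
  modelling.
- File readers cover delimited text only; binary instrument formats are
  out of scope.
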