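---
title: "Models and methods for ligand-protein binding spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for ligand-protein binding spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

`quenchbind` analyzes the spectroscopic workup of a small molecule
binding a fluorescent transport protein such as serum albumin. This
vignette documents the models, the assumptions they make, the tunable
parameters and their defaults, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the standard
methods leave room.

## Quench titrations

A titration fixes the protein concentration (3 µM in the default
design), steps the total ligand concentration (0–22.5 µM in 1.5 µM
increments), and records an emission spectrum per point (excitation
280 nm, emission 300–380 nm for a Trp-containing protein).

**Inner-filter correction.** A ligand absorbing at the excitation or
emission wavelength attenuates the measured signal by roughly half its
absorbance on each leg of the light path, so
`inner_filter_correct()` applies
\(F_{cor} = F_{obs}\,10^{(A_{ex}+A_{em})/2}\), with \(A_{ex}\),
\(A_{em}\) the *increments* in absorbance caused by the added ligand.
Two conventions are exposed: when only reference-wavelength intensities
are analyzed (`titration_intensities()`), \(A_{em}\) is the increment at
that single wavelength; `inner_filter_correct_spectrum()` corrects a
full spectrum with \(A_{em}(\lambda)\) interpolated per emission
wavelength. The correction assumes a 1 cm path and uniform absorber —
adequate for dilute cuvette work, wrong for front-face geometries.

**Stern-Volmer analysis.** `stern_volmer()` fits
\(F_0/F = 1 + K_{SV}[Q]\) by ordinary least squares. Quench plots of
albumin typically curve upward at high quencher concentration (a
combined static/dynamic regime), so only the linear prefix is fitted.
The selection rule — the package's own operationalization, since the
underlying method statements say only that linear zones were used — is:
take the largest prefix starting at \([Q]=0\) with \(r^2 \ge\) `r2_min`
(default 0.995) whose residuals, where they exceed numerical noise, form
more than three sign runs when at least six points are fitted (a convex
contaminated prefix produces the `+ − +` three-run pattern). The rule is
deterministic; if no prefix of three points qualifies, the full range is
used with a warning. The intercept is reported but not constrained to 1;
a deviation beyond 5 % warns, since it usually signals a miscorrected
inner filter or a wrong \(F_0\).

The bimolecular quenching constant \(k_q = K_{SV}/\tau_0\) uses the
unquenched lifetime `tau0` (default in the pipeline: 6.38 ns, the
conventional single-exponential value for albumin's Trp-214).
`classify_quenching()` labels the mechanism from the temperature trend
of \(K_{SV}\): strictly decreasing → static (complexes dissociate on
heating), strictly increasing → dynamic (diffusion accelerates),
anything else → ambiguous; it also reports whether the smallest
\(k_q\) exceeds the diffusion-controlled limit (default
\(10^{10}\,\mathrm{M^{-1}s^{-1}}\)), which no collisional mechanism can
beat.

## The binding isotherm

`binding_isotherm()` implements the double-logarithmic model with
mass-balance correction of the free ligand:

\[
\log_{10}\frac{F_0-F}{F} \;=\; n\,\log_{10}K_a \;+\;
n\,\log_{10}\!\Big([D_T] - \frac{F_0-F}{F_0}\,[P_T]\Big).
\]

Its defining assumption is that the fractional quench \((F_0-F)/F_0\)
equals the fractional saturation of binding sites, so the bound ligand
is occupancy × \([P_T]\). Two consequences deserve emphasis:

* **Partial quench depth.** If the fluorophore in the complex retains
  some emission (quench depth \(q < 1\)), the proxy underestimates
  occupancy and \(K_a\) is biased. At \(q = 0.72\) the bias is a few
  tens of percent; the package's recovery tests therefore use
  \(q \to 1\), where the model is exact (for 1:1 binding the relation
  \(\log\frac{F_0-F}{F} = \log K_a + \log[D]_{free}\) is then an
  identity).
* **Band shift.** Reading \(F\) at a fixed reference wavelength (the
  ligand-free emission maximum, the package default, since integrated
  versus peak intensity is usually unstated in published work)
  conflates quenching with any concurrent shift of the emission band.
  With the default synthetic −14 nm blue shift this inflates the
  apparent quench and biases \(K_a\) by roughly 10 %. Users with
  strongly shifting bands should consider integrated intensities;
  the estimator accepts any externally computed `f` vector.

Points with \(F \ge F_0\) or a non-positive free-ligand estimate are
excluded with a warning; at least four usable points are required.
\(K_a = 10^{\,\mathrm{intercept}/\mathrm{slope}}\) and \(n\) is the
slope. OLS standard errors are reported as the package's convention —
the classical literature rarely prints uncertainties for these fits.

## Thermodynamics

`vant_hoff()` regresses \(\ln K_a\) on \(1/T\):
\(\Delta H = -R\,\mathrm{slope}\), \(\Delta S = R\,\mathrm{intercept}\)
(\(R = 8.314\,\mathrm{J\,mol^{-1}K^{-1}}\)), both assumed
temperature-independent over the narrow experimental range — no
heat-capacity term, which over 30 K is a second-order effect for
albumin-ligand systems. \(\Delta G = \Delta H - T\Delta S\) follows in
the mixed units conventional in this field (kJ for \(\Delta H\),
\(\Delta G\); J for \(\Delta S\)).

Celsius-to-kelvin conversion uses +273.15 by default. A
`kelvin_offset = 273` switch exists because published tables are often
computed with the rounded offset; the four tabulated \(\Delta G\) values
the test suite checks reproduce at their printed precision only with
273, and the difference is otherwise negligible (0.05 %).

## FRET distances

`overlap_integral()` evaluates
\(J = \int F_D\,\varepsilon_A\,\lambda^4 d\lambda / \int F_D\,d\lambda\)
by the trapezoidal rule on the union of the two wavelength grids,
linearly interpolated, restricted to the common support — no smoothing,
no extrapolation. On 1 nm grids the quadrature error against a
100×-refined grid is below 0.1 % for realistic band widths
(\(\sigma \ge 10\) nm). Acceptor extinction comes from
`molar_extinction()` (absorbance / (path × concentration)); path and
concentration must be supplied explicitly or in the spectrum metadata —
silently assuming them is how unit errors of \(10^{28}\) happen in this
calculation.

`forster_radius()` adopts the convention
\(R_0^6(\text{Å}^6) = 8.79\times10^{-5}\,\kappa^2 n^{-4} Q_D J\) with
\(J\) in \(\mathrm{M^{-1}cm^{-1}nm^4}\), returning nm; a printed \(J\)
in \(\mathrm{M^{-1}cm^3}\) is accepted via the exact conversion
\(1\,\mathrm{M^{-1}cm^3} = 10^{28}\,\mathrm{M^{-1}cm^{-1}nm^4}\).
Defaults \(\kappa^2 = 2/3\) (isotropic dipole averaging — a rigid bound
chromophore can violate this, but the sixth root caps the induced
distance error at ~35 %), \(n = 1.336\) (dilute aqueous buffer),
\(Q_D = 0.118\) (native albumin). The efficiency is taken from an
explicit `f_ratio` = \(F/F_0\) at the 1:1 donor:acceptor point rather
than inferred from a titration, because which titration point a
published efficiency used is typically not recoverable.
`validate_fret()` reports the two standard reliability windows and
notes that \(r > R_0\) (efficiency below 50 % at 1:1) is the
configuration expected under static quenching.

## Conformational metrics

**Synchronous shifts.** `synchronous_shift()` locates each spectrum's
peak by fitting a parabola through the three points around the discrete
maximum (both refined and discrete positions are reported; the
refinement is exact for locally quadratic peaks and recovers sub-grid
positions to ~0.05 nm on 1–2 nm grids). The net shift is last minus
first; flat spectra are an error rather than a silent zero.

**EEM peaks.** `find_3d_peaks()` takes strict local maxima over the
8-neighbourhood. Maxima within `scatter_tol` (default 5 nm, half the
usual 10 nm excitation step) of the \(\lambda_{em} = \lambda_{ex}\)
diagonal are Rayleigh scatter; within tolerance of
\(\lambda_{em} = 2\lambda_{ex}\), second-order scatter. The two rules
cannot both fire away from the origin, and scatter never enters the
protein-peak ranking, which labels the two strongest remaining maxima
`peak1`/`peak2`. `peak_trajectory()` matches peaks across surfaces by
nearest excitation line (tolerance 15 nm — half the separation of the
two protein peaks), reporting intensity and emission sequences with
gaps flagged.

**CD and melts.** `mre_convert()` uses the molar-concentration form
\(MRE = \theta_{mdeg}/(10\,n_{res}\,c\,l)\), the standard convention;
the default 585 residues is the albumin chain length.
`melt_analysis()` defines the unfolding onset as the first temperature
past the baseline window (default 25–40 °C) where the signal leaves the
baseline by more than 3 SD of the baseline segment, floored at 1 % of
the total signal range so that noise-free synthetic curves get a finite
threshold — this onset rule is the package's own; the qualitative
literature statements it mirrors give only ranges. Recovery is the
reverse-scan signal at the evaluation temperature (default: the shared
start temperature, exposed as a parameter since published recovery
percentages rarely state it) as a percentage of the forward-scan
signal, which makes it invariant to overall signal scaling.

## Displacement assays

`relative_signal()` normalizes to the competitor-free point in percent,
preserving sign (induced CD signals may be negative). An optional
baseline — e.g. the competitor-protein complex's own CD at the
monitoring wavelength, a documented confounder for site II probes —
can be subtracted first. `assign_site()` applies a deliberately strict
rule: a site is claimed only when *every* marker of that site loses
more than the threshold (default 50 %) while *every* marker of the
other site stays below it; the per-marker table always accompanies the
verdict so users can apply their own rule. The threshold is the
package's operationalization of an argument the classical literature
makes qualitatively.

## Synthetic data

The generators exist so that every estimator can be tested against
known ground truth. Defaults mirror the albumin study design: 3 µM
protein, 0–22.5 µM ligand in 1.5 µM steps, \(K_a = 1.03\times10^5\)
M⁻¹ at 25 °C with \(\Delta H = -15.48\) kJ mol⁻¹ /
\(\Delta S = +44.06\) J mol⁻¹ K⁻¹ across 15–45 °C, 72 % maximal quench,
a −14 nm blue shift at saturation, emission band σ = 20 nm around
336 nm, ligand extinctions 4000 / 1000 M⁻¹cm⁻¹ at the excitation /
emission wavelengths (inner-filter absorbances up to ~0.09), and 1 %
relative multiplicative noise — values chosen once as realistic for
this class of experiment.

* `equilibrium_1to1()` solves the 1:1 mass balance through the
  free-ligand quadratic with stable root selection, accurate for
  \(K_a\) up to at least \(10^{9}\) M⁻¹ (validated against bisection).
* `simulate_titration()` composes occupancy → Gaussian band with
  quench and shift → inner-filter attenuation
  \(10^{-(A_{ex}+A_{em})/2}\) → noise, recording the absorbance
  increments so the analysis can invert the attenuation exactly.
  A `quench_mode = "bound_ligand"` with `n_sites > 1` provides a
  deliberate model-mismatch mode for robustness tests.
* `simulate_melt()` uses a two-state sigmoid (default midpoint 66 °C,
  width 4 °C, native MRE −21000 deg cm² dmol⁻¹). The denatured
  baseline defaults to 0 — random-coil ellipticity at 222 nm is near
  zero — which makes the reverse scan
  `baseline + reversibility × (forward − baseline)` start at exactly
  `reversibility` times the native signal, so the planted
  reversibility is identifiable from the recovery percentage.
  Melt noise defaults to 0.2 % of the native signal, a realistic CD
  noise floor.
* `simulate_eem()` sums 2-D Gaussian peaks (defaults at the native
  albumin positions 280/335 and 235/330 nm) and scatter ridges whose
  amplitude falls as \((\lambda_{ex}/300)^{-4}\), the Rayleigh
  wavelength dependence — which also gives each ridge a detectable
  crest maximum.
* `simulate_displacement()` solves the three-species mutually
  exclusive competitive equilibrium by damped fixed-point iteration on
  the free-protein concentration (relative residual < 10⁻¹²,
  validated against a refining grid-search oracle), with signal
  proportional to the marker-bound fraction.

All generators are bit-reproducible under a fixed seed. What they do
*not* emulate: instrument drift and baseline wander, detector
saturation, photobleaching, aggregation during melts, correlated noise,
and any photophysics beyond the static band model. Passing recovery
tests on this synthetic data therefore demonstrates correctness of the
estimators under their own assumptions, not robustness to every
instrumental artifact of real spectra.

## Problem sizes and test design

The validation suite runs titrations of 16 points, Monte-Carlo recovery
at 200 replicates × 1 % noise, melt curves of 56 points, and EEM
surfaces of 27 × 57 cells — sizes matched to the experimental designs
being emulated, and comfortably sufficient for the quoted tolerances
(e.g. the Stern-Volmer slope SE at 1 % noise is ~0.8 %, so a 2 %
recovery tolerance is a ~2.4 σ bound).

## Known limitations

* Single-site 1:1 binding only; no cooperative or multi-site models,
  no global multi-wavelength fitting, no ΔCp.
* The occupancy-equals-fractional-quench assumption is inherited from
  the double-log method; see the bias discussion above.
* Linear interpolation everywhere; no smoothing, so very coarse grids
  (> 4 nm) degrade peak refinement and overlap integrals.
* Marker dissociation constants are not estimated from displacement
  curves — the assay output is the loss table and site verdict.
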