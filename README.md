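# quenchbind

Fluorescence quench titration analysis of ligand–protein binding.

Small molecules — drugs, dietary flavonoids, metabolites — are carried
through the bloodstream bound to serum albumin, and the standard way to
characterize such an interaction is a battery of spectroscopic
experiments: titrate the protein with the ligand and watch the intrinsic
tryptophan fluorescence quench, repeat at several temperatures to
decompose the energetics, measure the donor–acceptor spectral overlap to
place the ligand relative to the fluorophore, and displace site-marker
drugs to name the binding pocket. `quenchbind` implements that entire
workup as composable R functions returning classed fit objects, plus a
synthetic-data generator with known ground truth so every stage can be
validated without instrument data.

## The models

**Inner-filter correction.** Ligands that absorb at the excitation or
emission wavelength attenuate the measured signal; the geometric-mean
correction restores it:
`F_cor = F_obs · 10^((A_ex + A_em)/2)`.

**Stern–Volmer quenching.** `F0/F = 1 + K_SV [Q]`, fitted by OLS over
the linear low-concentration zone (upward curvature at high [Q] is
detected and excluded). The bimolecular quenching constant
`k_q = K_SV / τ0` distinguishes static from dynamic quenching: values
far above the diffusion limit (~10¹⁰ M⁻¹ s⁻¹), and K_SV falling with
temperature, indicate ground-state complex formation.

**Binding isotherm.** The association constant K_a and stoichiometry n
come from the mass-balance-corrected double-logarithmic model

```
log10((F0 − F)/F) = n·log10(K_a) + n·log10([D_T] − (F0−F)/F0 · [P_T])
```

which estimates the free ligand concentration from the total instead of
assuming ligand excess.

**Van't Hoff thermodynamics.** OLS of ln K_a against 1/T gives
ΔH = −R·slope and ΔS = R·intercept; ΔG(T) = ΔH − TΔS.

**FRET distance.** The overlap integral
`J = ∫ F_D(λ) ε_A(λ) λ⁴ dλ / ∫ F_D(λ) dλ` (trapezoidal rule), the
Förster radius `R0⁶ = 8.79×10⁻⁵ κ² n⁻⁴ Q_D J` (Å⁶, J in M⁻¹cm⁻¹nm⁴),
the efficiency `E = 1 − F/F0`, and the donor–acceptor distance
`r = R0 ((1−E)/E)^(1/6)`, with the standard validity checks
(0.5 R0 < r < 2 R0; 2 nm < r < 8 nm).

**Conformation and site assignment.** Synchronous-scan peak shifts
(Δλ = 15 nm for Tyr, 60 nm for Trp), excitation–emission-matrix peak
detection with Rayleigh/second-order scatter classification, mean
residue ellipticity conversion, thermal melt onset/recovery analysis,
and site-marker displacement with a per-marker loss table and verdict.

## Worked example

```r
library(quenchbind)

ka_tab <- c(1.28e5, 1.03e5, 8.57e4, 6.92e4)  # M^-1 at 15/25/35/45 C
vh <- vant_hoff(ka_tab, c(15, 25, 35, 45), unit = "C", kelvin_offset = 273)
vh
#> van't Hoff analysis
#>   delta_H = -15.44 kJ mol^-1
#>   delta_S = +44.18 J mol^-1 K^-1
#>   r^2     = 0.99840 (4 temperatures)
#>  T_K       K_a delta_G_kJ
#>  288 1.280e+05     -28.16
#>  298 1.030e+05     -28.61
#>  308 8.570e+04     -29.05
#>  318 6.920e+04     -29.49
```

The negative ΔH with positive ΔS says binding is both enthalpy- and
entropy-favoured — the signature of van der Waals/hydrogen-bonding
contacts combined with hydrophobic desolvation — and ΔG near
−29 kJ mol⁻¹ corresponds to the moderate affinity (K_a ≈ 10⁵ M⁻¹)
typical of a transport interaction.

A full synthetic round trip:

```r
truth <- ground_truth(ka = 1.03e5, noise_sd = 0, quench_depth = 0.999,
                      band_shift = 0, seed = 1)
fit <- binding_isotherm(simulate_titration(truth))
fit
#> Double-logarithmic binding isotherm
#>   temperature: 25 degC
#>   K_a = 1.028e+05 M^-1
#>   n   = 0.999  (SE 0.000)
#>   r^2 = 1.00000 over 15 points
```

and the FRET chain from printed constants:

```r
r0 <- forster_radius(2.814e-15, j_unit = "M-1 cm3")  # 1.984 nm
donor_acceptor_distance(0.214, r0)                   # 2.465 nm
```

An end-to-end run over CSV inputs (quench → bind → thermo → fret →
sync → melt → displace) is available through `run_pipeline()`, driven
by an R list or YAML config; see `?run_pipeline`.

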