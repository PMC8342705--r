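---
title: "The Lorentz-oscillator model behind lorentzcorona"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Lorentz-oscillator model behind lorentzcorona}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lorentzcorona)
```

## The physical picture

A protein (or particle–protein complex) suspended in buffer and probed
by a microwave field is modelled as an ensemble of N identical charged
harmonic oscillators: each molecule carries net charge Q and mass M, is
bound by an effective spring (natural angular frequency ω₀, the
"mechanical frequency" — the quantity of interest, a proxy for
conformational state), damped by buffer drag (damping constant γ), and
driven by the probe field E₀·cos(ωt). Solving the driven, damped
equation of motion and collecting the in-phase part of the induced
polarization gives the relative permittivity

$$\varepsilon_r \;=\; 1 \;+\;
\frac{S\,(\omega_0^2-\omega^2)}
     {\varepsilon_0\!\left[(\omega_0^2-\omega^2)^2+(\gamma\omega)^2\right]},
\qquad S = \frac{NQ^2}{M}.$$

The experiment measures ε_r (via the shift of a resonant probe, outside
this package's scope) at temperatures 30–55 °C in 5 °C steps, two runs
per condition; the package inverts the relation above for ω₀ per sample
and temperature and derives the per-molecule dipole amplitude and the
polarization current density.

Assumptions worth keeping in mind: one oscillator species per
(non-inert) component — no distribution of modes, no Debye/Cole–Cole
relaxation spectrum; γ is frequency-independent; the ensemble responds
linearly; and the buffer's own permittivity is absorbed into the
constant 1 (the model describes the *excess* response).

## Units: angular versus cyclic frequency

All internal frequencies (ω, ω₀, γ) are angular (rad/s); everything a
user reads as a frequency (`drive_frequency_hz`, `f0_hz_*` columns) is
cyclic, f = ω/2π. Mixing the two conventions changes ω₀ by 2π ≈ 6.3 and
is the single easiest way to mis-derive MHz-scale numbers from this
model; the package fixes the convention once and converts only at the
interfaces.

## Exact inversion, and the two dialects

Writing x = ω₀² − ω² and B = S/(ε₀(ε_r − 1)) (defined only for
ε_r > 1), the forward relation is the quadratic
x² − Bx + γ²ω² = 0, so

$$\omega_0^2 \;=\; \omega^2 + \tfrac{1}{2}\!\left[B \pm
\sqrt{B^2 - 4\gamma^2\omega^2}\right].$$

This is the `"consistent"` mode of `invert_natural_frequency()`: both
roots are returned and each real root substituted back reproduces ε_r to
machine precision (the package tests this at 1e-9 relative, and reports
the residual per sweep row). A widely circulated closed form for this
inversion instead carries the discriminant
(B + 2ω²)² − 4(B + 2ω²)(ω⁴ + γ²ω² + Bω²), which is dimensionally
inhomogeneous and does not invert the forward relation; it is available
as `mode = "as_printed"` for audit, always flagged non-round-trippable,
and never used by the pipeline. Round-trip consistency is the only
contract a downstream user can verify, which is why the consistent
dialect is the default.

Three structural facts follow from the quadratic:

* both roots of x are positive whenever ε_r > 1 (their product is
  γ²ω² > 0 and their sum B > 0), hence **ω₀ > ω for every solvable
  measurement** — with a 6.41 GHz drive, natural frequencies below the
  drive frequency (e.g. MHz-scale values sometimes quoted for such
  samples) cannot satisfy the forward relation in consistent SI units;
* for γ > B/(2ω) the discriminant is negative and the root pair is a
  complex conjugate pair. The package returns it flagged
  (`root_real = FALSE`), never silently as a magnitude. Because complex
  roots still satisfy x² + γ²ω² = Bx, the forward model evaluated in
  complex arithmetic still reproduces ε_r exactly — the round-trip
  guarantee survives, only the physical interpretation (a real
  mechanical resonance) is lost;
* at ε_r = 1 the numerator forces ω₀ = ω and B diverges; such rows are
  degenerate-input errors, and the sweep skips them with a logged
  diagnostic.

Root selection: the smaller real root by default (the branch that keeps
ω₀ closest to the drive and varies smoothly with ε_r); both roots are
always reported. With no real root the pair member with positive
imaginary part is "selected" for bookkeeping, and such rows are excluded
from the radar comparison by default.

A discriminant within 1e-12 (relative to B²) of zero is treated as an
exact double root, so the critical-damping boundary does not flicker
between real and complex under floating-point rounding.

## Damping calibration

γ is an empirical parameter. It is fixed per protein species by matching
the model-implied per-molecule dipole amplitude

$$p \;=\; \frac{Q^2 E_0}{M\sqrt{(\omega_0^2-\omega^2)^2+(\gamma\omega)^2}}$$

(charge × displacement amplitude, with ω₀ re-solved from the inversion
at each trial γ) to a literature dipole moment: 369 D for insulin, 150 D
for papain (1 D = 3.33564e-30 C·m). Using the quadratic identity the
amplitude reduces to p = Q²E₀/(M√(Bx)), strictly decreasing in γ along
the smaller-root branch, so a bisection on log γ over
[1e-3, 1e15] s⁻¹ — truncated above at the critical damping B/(2ω),
beyond which no real root exists — is deterministic; `uniroot` is run to
1e-13 on log γ and the achieved dipole checked at 1e-8 relative.

The achievable dipole range has a hard floor, p_min = √2·Q²E₀/(MB) at
the critical damping. For the literature constants of this system
(insulin Q = 74.805e-10 C, M = 9.52e-18 kg, N ≈ 1.81e11 from 6.9 mg/ml
in a 250 µl holder, E₀ = 4.9 V/m) that floor is ≈ 2.3e-20 C·m, about
seven orders of magnitude *above* the 369 D ≈ 1.23e-27 C·m target. The
calibration therefore cannot reach the literature targets for these
study conditions: `calibrate_damping()` returns the nearest-achievable
damping (the critical damping) together with a `no_solution` diagnostic,
and the sweep carries that diagnostic in its calibration record. This is
reported honestly rather than hidden because any numeric path that
*does* land on the literature dipole with these constants must have
mixed units or rescaled N somewhere it did not say; the package declines
to guess. A side effect is that at temperatures where ε_r is larger than
at the calibration anchor, B shrinks below 2γω and the roots go complex
— visible as `selected_real = FALSE` in the example sweep.

Calibration is anchored once per species, at the coolest measured
temperature of its pure sample, and γ is held fixed across the sweep
(thermal variation of buffer drag is second-order compared with the
ε_r(T) signal); `recalibrate_per_temperature = TRUE` exposes the
alternative.

## Mixtures

Effective damping is the volume-weighted mean γ_mix = Σ γᵢVᵢ / Σ Vᵢ —
stated for two components in the source formulation, extended here to k
components by the same weighting because the ternary
insulin:papain:ZnO (8:1:4) design needs it. Oscillator strength is
additive, S = Σ NᵢQᵢ²/Mᵢ. Species flagged `inert` (the ZnO particles:
near-zero net charge, mass far above the proteins) contribute zero
strength; by default they are excluded from the damping average too,
since a species that does not oscillate should not dilute the drag of
those that do — `include_inert_damping = TRUE` flips that policy, which
is a genuine modelling choice rather than a derived fact. Each
component's molecule count is computed from its *own* stock
concentration and its *own* contributed volume (pre-mix mass is
conserved; the alternative — post-mix concentrations — changes N by the
volume ratio and is not used).

## Data conventions

Measurement tables are plain CSV
(`sample_id,temperature_C,epsilon_r,run`; auxiliary tables
`sample_id,quantity,value,run` with `zeta_mV` or
`enthalpy_J_per_g_degC`), UTF-8, "." decimal, Unicode minus normalised
on read, malformed rows rejected with their line numbers, duplicate keys
fatal. Replicate spread is half the range for two runs (matching how
two-run repeatability bars are drawn) and the sample standard deviation
for three or more (the zeta-potential triplicates). `printed_value()`
truncates toward zero by default because the reference tables this
package reproduces do (e.g. a triplicate mean of −19.1667 mV printed as
−19.1, 6.6867 mV as 6.68); rounding is available explicitly.

## Radar (relative-change) summary

For each quantity x ∈ {ε_r, dipole, J_P, f₀, ζ, ΔH} the summary reports
|x_sample − x_ref| / |x_ref| against the reference sample (pure
insulin), at a declared comparison temperature, 30 °C by default (the
coolest, least-perturbed condition; the choice is a parameter because
nothing in the data fixes it). Zeta and enthalpy come from replicate
aggregates; model quantities of rows with complex root pairs are
excluded (`NA`) by default. A missing reference or an exactly zero
reference value is an error, never an infinity.

## Verification scan

The resonant-absorption verification is simulated with the Lorentzian
consistent with this oscillator,
A(ω) = P_pump·(γω)²/((ω₀²−ω²)²+(γω)²), which equals the pump power
exactly on resonance; the experiment's lineshape is not specified
anywhere, so consistency with the model is the design criterion. Peak
location is refined by three-point parabolic interpolation, which is
exact for a quadratic peak and recovers a noise-free resonance to well
under one grid step. Pump levels convert by the standard
10^(p/10) mW rule, so −50 dBm is 10 nW; quoted correspondences of
−50 dBm to tens of microwatts are inconsistent with that definition and
are treated as a unit slip, not as an alternative mode.

## Synthetic data: what it emulates and what it does not

`synthetic_truth()` + `generate_measurements()` forward-simulate the
sweep protocol: temperatures 30–55 °C in 5 °C steps, two replicate runs,
multiplicative Gaussian noise on ε_r (error bars in this kind of data
grow with the permittivity magnitude; additive noise is a configuration
away), values clipped below at 1 + 1e-6 with the clip count logged. The
default study (`default_synthetic_study()`) uses the insulin-like
ensemble with γ_true = 0.5 ω and ω₀(T) falling linearly from 2.0 ω to
1.4 ω, which on the lower branch makes ε_r rise from ≈25 to ≈60 while
the mechanical frequency falls — the qualitative signature of a
thermally unfolding protein. Default noise is 5% (the scale of the
larger observed two-run spreads).

What passing recovery tests establishes: the pipeline inverts its own
forward model without bias (recovery error < 1% at 5% noise with 50
runs, → 0 as noise → 0). What they do not establish: that real samples
follow a single-mode Lorentz oscillator, that γ is
temperature-independent, or that replicate noise is multiplicative
Gaussian — those are modelling assumptions, not tested facts.

## Numerical choices, in one place

* ε₀ = 8.8541878128e-12 F/m; 1 D = 3.33564e-30 C·m.
* Discriminant treated as zero within 1e-12 relative to B².
* Calibration bracket [1e-3, 1e15] s⁻¹ ∩ (0, B/2ω]; log-γ bisection
  (`uniroot`, tol 1e-13); dipole tolerance 1e-8 relative.
* Synthetic clipping floor 1 + 1e-6.
* Property-test problem sizes: brute-force inversion oracle on 1e6-point
  grids × 100 random draws; derivative check on 100 draws at step
  1e-15 s; 1000-draw mixture-invariant sweeps; 200-scan Monte-Carlo peak
  recovery; 50-run noisy recovery sweeps. These sizes give the oracle
  grids a resolution (≈1e-6 relative in x) far below every tolerance
  they arbitrate.

## Known limitations

Single oscillator mode per component; no frequency-dependent relaxation
spectra; γ calibrated at one temperature; the polarization response and
current density are susceptibility-scaled field quantities (per-volume
normalisation of the underlying experiment is not specified, so absolute
magnitudes should be compared only within a run, not across
instruments); and the literature-dipole calibration is, for the study's
own constants, a bounded-below problem whose honest answer is the
critical damping plus a diagnostic, as discussed above.
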