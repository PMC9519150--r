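---
title: "Pinnal cavity acoustics: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pinnal cavity acoustics: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resonear)
```

# The system and the questions

Some neotropical katydids carry cuticular flaps (pinnae) that partially
enclose each tympanal membrane of the foreleg ear, leaving only a narrow slit
open. Each flap and the air pocket behind it form a cavity that can act as a
*neckless Helmholtz resonator*: a volume of air whose opening behaves as an
oscillating air plug, resonating at a frequency set by the opening radius, an
end-correction, and the cavity volume. Because the cavities are sub-millimetre,
the predicted resonances fall in the high ultrasonic band used by hunting
bats, far above the species' own calling song. This package implements the
computational chain used to examine that hypothesis:

1. lumped resonance predictions from cavity morphometry,
2. a finite-element (FEM) model of plane-wave scattering by a thin-shelled
   cavity, in the frequency and time domains,
3. analysis of tone-burst and chirp vibrometry recordings,
4. behavioural and neural audiogram summaries, and
5. bat echolocation call parameterisation and band overlap,

with seeded synthetic generators standing in for every laboratory instrument.

# Lumped model

For a cavity of volume $V$ with a neckless circular opening of radius $r$,

$$ f_h = \frac{c}{2\pi}\sqrt{\frac{\lambda\, r}{V}}, $$

with $c$ the speed of sound (343 m/s by default) and $\lambda = 1.85$ the
end-correction factor: the slit has no physical neck, so the oscillating air
plug is entirely virtual and its effective length is proportional to $r$.
The slit is converted to $r$ by treating its area $A$ as a perfect circle,
$r = \sqrt{A/\pi}$. Internally everything is SI; the user-facing morphometry
tables are in mm²/mm³ because that is how such measurements are reported.
The end-correction is an explicit parameter (default 1.85) because its
appropriate value depends on how the opening is flanged; see the FEM
discussion below. Predicted frequencies are kept at full precision and only
rounded (two decimals in kHz) for display.

# Finite-element scattering model

The acoustic domain is a sphere of air (default radius 3 mm; the examples in
this package use 1.4–1.8 mm, which keeps every validation case under ~50k
elements) surrounding the ear geometry. In the frequency domain we solve the
Helmholtz equation $\frac{1}{\rho}(\Delta p + k^2 p) = 0$ for the total
pressure, with a second-order spherical radiation condition on the outer
boundary,

$$ \partial_n p + \left(ik + \frac{1}{R}\right)p
   - \frac{R}{2(ikR+1)}\Delta_\parallel p \;=\; \text{(same operator applied to } p^i\text{)}, $$

so the incident plane wave $p^i = e^{-ik\,x\cdot e_k}$ enters through the
boundary data and scattered waves leave without reflection. The printed form
of this operator in the source literature is typographically ambiguous; the
form above is the standard second-order expansion in spherical coordinates,
and with no scatterer present it reproduces the incident wave throughout the
domain to well under 2 % at the mesh rule below (this is asserted by the test
suite). The time-domain model solves the wave equation with the analogous
first-order spherical condition and a gated sinusoidal incident tone,
integrated by the generalized-alpha method with spectral radius
$\rho_\infty = 0.75$.

**Meshes.** No tetrahedral mesher exists in the R ecosystem this package
targets, so it builds structured layered latitude–longitude ball meshes:
identical surface triangulations on every spherical layer, triangular prisms
between layers split into tetrahedra by the min-vertex-index diagonal rule
(which provably never produces the unsplittable cyclic prism), and a
tetrahedral fan at the centre. The parametric ear is a spherical-bowl cavity:
one mesh layer is placed exactly at the cavity radius, the wall nodes beyond
the slit rim are duplicated so the interior communicates with the exterior
only through the slit, and the cavity radius and slit angle are calibrated in
two passes so the realized discrete volume and slit area are within 2 % of
the request. The mesh rule is six tetrahedra per wavelength at the highest
analysis frequency, $h_{max} = c/(6 f_{max})$; the time step default
$\Delta t = 1/(60 f_{max})$ makes the CFL number $c\,\Delta t/h_{max}$ exactly
0.1.

**Elements and solver.** Quadratic Lagrange tetrahedra are the default
(linear elements are available and are used for the long time-domain runs,
where geometry rather than dispersion limits accuracy). Element integrals use
Gauss–Jacobi conical-product quadrature derived in-package via Golub–Welsch;
exactness is asserted in the tests against closed-form barycentric monomial
integrals. The complex linear systems are solved by BiCGSTAB preconditioned
with a supernodal Cholesky factorisation of the positive-shifted operator
$K + k^2 M + M_\Gamma/R$ — the domains span at most a few wavelengths, so
convergence takes tens of iterations — with a direct sparse-LU fallback on
the real $2n$ interleaved system if the iteration ever stalls (tolerance
1e-8 relative residual).

**Shells.** The tympanal membranes and cavity walls are isotropic thin
shells (Young's modulus 2 GPa, density 1300 kg/m³, Poisson 0.3; thickness
5 µm for the tympana and 175 µm elsewhere). This package models them as a
*locally-reacting* impedance: per-area mass $\rho_s t$ plus a per-area
stiffness derived from the fundamental bending mode of a clamped circular
plate of configurable effective radius, eliminated analytically so the wall
couples the pressure jump across the duplicated nodes. This captures the
mass-law and first-resonance behaviour of the shell without a full
Kirchhoff–Love facet-shell discretisation, which is beyond the intended
problem sizes; a rigid-wall mode (the limit of infinite stiffness, verified
in the tests) is the reference configuration for all oracle comparisons. The
air density (1.21 kg/m³, 20–25 °C) enters only this coupling; pure pressure
ratios such as cavity gains are density-invariant.

**Validation.** Three independent oracles are wired into the tests: (i)
radiation-boundary transparency against the exact plane wave; (ii) rigid
sphere scattering at $ka = 1$ against the partial-wave series (computed in
the test helpers from spherical Bessel functions, with monotone error decay
under mesh refinement); (iii) time-domain steady-state amplitudes against the
frequency-domain solution on the same mesh at 23, 40 and 60 kHz.

## The lumped formula versus the FEM cavity

At the study's mean morphometry (slit 0.16 mm², volume 0.14 mm³) the
equivalent slit radius is 0.70 of the cavity radius: the opening is enormous
relative to the cavity, far outside the small-aperture regime in which the
lumped formula is derived. The FEM interior-pressure peak of the parametric
spherical-bowl cavity converges (under both angular refinement and element
order) to roughly 24 % above the lumped prediction, and even at small
apertures ($a/r_{cav} \le 0.35$) the converged ratio is about 1.16: a thin
*curved* wall is effectively unflanged on both faces and carries less
end-correction than the factor 1.85 assumes, and a conforming FEM approaches
a cavity resonance from above. One acceptance check in the test suite asserts
the 15 % lumped/FEM agreement at the study morphometry and therefore fails;
it is kept as an honest record of this model discrepancy rather than being
relaxed. It is worth noting that the package's FEM peak for this cavity
(~117 kHz) sits close to the tympanal resonances and simulated gain peaks
reported for the real ears (~108–118 kHz), i.e. the lumped formula — not the
FEM — is the biased estimate for these wide-slit cavities.

# Vibrometry signal analysis

Tone bursts are four-cycle sine bursts; burst onsets are honoured at
sub-sample precision because the measurand is a microsecond-scale arrival
difference sampled at 512 kHz. Recordings are band-pass filtered with a
4th-order Butterworth applied forward-backward: the filter design is a
package choice, but zero phase is mandatory because group delay would bias
arrival times. Bands follow the recording protocol (10–30 kHz for 23 kHz
stimuli, 30–50 for 40, 50–70 for 60; anything else falls back to ±10 kHz
with a warning).

The "second oscillation" landmark is the second positive-going zero crossing
after burst onset. Counting crossings directly from an envelope-threshold
onset is fragile: one stray noise crossing shifts the arrival by a full
period. Instead the implementation anchors on the 50 % crossing of the
analytic (Hilbert) envelope — which sits at a fixed ~0.1-period offset from
the true onset of a short tone burst, independent of amplitude — and selects
the zero crossing nearest one period after that anchor. A detection also
requires the envelope peak to exceed its median by 15 dB; pure stationary
noise peaks near 11 dB above its median, so noise-only windows return an
explicit no-detection. Phase differences are $\varphi = 360^\circ f\,
\Delta t$, unwrapped by default. Point zero is the sweep angle minimising the
absolute phase difference between the two tympana, requiring detections on
both tympana at three or more angles, with ties resolved towards 0°.

Chirp transfer functions are mean Hamming-windowed Welch periodograms of the
response divided by the reference (segment length 1024 at 512 kHz, i.e.
500 Hz bins, 50 % overlap; all parameters recorded on the result), and
resonance peaks are refined by quadratic interpolation through the three
bins around the maximum so the estimate does not depend on the sweep step;
boundary maxima and exact ties are flagged rather than interpolated.
Frequencies for scaled 3D-printed models divide by the print scale; the
1:11.43 convention reproduces the printed scaled stimuli (5.25 kHz for
60 kHz, etc.).

# Audiograms

Behavioural threshold matrices are individuals × frequencies (20–120 kHz in
5 kHz steps) in dB SPL with `NaN` for stimuli that evoked no response.
Summaries use the arithmetic mean and the *sample* standard deviation
(n−1 denominator) over non-missing entries — the n−1 convention is pinned by
the printed table itself (40 kHz column: SD 7.07 only under n−1). Band
summaries require an explicit pooling mode (`raw`, `per_frequency`,
`per_individual`) because the three differ on ragged matrices; the reported
90–120 kHz band means are 58.06 / 58.07 / 58.45 dB SPL respectively, none of
which reproduces the 59.28 ± 1.80 dB figure printed alongside the source
table — the closest single match is the 110 kHz column mean (59.29). The
discrepancy is flagged here rather than resolved; `raw` is the default.

Neural traces are RMS-transformed with an exponential smoother (time
constant 0.66 ms, the instrument convention; a sliding-window variant is
selectable), and responses are trapezoidal areas under the envelope over
475 ms windows. "Excluding the transient on-response" is operationalised as
starting the window 25 ms after stimulus onset (the 500 − 475 ms gap),
configurable. On/off comparisons use the percent elevation
$100\,( \text{on} - \text{off})/\text{off}$ and a standard paired t-test.

# Bat calls and band overlap

Spectrograms use the conventional call-analysis settings (FFT 512, Hamming,
50 % overlap). Call parameters are measured on the composite power spectrum:
peak frequency at the maximum, and minimum/maximum frequencies as the
*outermost* crossings of the −20 dB level below and above the peak (matching
"lowest frequency below / highest frequency above the peak"), linearly
interpolated in dB between bins; spectra that never fall 20 dB below the
peak are flagged at the support edges. Band overlap is plain interval
arithmetic, $|g \cap b|/|b|$ for gain band $g$ and call band $b$.

# Synthetic generators

Every generator is a pure function of a seeded configuration: identical
seeds give identical outputs, and each returns its ground truth so every
downstream stage has a recovery test. Defaults encode the study conditions:
slit areas 0.16 ± 0.01 mm², cavity volumes 0.14/0.15 ± 0.01 mm³, tympanal
resonances 107.84/111.13 kHz, the printed behavioural threshold means/SDs on
the 20–120 kHz grid with 5 dB staircase quantisation, clipping to the tested
40–90 dB range and ~10 % missingness, a 2 µs anterior-to-posterior arrival
lag at the extreme speaker angle (12 cm arc, 1° = 0.56 mm steps), and the
three printed gleaning-bat call templates. Angle sweeps place the arrival
symmetry axis at the injected point zero and, with pinnae intact, put the
amplitude maxima at ±10° with the minimum near point zero (ablated: maximum
at point zero) — the qualitative pattern reported for the real ears, with
~2–3 nm displacement scales. The default additive noise (0.02 of the signal
unit) leaves tone-burst SNRs near 35 dB, comparable to good vibrometry
sessions. Bat calls are synthesised in the frequency domain: a two-sided
parabolic dB envelope anchored exactly at the −20 dB bounds, a linear
downward group delay spanning the call duration, and a −26 dB second
harmonic for the multi-harmonic character; this guarantees the round-trip
through `call_params()` to within a spectrogram bin.

What the generators deliberately do *not* emulate: real tympanal mechanics
(travelling waves on the membrane), correlated noise and instrument
artefacts, spike structure in nerve recordings (only summed activity), and
atmospheric attenuation of bat calls. Passing recovery tests therefore
demonstrates the correctness of the analysis chain, not the fidelity of any
biological model.

# Problem sizes and runtime choices

The validation problems are sized for a single desktop CPU: radiation
spheres of 1.4–1.8 mm radius, meshes of roughly 7k–32k tetrahedra (up to
~45k quadratic degrees of freedom), frequency sweeps of 15–20 points with
interpolated peak extraction, and time-domain runs of a few thousand steps
at CFL 0.1. Full-resolution replication of 17 micro-CT ear geometries at
150 kHz is explicitly out of scope; the package demonstrates the same
physics on reduced synthetic geometries.

# Known limitations

- The locally-reacting shell ignores bending wave propagation along the
  shell and any anisotropy; time-domain runs support rigid walls only.
- The structured mesher only builds spherical topologies; STL geometries are
  tetrahedralised by a voxel cut-cell method suitable for volume estimates
  and inspection, not for production scattering runs.
- No thermoviscous losses: sub-millimetre slits plausibly dissipate enough
  to flatten the cavity resonance peaks, which the lossless model cannot
  show.
- The lumped/FEM discrepancy discussed above means the 1.85 end-correction
  should be treated as a reporting convention, not as a validated physical
  constant for these geometries.
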