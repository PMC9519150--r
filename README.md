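# resonear

Analysis toolkit for the acoustics of katydid ear pinnae — the cuticular
flaps that enclose each tympanal membrane of the foreleg ear in an air
cavity opened by a narrow slit. Such a cavity behaves as a **neckless
Helmholtz resonator**, and because the cavities are sub-millimetre their
resonances fall in the high ultrasonic band used by echolocating gleaning
bats rather than in the insect's own calling-song band. `resonear` is for
bioacousticians and sensory ecologists who want to run, test or extend the
full computational chain behind that observation:

- **Morphometry → resonance.** For a slit of area *A* and a cavity of
  volume *V*, the opening is treated as a circle of radius
  *r* = √(*A*/π) and the resonance is

  *f*ₕ = (*c*/2π) · √(1.85 · *r* / *V*),

  with *c* the speed of sound and 1.85 the end-correction factor of the
  neckless opening.
- **Finite-element scattering.** Plane-wave scattering by a thin-shelled
  cavity inside a spherical air domain, in the frequency domain (Helmholtz
  equation with a second-order spherical radiation boundary) and the time
  domain (generalized-alpha stepping at CFL 0.1), with rigid or
  locally-reacting elastic walls, on structured tetrahedral meshes built
  in-package (six elements per wavelength).
- **Vibrometry signal analysis.** Four-cycle tone-burst arrival times and
  displacements (zero-phase Butterworth band-passing, second-oscillation
  landmark), phase differences φ = 360·*f*·Δ*t*, point-zero location from
  angle sweeps, chirp transfer functions and interpolated resonance peaks,
  and print-scale frequency conversion for 3D-printed model experiments.
- **Audiograms.** Behavioural threshold matrices with missing-value-aware
  means/SDs and band summaries; neural responses via RMS envelopes
  (τ = 0.66 ms), 475 ms response areas, percent-above-background and paired
  on/off t-tests.
- **Bat calls.** Spectrograms (FFT 512, Hamming, 50 % overlap), call
  parameters (peak frequency and −20 dB minimum/maximum), and the overlap
  between cavity gain bands and call bands.
- **Synthetic data.** Seeded generators for every input above, with ground
  truth returned alongside, so the entire pipeline is testable without
  instrument data.

## Worked example

```r
library(resonear)

morph <- read_morphometry(system.file("extdata", "pinnal_morphometry_means.csv",
                                      package = "resonear"))
helmholtz_resonance(morph)
#>   label slit_area_mm2 cavity_volume_mm3 resonance_khz
#> 1   APC          0.16              0.14      94.27111
#> 2   PPC          0.16              0.15      91.07455
```

The anterior pinnal cavity (APC: slit 0.16 mm², volume 0.14 mm³) is
predicted to resonate at 94.27 kHz and the posterior (PPC) at 91.07 kHz —
bat-call territory, nowhere near the 23 kHz calling song.

```r
tm <- read_threshold_matrix(system.file("extdata", "behavioural_thresholds.csv",
                                        package = "resonear"))
band_mean(tm, 90, 120)
#>    mean_db    sd_db  n pooling f_low f_high
#> 1 58.06122 6.440135 49     raw    90    120
```

Behavioural startle thresholds in the 90–120 kHz band (the cavity-resonance
band) average 58.1 dB SPL over the 49 recorded responses — the katydids
stay sensitive exactly where the cavities amplify.

```r
cfg <- generator_config(seed = 1)
ch <- gen_chirp_response(cfg, resonance_f0 = 107.84e3)      # synthetic tympanum
resonance_peak(chirp_transfer(ch$response, ch$stimulus), c(80e3, 120e3))
#>     f_peak gain_peak boundary   tie found
#> 1 107565.1  29.83695    FALSE FALSE  TRUE

est <- call_params(power_spectrum(gen_bat_call(bat_call_templates()[3, ])))
band_overlap(c(60, 120), c(est$fmin_khz, est$fmax_khz))
#> [1] 0.7782327
```

The chirp analysis recovers the synthetic tympanal resonance (107.84 kHz)
to within a spectral bin, and 78 % of the synthesised *Micronycteris
microtis* call band falls inside the 60–120 kHz cavity gain band.

`run_pipeline(pipeline_config(seed = 1))` chains every stage (resonance →
FEM sweep → burst/chirp analysis → audiograms → bat-call overlap) on
all-synthetic inputs and returns one result bundle with per-stage logs;
`write_results()` serialises it with the resolved configuration embedded.

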