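Package: resonear
Title: Pinnal Cavity Acoustics and Ultrasonic Hearing Analysis for Katydid Ears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how cuticular pinnae turn katydid ears into
    Helmholtz-like ultrasound resonators. Implements neckless Helmholtz
    resonance predictions from cavity morphometry, a finite-element model of
    acoustic scattering by thin-shelled ear cavities in the frequency and time
    domains with a second-order spherical radiation boundary, tone-burst and
    chirp vibrometry signal analysis (arrival times, phase differences,
    point-zero location, transfer functions and resonance peaks), behavioural
    and neural audiogram summaries, bat echolocation call parameterisation and
    band-overlap metrics, and seeded synthetic generators that emulate every
    laboratory input so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
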