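Package: bisdemod
Title: Multitone Bioimpedance Spectroscopy by Coherent Sub-Sampling Demodulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of a low-resource multitone bioimpedance
    spectroscopy readout. Tones are placed on a power-of-two grid fi = f0/2^i,
    the voltage response of a tissue model (constant phase elements, R/C/CPE
    networks, or tabulated spectra) is sampled coherently at 4*f0, and complex
    impedance per tone is recovered by synchronous decimation-accumulation
    demodulation (additions only, no multipliers) followed by an exact
    recursive correction of the deliberate aliasing. Includes a bit-true
    fixed-point accumulator model with adder sizing and MSB truncation,
    analytic and Monte Carlo noise/SNR analysis of the estimator, reference
    estimators (single-tone coherent sampling, single-bin Fourier
    correlation), and an operation-count/acquisition-time cost model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
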