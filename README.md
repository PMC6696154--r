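# bisdemod

Simulation and analysis of a minimal digital readout for **bioimpedance
spectroscopy** — the measurement of a tissue's complex electrical impedance
Z(f) across frequency, used for body-composition analysis, tissue
characterization and health monitoring. The package is aimed at
mixed-signal/biomedical engineers evaluating low-power readout
architectures, and at anyone who needs a faithful, testable software model
of coherent multitone demodulation.

## The method

Tissue spectra are smooth and resonance-free, so a sparse logarithmic grid
suffices. All tones are placed at

    f_i = f0 / 2^i,   0 <= i < nf        (~3.32 points per decade)

and excited simultaneously by unit cosines. The voltage response is sampled
coherently at `fclk = 4*f0`; stage *j* of the demodulator simply averages
every 2^(j+2)-th sample (in-phase, S_j) and the samples 2^j clock ticks — a
quarter period of f_j — later (quadrature, Q_j). That is the entire signal
path: **additions only, no multiplier**, and one acquisition lasts a single
period of the lowest tone (2^(nf-1)/f0 — nf times faster than a single-tone
sweep, at 2(2^nf − 1) additions versus nf·2^(nf+1) multiply-adds for
transform-based analysis).

Sub-sampling deliberately folds the higher tones onto DC. The folded
mixture is known in closed form,

    S_j = Σ_{i<=j} Re(Z_i),
    Q_j = Σ_{i<=j-2} Re(Z_i) − Re(Z_{j-1}) − Im(Z_j),

and is inverted exactly by the recursion

    Re(Z_j) = S_j − S_{j-1},    Im(Z_j) = 2 S_{j-2} − S_{j-1} − Q_j

(with the obvious j = 0, 1 special cases). The package implements the full
chain — impedance models (CPE / R / C networks, tabulated spectra),
multitone synthesis, a behavioral ADC (noise, jitter, DC offset, midtread
quantization), float and bit-true fixed-point demodulation, the exact
recovery, resistor calibration — plus the noise/SNR analysis (closed-form,
exact per-sample weight accounting, and Monte Carlo), reference estimators
(single-tone sweep, single-bin Fourier correlation) and the cost model, and
a small CLI (`inst/cli/bisdemod`).

## Worked example

Eight tones from 250 kHz down to 1953.125 Hz (1 MHz ADC clock), driving the
packaged tuna-muscle reference spectrum; one noiseless 512-sample record:

```r
library(bisdemod)

grid   <- build_grid(f0 = 250e3, nf = 8)
model  <- tuna_reference_model()
stream <- sample_adc(model, grid)          # ideal ADC, one global period
est    <- estimate_spectrum(stream)        # demodulate + exact alias recovery
est
#> Recovered impedance spectrum (8 tones)
#>  frequency_hz   re_ohm     im_ohm modulus_ohm  phase_rad
#>    250000.000 234.9133  -17.42535    235.5587 -0.0740422
#>    125000.000 241.4572  -20.62855    242.3368 -0.0852266
#>     62500.000 249.7080  -26.07362    251.0656 -0.1040394
#>     31250.000 260.2114  -34.08702    262.4346 -0.1302557
#>     15625.000 273.2795  -45.80039    277.0909 -0.1660522
#>      7812.500 288.9428  -64.10769    295.9692 -0.2183331
#>      3906.250 307.3254  -95.27469    321.7548 -0.3006170
#>      1953.125 329.1229 -152.00845    362.5306 -0.4326722
```

Modulus and phase reproduce the reference table to machine precision
(`max` relative error ≈ 1.6e-14): the aliasing recursion is an exact
inverse, and on noiseless coherent samples the accumulator averages equal
the analytic mixture. The same run with Gaussian noise shows the estimator's
1/f variance growth and, for a tissue-like CPE load (alpha = 1/2), a
per-tone SNR that stays flat because the impedance rises at exactly the rate
the accumulators get noisier:

```r
mc <- monte_carlo_variance(model, grid, sigma = 0.5, trials = 1000, seed = 42)
mc$norm_var_re          # doubles per stage toward low frequency
cost_model("multi_coherent", 8, 250e3)
#> Method multi_coherent  : acquisition 128/f0 s (= 0.000512 s), 510 additions, 0 multiplications
```

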