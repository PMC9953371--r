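# radarvitals

Non-contact vital-signs (NCVS) monitoring with a continuous-wave (CW)
Doppler radar, in R. The package is for signal-processing researchers and
biomedical engineers who want to simulate, demodulate and evaluate a
quadrature radar vital-signs chain end to end: it generates physically
modeled I/Q baseband records of a breathing, heart-beating subject,
recovers the chest-motion phase by arctangent demodulation, estimates
respiration rate (RR) and heart rate (HR) in BPM by band-limited spectral
peak finding, scores waveform quality, and reproduces a clinical-trial
style error analysis on synthetic patient cohorts.

## The model and the method

Periodic chest motion produces no net Doppler shift; it phase-modulates
the reflected carrier. With respiration displacement *x(t)* and heartbeat
displacement *y(t)*, the quadrature baseband channels are

    I = A cos(θ + 4π(x + y)/λ + Δφ) + V_I + n_I
    Q = A g sin(θ + 4π(x + y)/λ + Δφ + ε) + V_Q + n_Q

where θ = 4π·d₀/λ is the path phase at standoff d₀, Δφ is oscillator phase
noise, V are DC offsets, g and ε channel imbalances, n thermal noise. At
2.4 GHz, λ = 12.5 cm — a single-channel receiver loses all sensitivity
every λ/4 = 3.125 cm of distance (*null points*), which is exactly what
the four-quadrant arctangent φ = atan2(Q, I) avoids: after unwrapping and
streaming DC removal (8 samples per 0.04 s update at 200 Hz / 25 Hz), the
phase is proportional to chest displacement at any distance. RR and HR are
read off as the interpolated peak of the zero-padded autocorrelation power
spectrum inside 0.05–0.5 Hz (respiration) and 0.8–2 Hz (heart) bands.

## Worked example

Simulate one subject (RR 16 breaths/min, HR 78 beats/min, moderate noise),
demodulate, and stream per-tick estimates:

```r
library(radarvitals)

cfg     <- radar_config()                      # 2.4 GHz, 200 Hz, 1.3 m
profile <- vital_profile(rr_bpm = 16, hr_bpm = 78)
noise   <- noise_spec(thermal_std = 1e-4, phase_walk_std = 1e-3, seed = 42)

rates <- synthesize_quadrature(cfg, profile, noise, duration = 60) |>
  arctan_demodulate() |>
  remove_dc_streaming(cfg) |>
  estimate_rates_streaming(cfg, window_length = 30)

post <- dplyr::filter(rates, t_s >= 30)        # past the warm-up window
c(rr = median(post$rr_bpm), hr = median(post$hr_bpm))
#>       rr       hr
#> 15.98663 77.98046
```

The medians land within 0.02 BPM of the simulated truth: the 30 s analysis
window alone would only resolve 2 BPM, and the sub-bin peak interpolation
closes that gap. A small synthetic cohort, run through the same pipeline
and summarized the way trial results are reported:

```r
res <- generate_cohort(5, seed = 2) |> run_cohort(duration = 60)
glance(res)
#> # A tibble: 1 × 7
#>       n rr_median_error rr_sd_error rr_median_abs_error hr_median_error ...
#> 1     5         -0.0126     0.00306              0.0126        0.000457

error_stats(res, group_by = "gender")
#> # A tibble: 4 × 9
#>   metric   group      n    median      sd     min       q1       q3      max
#> 1 hr_error female     3  0.000457 0.0166  -0.0250 -0.0122   0.00337  0.00628
#> 2 hr_error male       2  0.0127   0.0408  -0.0162 -0.00173  0.0271   0.0416
#> 3 rr_error female     3 -0.0126   0.00141 -0.0147 -0.0136  -0.0123  -0.0120
#> 4 rr_error male       2 -0.0155   0.00511 -0.0192 -0.0174  -0.0137  -0.0119
```

Waveform quality (the posture check an operator does by eye — combined I/Q
swing must exceed 3 mV):

```r
rec <- synthesize_quadrature(radar_config(amplitude = 4e-3),
                             vital_profile(resp_amplitude = 12e-3),
                             noise_spec(), duration = 30)
posture_quality(rec)
#> # A tibble: 1 × 4
#>   i_swing q_swing combined label
#> 1 0.00716 0.00388  0.00576 Good
```

`autoplot()` methods draw I/Q traces, demodulated phase and streaming rate
series; `plot_error_boxplots()` draws grouped error boxplots.

## Command line

A thin CLI wraps the same functions (`inst/cli/radarvitals`, installed
under the package's `cli/` directory):

```sh
Rscript inst/cli/radarvitals simulate --rr 15 --hr 72 --duration 120 --seed 1 --out iq.csv
Rscript inst/cli/radarvitals demod    --input iq.csv --out phase.csv
Rscript inst/cli/radarvitals estimate --input phase.csv --window 30 \
        --rr-band 0.05:0.5 --hr-band 0.8:2.0 --out rates.csv
Rscript inst/cli/radarvitals quality  --input iq.csv --threshold-mv 3
Rscript inst/cli/radarvitals trial    --n 20 --seed 1 --duration 120 --out results.csv
Rscript inst/cli/radarvitals stats    --input results.csv --group-by gender
```

Every file-writing run emits a `<out>.manifest.json` (seed, options,
package version, timestamp) for bit-identical reproduction.

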