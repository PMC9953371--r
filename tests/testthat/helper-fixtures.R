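# Fixtures are generated in code; nothing is read from disk.

# a tone wrapped as a phase record, fs in Hz, duration in s
tone_phase <- function(freq_hz, duration = 60, fs = 200, amp = 1, phi = 0) {
  t <- (0:(duration * fs - 1)) / fs
  as_phase_record(amp * sin(2 * pi * freq_hz * t + phi), fs, dc_removed = TRUE)
}

# white-noise phase record under a fixed seed
noise_phase <- function(duration = 60, fs = 200, sd = 1, seed = 1) {
  withr::with_seed(seed, as_phase_record(rnorm(duration * fs, 0, sd), fs,
                                         dc_removed = TRUE))
}

# full demodulation chain: synthesize -> arctan -> streaming DC removal
demod_chain <- function(config, profile, noise = noise_spec(), duration = 60) {
  synthesize_quadrature(config, profile, noise, duration) |>
    arctan_demodulate() |>
    remove_dc_streaming(config)
}

# the constructed outlier subject: true HR at the 2 Hz band edge plus a
# 4th respiration harmonic inside the heart band (RR 18 BPM -> 1.2 Hz)
outlier_profile <- function(harmonic_weight = 0.05, hr_bpm = 120) {
  vital_profile(rr_bpm = 18, hr_bpm = hr_bpm,
                resp_harmonic_weights = c(1, 0, 0, harmonic_weight))
}
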