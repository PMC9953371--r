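test_that("band constructors carry the system defaults and reject bad edges", {
  expect_equal(band_combined()[c("low", "high")], list(low = 0.05, high = 2.0))
  expect_equal(band_respiration()[c("low", "high")], list(low = 0.05, high = 0.5))
  expect_equal(band_heart()[c("low", "high")], list(low = 0.8, high = 2.0))
  expect_equal(band_heart(high = 2.5)$high, 2.5)
  expect_error(band_heart(high = 3), "not supported")
  expect_error(band_spec(0.5, 0.5))
  expect_error(band_spec(-0.1, 1))
})

test_that("hz_to_bpm converts and guards its domain", {
  expect_identical(hz_to_bpm(2), 120)
  expect_identical(hz_to_bpm(0), 0)
  expect_identical(hz_to_bpm(2.5), 150)
  expect_error(hz_to_bpm(-1))
})

test_that("bandpass passes in-band tones, kills DC and attenuates out-of-band", {
  fs <- 200
  tone <- tone_phase(0.25, duration = 60, fs = fs)
  out <- bandpass(tone, band_respiration())
  mid <- out$phase_rad[(10 * fs):(50 * fs)]
  expect_equal(max(abs(mid)), 1, tolerance = 0.02)
  # constant maps to exactly zero
  const <- as_phase_record(rep(2.2, 4000), fs)
  expect_true(all(bandpass(const, band_combined())$phase_rad == 0))
  # 5 Hz through the 0.05-2 Hz band: >= 20 dB down
  hi <- tone_phase(5, duration = 60, fs = fs)
  hi_out <- bandpass(hi, band_combined())$phase_rad[(10 * fs):(50 * fs)]
  expect_lt(20 * log10(max(abs(hi_out))), -20)
  expect_error(bandpass(tone, band_spec(0.5, 150)), "Nyquist")
})

test_that("spectral_rate recovers pure tones to sub-bin accuracy", {
  expect_equal(spectral_rate(tone_phase(0.25), band_respiration()), 15,
               tolerance = 0.2 / 15)
  expect_equal(spectral_rate(tone_phase(1.2), band_heart()), 72,
               tolerance = 0.5 / 72)
})

test_that("sub-bin interpolation beats the raw 2 BPM bin on a fine tone grid", {
  # 30 s window: raw DFT bin = 2 BPM; interpolation must stay under 0.2
  for (f in seq(0.18, 0.45, by = 0.0317)) {
    est <- spectral_rate(tone_phase(f, duration = 30, phi = 1.1),
                         band_respiration())
    expect_lt(abs(est - f * 60), 0.2)
  }
  for (f in seq(0.95, 1.95, by = 0.117)) {
    est <- spectral_rate(tone_phase(f, duration = 30, phi = 0.3), band_heart())
    expect_lt(abs(est - f * 60), 0.2)
  }
})

test_that("white noise yields no detected rate", {
  ph <- noise_phase(duration = 60, seed = 1)
  expect_true(is.na(spectral_rate(ph, band_respiration())))
  expect_true(is.na(spectral_rate(ph, band_heart())))
})

test_that("too-short records are rejected", {
  expect_error(spectral_rate(tone_phase(0.3, duration = 4), band_respiration()),
               "short")
})

test_that("harmonic_mask zeroes respiration multiples inside the heart band only", {
  sp <- tibble::tibble(freq_hz = seq(0, 2.5, by = 0.005), power = 1)
  out <- harmonic_mask(sp, rr_bpm = 18, hr_band = band_heart())
  zeroed <- out$freq_hz[out$power == 0]
  for (f0 in c(0.9, 1.2, 1.5, 1.8)) {
    expect_true(any(abs(zeroed - f0) < 1e-9))
  }
  near_harmonic <- rowSums(abs(outer(zeroed, c(0.9, 1.2, 1.5, 1.8), "-")) <=
                             0.03 + 1e-9) > 0
  expect_true(all(near_harmonic))
  expect_true(all(out$power[out$freq_hz < 0.8 - 1e-9] == 1))
  expect_true(all(out$power[out$freq_hz > 2.0 + 1e-9] == 1))
  # harmonics all outside the band: nothing changes (RR 25 BPM -> 0.4167 Hz;
  # multiples 0.833, 1.25, 1.667, 2.083 -- use a band that dodges them)
  nb <- band_spec(1.30, 1.60, "heart")
  out2 <- harmonic_mask(tibble::tibble(freq_hz = seq(1.3, 1.6, by = 0.005),
                                       power = 1), 25, nb)
  expect_true(all(out2$power == 1))
})

test_that("masking respiration harmonics rescues a contaminated heart estimate", {
  cfg <- radar_config()
  # strong 4th harmonic of RR 18 BPM at 1.2 Hz; true HR nearby at 76 BPM
  prof <- vital_profile(rr_bpm = 18, hr_bpm = 76,
                        resp_harmonic_weights = c(1, 0, 0, 0.12))
  ph <- demod_chain(cfg, prof, duration = 60)
  unmasked <- spectral_rate(ph, band_heart())
  masked <- spectral_rate(ph, band_heart(), mask_rr_bpm = 18)
  expect_gt(abs(unmasked - 76), 3)     # harmonic captured the peak
  expect_lt(abs(masked - 76), 0.5)     # mask restores the true heartbeat
  expect_lt(abs(masked - 76), abs(unmasked - 76))
})

test_that("streaming estimator ticks at the refresh cadence with NA warm-up", {
  cfg <- radar_config()
  ph <- demod_chain(cfg, vital_profile(), duration = 40)
  rs <- estimate_rates_streaming(ph, cfg, window_length = 30)
  expect_equal(unique(round(diff(rs$t_s), 10)), 0.04)
  expect_true(all(is.na(rs$rr_bpm[rs$t_s < 30])))
  post <- rs[rs$t_s >= 30, ]
  expect_equal(nrow(post), floor((40 - 30) * 25) + 1)
  expect_equal(attr(rs, "window_length"), 30)
})

test_that("streaming estimates are stable and accurate on a stationary subject", {
  cfg <- radar_config()
  ph <- demod_chain(cfg, vital_profile(rr_bpm = 15, hr_bpm = 72),
                    noise_spec(thermal_std = 5e-5, phase_walk_std = 5e-4,
                               seed = 8), duration = 120)
  rs <- estimate_rates_streaming(ph, cfg, window_length = 30)
  post <- rs[rs$t_s >= 30, ]
  expect_lt(sd(post$rr_bpm, na.rm = TRUE), 0.2)
  expect_lt(sd(post$hr_bpm, na.rm = TRUE), 1)
  expect_lt(abs(median(post$rr_bpm, na.rm = TRUE) - 15), 0.2)
  expect_lt(abs(median(post$hr_bpm, na.rm = TRUE) - 72), 0.5)
})

test_that("decimated streaming path agrees with the full-rate batch estimator", {
  cfg <- radar_config()
  ph <- demod_chain(cfg, vital_profile(rr_bpm = 17.3, hr_bpm = 84.2),
                    noise_spec(thermal_std = 1e-4, phase_walk_std = 1e-3,
                               seed = 5), duration = 90)
  rs <- estimate_rates_streaming(ph, cfg, window_length = 30)
  post <- rs[rs$t_s >= 30, ]
  batch_rr <- spectral_rate(ph, band_respiration())
  batch_hr <- spectral_rate(ph, band_heart())
  expect_equal(median(post$rr_bpm, na.rm = TRUE), batch_rr, tolerance = 0.02)
  expect_equal(median(post$hr_bpm, na.rm = TRUE), batch_hr, tolerance = 0.02)
})

test_that("window validation matches the three-cycle rule", {
  cfg <- radar_config()
  ph <- demod_chain(cfg, vital_profile(), duration = 40)
  expect_error(estimate_rates_streaming(ph, cfg, window_length = 50),
               "not longer")
  expect_error(estimate_rates_streaming(ph, cfg, window_length = 2),
               "cycles")
})

test_that("a 2 Hz heart-band cutoff loses a 120 BPM subject; 2.5 Hz recovers it", {
  cfg <- radar_config()
  ph <- demod_chain(cfg, outlier_profile(), duration = 60)
  hr_low_cutoff <- spectral_rate(ph, band_heart(high = 2.0))
  hr_high_cutoff <- spectral_rate(ph, band_heart(high = 2.5))
  expect_gt(abs(hr_low_cutoff - 120), 5)
  expect_lte(abs(hr_high_cutoff - 120), 3)
})
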