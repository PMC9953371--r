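#' Zero-phase band-pass filtering of a phase record
#'
#' Band-limits the demodulated phase to a [band_spec()]. The input is
#' demeaned, then passed through an order-4 Butterworth high-pass at
#' `band$low` and an order-4 Butterworth low-pass at `band$high`, each
#' applied forward and backward (zero phase distortion, effective order 8
#' per section). The cascade of two order-4 sections is used instead of a
#' single order-8 band-pass polynomial because the latter is numerically
#' unstable at the very small normalized low edge (0.05 Hz at a 200 Hz
#' sample rate). DC is rejected exactly: a constant record maps to zero.
#'
#' @param phase A `phase_record`.
#' @param band A [band_spec()]; `high` must not exceed the Nyquist
#'   frequency.
#' @return A filtered `phase_record` (attribute `band` records the band).
#' @examples
#' rec <- synthesize_quadrature(radar_config(), vital_profile(), duration = 20)
#' ph <- arctan_demodulate(rec) |> bandpass(band_respiration())
#' @export
bandpass <- function(phase, band) {
  stopifnot(inherits(phase, "phase_record"), inherits(band, "band_spec"))
  fs <- sample_rate(phase)
  if (band$high > fs / 2) abort("`band$high` exceeds the Nyquist frequency.")
  y <- filter_band(phase$phase_rad, fs, band$low, band$high)
  out <- new_phase_record(phase$t_s, y, fs,
                          dc_removed = isTRUE(attr(phase, "dc_removed")))
  attr(out, "band") <- band
  out
}

# demean + zero-phase HP/LP cascade on a bare numeric vector
#' @noRd
filter_band <- function(x, fs, low, high) {
  y <- x - mean(x)
  if (low > 0) {
    hp <- signal::butter(4, low / (fs / 2), type = "high")
    y <- signal::filtfilt(hp, y)
  }
  if (high < fs / 2) {
    lp <- signal::butter(4, high / (fs / 2), type = "low")
    y <- signal::filtfilt(lp, y)
  }
  y
}

#' Power spectrum of a phase record
#'
#' Zero-padded periodogram `|FFT(x)|^2 / N` of the demeaned signal --
#' identically the DFT of the biased (positive-semidefinite)
#' autocorrelation estimate, which is the estimator the rate extractor
#' peaks over. Padding to at least `nfft_factor` times the record length
#' gives the dense frequency grid needed for sub-bin peak interpolation.
#'
#' @param phase A `phase_record` (typically already band-passed).
#' @param nfft_factor Minimum zero-padding factor (default 8; the FFT
#'   length is the next power of two).
#' @return A tibble with columns `freq_hz`, `power` covering 0..Nyquist.
#' @examples
#' rec <- synthesize_quadrature(radar_config(), vital_profile(), duration = 30)
#' sp <- arctan_demodulate(rec) |>
#'   bandpass(band_respiration()) |>
#'   power_spectrum()
#' @export
power_spectrum <- function(phase, nfft_factor = 8) {
  stopifnot(inherits(phase, "phase_record"))
  ps <- periodogram(phase$phase_rad, sample_rate(phase), nfft_factor)
  tibble(freq_hz = ps$freq, power = ps$power)
}

#' @noRd
periodogram <- function(x, fs, nfft_factor = 8) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(max(2, nfft_factor * n)))
  sp <- fft(c(x, rep(0, nfft - n)))
  half <- seq_len(nfft %/% 2 + 1L)
  list(freq = (half - 1) * fs / nfft,
       power = (Mod(sp[half])^2) / n,
       nfft = nfft)
}

#' Suppress respiration harmonics inside the heart band
#'
#' Chest motion is not sinusoidal; harmonics of the respiration fundamental
#' can land inside the heart band and out-power the true heartbeat line.
#' Given the current respiration estimate, this zeroes spectrum bins within
#' `tol_hz` of every integer multiple of `rr_bpm / 60` that falls inside
#' `hr_band`, so the heart peak search skips them.
#'
#' @param spectrum A tibble with columns `freq_hz`, `power` (as from
#'   [power_spectrum()]).
#' @param rr_bpm Current respiration estimate in BPM (> 0).
#' @param hr_band The heart [band_spec()].
#' @param tol_hz Half-width of each notch in Hz (default 0.03).
#' @return The spectrum tibble with masked bins set to zero power.
#' @examples
#' sp <- tibble::tibble(freq_hz = seq(0, 3, by = 0.01), power = 1)
#' masked <- harmonic_mask(sp, rr_bpm = 18, hr_band = band_heart())
#' @export
harmonic_mask <- function(spectrum, rr_bpm, hr_band, tol_hz = 0.03) {
  stopifnot(is.data.frame(spectrum), inherits(hr_band, "band_spec"))
  check_number(rr_bpm, "rr_bpm", 0, strict = TRUE)
  f0 <- rr_bpm / 60
  k <- seq.int(max(1, floor(hr_band$low / f0)), ceiling(hr_band$high / f0))
  notch <- k * f0
  notch <- notch[notch >= hr_band$low - tol_hz & notch <= hr_band$high + tol_hz]
  if (length(notch)) {
    hit <- vapply(spectrum$freq_hz,
                  function(f) any(abs(f - notch) <= tol_hz), logical(1))
    spectrum$power[hit & spectrum$freq_hz >= hr_band$low &
                     spectrum$freq_hz <= hr_band$high] <- 0
  }
  spectrum
}

# Core single-window estimator on a bare numeric vector already limited to
# the band (or close to it). Returns BPM or NA (no-rate-detected).
# Detection gate: the raw zero-padded periodogram of pure noise has a
# max/median ratio well above any fixed small threshold, so presence is
# gated on a 4-segment Bartlett-averaged spectrum (max in-band power >= 3x
# the in-band median) before the full-resolution periodogram is used for
# peak location and 3-point log-parabolic interpolation.
#' @noRd
rate_core <- function(x, fs, band, nfft_factor = 8, prominence = 3,
                      mask_rr_bpm = NULL, mask_tol_hz = 0.03) {
  n <- length(x)
  if (n < 8L) return(NA_real_)
  # a peak is only credible with >= 3 cycles in the window: the search
  # floor rises to 3/duration when the band edge asks for fewer
  low_eff <- max(band$low, 3 / (n / fs))
  if (low_eff >= band$high) {
    abort(sprintf(
      "window too short: %.3g s holds < 3 cycles of every in-band frequency.",
      n / fs))
  }
  band <- band_spec(low_eff, band$high, band$label)
  x <- x - mean(x)
  if (all(abs(x) < .Machine$double.eps * 10)) return(NA_real_)

  # presence gate on a segment-averaged spectrum -- averaging is what
  # makes a fixed 3x-median threshold discriminate tones from noise. Use
  # the most segments (8, 6 or 4) that still leave >= 3 spectral
  # resolution cells inside the band, so a real tone's main lobe cannot
  # swamp the in-band median; skip the gate for very short windows.
  bw <- band$high - band$low
  nseg <- 4L
  for (m in c(8L, 6L)) {
    if (n %/% m >= 16L && bw * (n / m) / fs >= 3) { nseg <- m; break }
  }
  seg_len <- n %/% nseg
  if (seg_len >= 16L && bw * seg_len / fs >= 2) {
    acc <- NULL
    for (s in seq_len(nseg)) {
      seg <- x[((s - 1L) * seg_len + 1L):(s * seg_len)]
      ps <- periodogram(seg, fs, 4)
      acc <- if (is.null(acc)) ps$power else acc + ps$power
    }
    freq_c <- periodogram(x[seq_len(seg_len)], fs, 4)$freq
    inb <- freq_c >= band$low & freq_c <= band$high
    if (!any(inb)) return(NA_real_)
    pk <- max(acc[inb])
    med <- median(acc[inb])
    if (!(med > 0) || pk < prominence * med) return(NA_real_)
  }

  ps <- periodogram(x, fs, nfft_factor)
  pw <- ps$power
  if (!is.null(mask_rr_bpm) && is.finite(mask_rr_bpm) && mask_rr_bpm > 0) {
    masked <- harmonic_mask(tibble(freq_hz = ps$freq, power = pw),
                            mask_rr_bpm, band, mask_tol_hz)
    pw <- masked$power
  }
  inb <- which(ps$freq >= band$low & ps$freq <= band$high)
  if (!length(inb)) return(NA_real_)
  pin <- pw[inb]
  if (max(pin) <= 0) return(NA_real_)
  # ties broken toward the lower frequency (which.max takes the first)
  k <- inb[which.max(pin)]
  f_hat <- ps$freq[k]
  # 3-point log-parabolic interpolation on the dense grid
  if (k > 1L && k < length(pw) && pw[k - 1L] > 0 && pw[k + 1L] > 0 &&
      pw[k] > pw[k - 1L] && pw[k] > pw[k + 1L]) {
    la <- log(pw[k - 1L]); lb <- log(pw[k]); lc <- log(pw[k + 1L])
    denom <- la - 2 * lb + lc
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (la - lc) / denom
      if (abs(delta) <= 1) f_hat <- f_hat + delta * fs / ps$nfft
    }
  }
  hz_to_bpm(f_hat)
}

#' Spectral rate estimate from a phase record
#'
#' Batch estimator of the dominant periodic rate inside a band: the record
#' is band-pass filtered ([bandpass()]), demeaned, its biased
#' autocorrelation power spectrum is computed on a zero-padded grid
#' (>= `nfft_factor` times the record length), the largest in-band peak is
#' located, refined by three-point log-parabolic interpolation, and
#' converted to BPM. If no in-band peak stands out from the noise floor
#' (segment-averaged peak below `prominence` times the in-band median) the
#' record is declared rate-free and `NA` is returned.
#'
#' A rate is only credible if the window holds at least three of its
#' cycles, so for short records the peak-search floor is raised from
#' `band$low` to `3 / duration`; a record too short to hold three cycles
#' of any in-band frequency is an error.
#'
#' @param phase A `phase_record` at least `3 / band$high` seconds long.
#' @param band A [band_spec()].
#' @param nfft_factor Zero-padding factor for the spectrum (default 8).
#' @param prominence Detection threshold as a multiple of the in-band
#'   median of the segment-averaged spectrum (default 3).
#' @param mask_rr_bpm If non-`NULL`, zero spectrum bins at harmonics of
#'   this respiration rate inside `band` before peak finding (see
#'   [harmonic_mask()]); default off.
#' @return Rate in BPM, or `NA` if no rate is detected.
#' @examples
#' rec <- synthesize_quadrature(radar_config(),
#'                              vital_profile(rr_bpm = 15, hr_bpm = 72),
#'                              duration = 60)
#' ph <- remove_dc_streaming(arctan_demodulate(rec), radar_config())
#' spectral_rate(ph, band_respiration())  # ~15 BPM
#' spectral_rate(ph, band_heart())        # ~72 BPM
#' @export
spectral_rate <- function(phase, band, nfft_factor = 8, prominence = 3,
                          mask_rr_bpm = NULL) {
  stopifnot(inherits(phase, "phase_record"), inherits(band, "band_spec"))
  fs <- sample_rate(phase)
  dur <- nrow(phase) / fs
  if (dur < 3 / band$high) {
    abort(sprintf("record too short: %.3g s holds fewer than 3 cycles of %g Hz.",
                  dur, band$high))
  }
  y <- filter_band(phase$phase_rad, fs, band$low, band$high)
  rate_core(y, fs, band, nfft_factor, prominence, mask_rr_bpm)
}

#' Per-refresh-tick streaming RR/HR estimation
#'
#' Mirrors the deployed system's update loop: estimates are refreshed every
#' `1 / refresh_rate` seconds (0.04 s at the defaults) from the trailing
#' `window_length` seconds of phase. Each band is zero-phase band-pass
#' filtered once over the whole record and then decimated (the band filter
#' itself is the anti-alias filter) before the per-tick spectra, which
#' makes per-tick estimation over minutes of signal cheap without changing
#' the estimates beyond the spectral resolution. Ticks earlier than one
#' full window are emitted as `NA` (warm-up).
#'
#' @param phase A `phase_record` longer than `window_length`, DC-removed.
#' @param config A [radar_config()] supplying the refresh cadence.
#' @param rr_band,hr_band Respiration and heart [band_spec()]s.
#' @param window_length Trailing analysis window in s (default 30; must
#'   hold at least 3 cycles of some in-band frequency of each band).
#' @param harmonic_suppression If `TRUE`, each tick's respiration estimate
#'   masks its harmonics out of that tick's heart spectrum (default
#'   `FALSE`).
#' @param prominence Detection threshold passed to the core estimator.
#' @return A `rate_series` tibble with columns `t_s`, `rr_bpm`, `hr_bpm`
#'   (one row per refresh tick; `NA` during warm-up or when no rate is
#'   detected); attributes `refresh_rate` and `window_length`.
#' @examples
#' rec <- synthesize_quadrature(radar_config(), vital_profile(), duration = 40)
#' ph <- remove_dc_streaming(arctan_demodulate(rec), radar_config())
#' rs <- estimate_rates_streaming(ph, radar_config(), window_length = 30)
#' @export
estimate_rates_streaming <- function(phase, config,
                                     rr_band = band_respiration(),
                                     hr_band = band_heart(),
                                     window_length = 30,
                                     harmonic_suppression = FALSE,
                                     prominence = 3) {
  stopifnot(inherits(phase, "phase_record"), inherits(config, "radar_config"))
  check_number(window_length, "window_length", 0, strict = TRUE)
  fs <- sample_rate(phase)
  dur <- nrow(phase) / fs
  if (window_length < 3 / rr_band$high) {
    abort(sprintf("window_length %.3g s holds fewer than 3 cycles of %g Hz.",
                  window_length, rr_band$high))
  }
  if (dur <= window_length) abort("record is not longer than `window_length`.")

  prep <- function(band) {
    y <- filter_band(phase$phase_rad, fs, band$low, band$high)
    dec <- max(1L, floor(fs / max(8, 4 * band$high)))
    idx <- seq.int(1L, length(y), by = dec)
    list(y = y[idx], t = phase$t_s[idx], fs = fs / dec)
  }
  pr <- prep(rr_band)
  ph_ <- prep(hr_band)

  ticks <- seq_len(floor(dur * config$refresh_rate)) / config$refresh_rate
  t0 <- phase$t_s[1]
  rr <- rep(NA_real_, length(ticks))
  hr <- rep(NA_real_, length(ticks))
  for (j in seq_along(ticks)) {
    tk <- ticks[j]
    if (tk < window_length) next
    wr <- pr$y[pr$t > t0 + tk - window_length - 1e-9 & pr$t <= t0 + tk + 1e-9]
    wh <- ph_$y[ph_$t > t0 + tk - window_length - 1e-9 & ph_$t <= t0 + tk + 1e-9]
    rr[j] <- rate_core(wr, pr$fs, rr_band, prominence = prominence)
    hr[j] <- rate_core(wh, ph_$fs, hr_band, prominence = prominence,
                       mask_rr_bpm = if (harmonic_suppression) rr[j] else NULL)
  }
  out <- new_tibble(tibble(t_s = t0 + ticks, rr_bpm = rr, hr_bpm = hr),
                    nrow = length(ticks),
                    class = c("rate_series", "tbl_df", "tbl", "data.frame"))
  attr(out, "refresh_rate") <- config$refresh_rate
  attr(out, "window_length") <- window_length
  attr(out, "sample_rate") <- config$refresh_rate
  out
}
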