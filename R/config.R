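#' Radar system configuration
#'
#' Collects the geometry and timing constants of the CW Doppler sensor: the
#' carrier, the derived free-space wavelength, the raw sample rate of the
#' quadrature baseband stream, the estimate refresh rate, the antenna-to-chest
#' standoff distance and the received-signal amplitude (an abstract scaling
#' standing in for the TX/RX gain product of the radio front end).
#'
#' Defaults describe a 2.4 GHz carrier (wavelength 12.5 cm with the rounded
#' propagation speed of 3e8 m/s), a 200 Hz sample rate refreshed at 25 Hz
#' (8 samples per update), a 1.3 m standoff and a 1 mV received amplitude.
#' The rounded propagation speed is deliberate: it makes the wavelength and
#' the quarter-wavelength null spacing come out at the textbook 12.5 cm and
#' 3.125 cm exactly; pass `propagation_speed = 299792458` for the physical
#' value.
#'
#' @param carrier_frequency Carrier frequency in Hz.
#' @param propagation_speed Propagation speed in m/s.
#' @param sample_rate Baseband sample rate in Hz.
#' @param refresh_rate Estimate update rate in Hz; must divide `sample_rate`.
#' @param distance Antenna-to-subject distance d0 in m.
#' @param amplitude Received-signal amplitude in V.
#'
#' @return A `radar_config` list with the fields above plus the derived
#'   `wavelength` (m) and `samples_per_refresh`.
#' @examples
#' cfg <- radar_config()
#' cfg$wavelength        # 0.125 m
#' cfg$samples_per_refresh  # 8
#' @export
radar_config <- function(carrier_frequency = 2.4e9,
                         propagation_speed = 3.0e8,
                         sample_rate = 200,
                         refresh_rate = 25,
                         distance = 1.3,
                         amplitude = 1e-3) {
  check_number(carrier_frequency, "carrier_frequency", 0, strict = TRUE)
  check_number(propagation_speed, "propagation_speed", 0, strict = TRUE)
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  check_number(refresh_rate, "refresh_rate", 0, strict = TRUE)
  check_number(distance, "distance", 0, strict = TRUE)
  check_number(amplitude, "amplitude", 0, strict = TRUE)
  spr <- sample_rate / refresh_rate
  if (abs(spr - round(spr)) > 1e-9) {
    abort("`sample_rate` must be an integer multiple of `refresh_rate`.")
  }
  structure(
    list(
      carrier_frequency = carrier_frequency,
      propagation_speed = propagation_speed,
      wavelength = propagation_speed / carrier_frequency,
      sample_rate = sample_rate,
      refresh_rate = refresh_rate,
      samples_per_refresh = as.integer(round(spr)),
      distance = distance,
      amplitude = amplitude
    ),
    class = "radar_config"
  )
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  carrier     %.4g Hz (wavelength %.4g m)\n",
              x$carrier_frequency, x$wavelength))
  cat(sprintf("  sampling    %g Hz, refresh %g Hz (%d samples/update)\n",
              x$sample_rate, x$refresh_rate, x$samples_per_refresh))
  cat(sprintf("  distance    %g m, amplitude %g V\n", x$distance, x$amplitude))
  invisible(x)
}

#' Ground-truth physiology for a simulated subject
#'
#' The chest moves as the sum of a respiration displacement (a harmonic
#' series at the respiration fundamental, mm scale) and a smaller heartbeat
#' displacement (a pure sinusoid, sub-mm). `resp_harmonic_weights` gives the
#' relative amplitude of the k-th respiration harmonic; the default single
#' weight is a pure sinusoid. Non-trivial weights exist to reproduce the
#' interference mechanism where respiration harmonics land inside the heart
#' band and masquerade as a heartbeat.
#'
#' @param rr_bpm Respiration rate in breaths per minute.
#' @param hr_bpm Heart rate in beats per minute.
#' @param resp_amplitude Peak respiration chest displacement in m.
#' @param heart_amplitude Peak heartbeat chest displacement in m.
#' @param resp_harmonic_weights Relative amplitudes of respiration harmonics
#'   (first element = fundamental).
#' @param resp_phase,heart_phase Initial phases in rad.
#'
#' @return A `vital_profile` list.
#' @examples
#' vital_profile(rr_bpm = 15, hr_bpm = 72)
#' @export
vital_profile <- function(rr_bpm = 15,
                          hr_bpm = 72,
                          resp_amplitude = 4e-3,
                          heart_amplitude = 3e-4,
                          resp_harmonic_weights = 1.0,
                          resp_phase = 0,
                          heart_phase = 0) {
  check_number(rr_bpm, "rr_bpm", 0)
  check_number(hr_bpm, "hr_bpm", 0)
  check_number(resp_amplitude, "resp_amplitude", 0)
  check_number(heart_amplitude, "heart_amplitude", 0)
  if (!is.numeric(resp_harmonic_weights) || length(resp_harmonic_weights) < 1L ||
      any(!is.finite(resp_harmonic_weights))) {
    abort("`resp_harmonic_weights` must be a non-empty finite numeric vector.")
  }
  check_number(resp_phase, "resp_phase")
  check_number(heart_phase, "heart_phase")
  if (heart_amplitude >= resp_amplitude && resp_amplitude > 0) {
    warn("heart_amplitude >= resp_amplitude: unusual for chest-wall motion.")
  }
  structure(
    list(
      rr_bpm = rr_bpm, hr_bpm = hr_bpm,
      resp_amplitude = resp_amplitude, heart_amplitude = heart_amplitude,
      resp_harmonic_weights = resp_harmonic_weights,
      resp_phase = resp_phase, heart_phase = heart_phase
    ),
    class = "vital_profile"
  )
}

#' @export
print.vital_profile <- function(x, ...) {
  cat("<vital_profile>\n")
  cat(sprintf("  RR %g BPM (amp %g m, %d harmonic(s)), HR %g BPM (amp %g m)\n",
              x$rr_bpm, x$resp_amplitude, length(x$resp_harmonic_weights),
              x$hr_bpm, x$heart_amplitude))
  invisible(x)
}

#' Measurement corruption model
#'
#' Describes everything the ideal quadrature derivation ignores and the
#' simulator re-introduces: oscillator (VCO/PLL) phase noise modeled as a
#' Gaussian random walk, per-channel additive thermal noise, DC offsets,
#' amplitude imbalance between the Q and I channels, and quadrature phase
#' error. A `seed` makes a record bit-reproducible.
#'
#' @param phase_walk_std Std of the per-sample increments of the phase-noise
#'   random walk, rad.
#' @param thermal_std Per-channel additive white Gaussian noise std, V.
#' @param dc_offset_i,dc_offset_q Channel DC offsets, V.
#' @param gain_imbalance Q-vs-I amplitude ratio (1 = balanced).
#' @param quadrature_error Departure of the I/Q phase split from 90 degrees,
#'   rad.
#' @param seed Integer seed; `NULL` draws from the ambient RNG stream.
#'
#' @return A `noise_spec` list.
#' @examples
#' noise_spec()                       # ideal channel
#' noise_spec(thermal_std = 1e-4, seed = 7)
#' @export
noise_spec <- function(phase_walk_std = 0,
                       thermal_std = 0,
                       dc_offset_i = 0,
                       dc_offset_q = 0,
                       gain_imbalance = 1.0,
                       quadrature_error = 0,
                       seed = NULL) {
  check_number(phase_walk_std, "phase_walk_std", 0)
  check_number(thermal_std, "thermal_std", 0)
  check_number(dc_offset_i, "dc_offset_i")
  check_number(dc_offset_q, "dc_offset_q")
  check_number(gain_imbalance, "gain_imbalance", 0, strict = TRUE)
  check_number(quadrature_error, "quadrature_error")
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(
      phase_walk_std = phase_walk_std, thermal_std = thermal_std,
      dc_offset_i = dc_offset_i, dc_offset_q = dc_offset_q,
      gain_imbalance = gain_imbalance, quadrature_error = quadrature_error,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "noise_spec"
  )
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec>\n")
  cat(sprintf("  phase walk %g rad/sample, thermal %g V\n",
              x$phase_walk_std, x$thermal_std))
  cat(sprintf("  DC (%g, %g) V, gain imbalance %g, quad error %g rad, seed %s\n",
              x$dc_offset_i, x$dc_offset_q, x$gain_imbalance,
              x$quadrature_error,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Frequency band for rate extraction
#'
#' `band_spec()` builds an arbitrary band; `band_combined()`,
#' `band_respiration()` and `band_heart()` are the system defaults:
#' 0.05-2 Hz combined (the deployed filter range), 0.05-0.5 Hz for
#' respiration (RR below 30 BPM) and 0.8-2 Hz for heartbeat (HR below
#' 120 BPM; raise `high` to 2.5 Hz / 150 BPM to avoid clipping tachycardic
#' subjects at the band edge).
#'
#' @param low,high Band edges in Hz, `0 <= low < high`.
#' @param label One of `"respiration"`, `"heart"`, `"combined"`.
#' @return A `band_spec` list.
#' @examples
#' band_heart()
#' band_heart(high = 2.5)
#' @export
band_spec <- function(low, high, label = c("combined", "respiration", "heart")) {
  check_number(low, "low", 0)
  check_number(high, "high", 0, strict = TRUE)
  if (low >= high) abort("`low` must be < `high`.")
  label <- match.arg(label)
  structure(list(low = low, high = high, label = label), class = "band_spec")
}

#' @rdname band_spec
#' @export
band_combined <- function(low = 0.05, high = 2.0) {
  band_spec(low, high, "combined")
}

#' @rdname band_spec
#' @export
band_respiration <- function(low = 0.05, high = 0.5) {
  band_spec(low, high, "respiration")
}

#' @rdname band_spec
#' @export
band_heart <- function(low = 0.8, high = 2.0) {
  if (high > 2.5) abort("heart band `high` above 2.5 Hz (150 BPM) is not supported.")
  band_spec(low, high, "heart")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz (%g-%g BPM)\n",
              x$label, x$low, x$high, x$low * 60, x$high * 60))
  invisible(x)
}

#' Convert a frequency in Hz to beats/breaths per minute
#'
#' @param f Frequency in Hz, non-negative.
#' @return `f * 60`, in BPM.
#' @examples
#' hz_to_bpm(2)    # 120 BPM
#' hz_to_bpm(2.5)  # 150 BPM
#' @export
hz_to_bpm <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    abort("`f` must be finite and non-negative.")
  }
  f * 60
}
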