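#' @noRd
new_record <- function(df, class, sample_rate, ...) {
  out <- new_tibble(df, nrow = nrow(df), class = class)
  attr(out, "sample_rate") <- sample_rate
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Sample rate of a record
#'
#' @param x A record produced by this package (displacement, quadrature,
#'   phase or rate series).
#' @return Sample rate in Hz.
#' @export
sample_rate <- function(x) {
  sr <- attr(x, "sample_rate")
  if (is.null(sr)) abort("`x` carries no sample_rate attribute.")
  sr
}

#' Simulate chest-wall displacement
#'
#' The chest displacement is the sum of a respiration component
#' `x(t) = resp_amplitude * sum_k w_k sin(2 pi k f_r t + resp_phase)` (with
#' `f_r = rr_bpm/60` and harmonic weights `w_k`) and a heartbeat component
#' `y(t) = heart_amplitude * sin(2 pi f_h t + heart_phase)`. Both components
#' are retained separately so downstream demodulation can be checked against
#' the exact ground truth.
#'
#' @param profile A [vital_profile()].
#' @param sample_rate Sampling rate in Hz.
#' @param duration Record length in s.
#' @return A `displacement_record` tibble with columns `t_s`, `x_m`
#'   (respiration), `y_m` (heartbeat) and `displacement_m` (their sum), one
#'   row per sample starting at t = 0.
#' @examples
#' d <- chest_displacement(vital_profile(rr_bpm = 15), 200, 10)
#' max(abs(d$x_m))   # ~ resp_amplitude
#' @export
chest_displacement <- function(profile, sample_rate, duration) {
  stopifnot(inherits(profile, "vital_profile"))
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  check_number(duration, "duration", 0, strict = TRUE)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f_r <- profile$rr_bpm / 60
  f_h <- profile$hr_bpm / 60
  w <- profile$resp_harmonic_weights
  x <- rep(0, n)
  for (k in seq_along(w)) {
    if (w[k] != 0) {
      x <- x + w[k] * sin(2 * pi * k * f_r * t + profile$resp_phase)
    }
  }
  x <- profile$resp_amplitude * x
  y <- profile$heart_amplitude * sin(2 * pi * f_h * t + profile$heart_phase)
  new_record(
    tibble(t_s = t, x_m = x, y_m = y, displacement_m = x + y),
    c("displacement_record", "tbl_df", "tbl", "data.frame"),
    sample_rate
  )
}

#' Oscillator phase-noise random walk
#'
#' Cumulative sum of i.i.d. zero-mean Gaussian increments with std
#' `noise$phase_walk_std`, first element exactly 0 -- a stand-in for the
#' close-in phase noise of the VCO/PLL generating the carrier (the true
#' spectrum is hardware-specific; a random walk reproduces its low-frequency
#' concentration).
#'
#' @param noise A [noise_spec()]; `phase_walk_std` and `seed` are used.
#' @param n_samples Number of samples (>= 0).
#' @return Numeric vector of phase offsets in rad.
#' @examples
#' phase_noise_walk(noise_spec(phase_walk_std = 0.01, seed = 1), 5)
#' @export
phase_noise_walk <- function(noise, n_samples) {
  stopifnot(inherits(noise, "noise_spec"))
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 0) {
    abort("`n_samples` must be a single non-negative count.")
  }
  n <- as.integer(n_samples)
  if (n == 0L) return(numeric(0))
  if (noise$phase_walk_std == 0) return(rep(0, n))
  inc <- with_seed_maybe(noise$seed, rnorm(n - 1L, 0, noise$phase_walk_std))
  c(0, cumsum(inc))
}

#' Synthesize a corrupted quadrature baseband record
#'
#' Implements the phase-modulation measurement model of the CW Doppler
#' sensor. The round-trip path phase is `theta = 4 pi d0 / lambda`; periodic
#' chest motion adds `(4 pi / lambda) (x(t) + y(t))` and the oscillator adds
#' the random-walk term, giving the total phase `phi(t)`. The emitted
#' channels are
#' `I = A cos(phi) + dc_i + n_I` and
#' `Q = A g sin(phi + e) + dc_q + n_Q`
#' with amplitude `A`, gain imbalance `g`, quadrature error `e` and
#' independent white thermal noise per channel. The ground-truth
#' displacement record and total synthesis phase are attached as attributes
#' `truth` and `true_phase` for oracle checks.
#'
#' @param config A [radar_config()].
#' @param profile A [vital_profile()].
#' @param noise A [noise_spec()].
#' @param duration Record length in s (`duration * sample_rate >= 2`).
#' @return A `quadrature_record` tibble with columns `t_s`, `i_v`, `q_v`.
#' @examples
#' rec <- synthesize_quadrature(radar_config(), vital_profile(), duration = 10)
#' range(rec$i_v)
#' @export
synthesize_quadrature <- function(config, profile, noise = noise_spec(),
                                  duration = 60) {
  stopifnot(inherits(config, "radar_config"), inherits(profile, "vital_profile"),
            inherits(noise, "noise_spec"))
  check_number(duration, "duration", 0, strict = TRUE)
  n <- round(duration * config$sample_rate)
  if (n < 2) abort("duration * sample_rate must be at least 2 samples.")
  disp <- chest_displacement(profile, config$sample_rate, duration)
  theta <- 4 * pi * config$distance / config$wavelength
  draws <- with_seed_maybe(noise$seed, {
    inc <- if (noise$phase_walk_std > 0) {
      rnorm(n - 1L, 0, noise$phase_walk_std)
    } else {
      rep(0, n - 1L)
    }
    ni <- if (noise$thermal_std > 0) rnorm(n, 0, noise$thermal_std) else rep(0, n)
    nq <- if (noise$thermal_std > 0) rnorm(n, 0, noise$thermal_std) else rep(0, n)
    list(walk = c(0, cumsum(inc)), ni = ni, nq = nq)
  })
  phi <- theta + (4 * pi / config$wavelength) * disp$displacement_m + draws$walk
  a <- config$amplitude
  i_v <- a * cos(phi) + noise$dc_offset_i + draws$ni
  q_v <- a * noise$gain_imbalance * sin(phi + noise$quadrature_error) +
    noise$dc_offset_q + draws$nq
  new_record(
    tibble(t_s = disp$t_s, i_v = i_v, q_v = q_v),
    c("quadrature_record", "tbl_df", "tbl", "data.frame"),
    config$sample_rate,
    truth = disp, true_phase = phi, amplitude = a, theta = theta
  )
}

#' Null-point distances of a single-channel receiver
#'
#' A receiver that demodulates a single baseband channel loses phase
#' sensitivity wherever the round-trip path phase makes the carrier land on
#' an extremum of the cosine -- every quarter wavelength of standoff
#' distance. At 2.4 GHz (lambda = 12.5 cm) that is every 3.125 cm. The
#' quadrature arctangent receiver has no such nulls.
#'
#' @param config A [radar_config()].
#' @param max_distance Largest distance to enumerate, m.
#' @return A tibble with column `distance_m` (the arithmetic sequence
#'   `lambda/4, 2 lambda/4, ...` up to `max_distance`); the spacing is
#'   attached as attribute `spacing` and column `spacing_m`.
#' @examples
#' null_point_positions(radar_config(), 0.2)
#' @export
null_point_positions <- function(config, max_distance) {
  stopifnot(inherits(config, "radar_config"))
  check_number(max_distance, "max_distance", 0, strict = TRUE)
  spacing <- config$wavelength / 4
  d <- seq_len(floor(max_distance / spacing + 1e-9)) * spacing
  out <- tibble(distance_m = d, spacing_m = rep(spacing, length(d)))
  attr(out, "spacing") <- spacing
  out
}

#' Wrap raw I/Q samples as a quadrature record
#'
#' For data not produced by [synthesize_quadrature()] -- e.g. captures from
#' real hardware already in memory (use [read_quadrature()] for CSV files).
#'
#' @param i_v,q_v Equal-length numeric vectors of channel voltages, V.
#' @param sample_rate Sampling rate in Hz.
#' @return A `quadrature_record` tibble (`t_s` starts at 0).
#' @examples
#' as_quadrature_record(cos(1:100 / 10), sin(1:100 / 10), 200)
#' @export
as_quadrature_record <- function(i_v, q_v, sample_rate) {
  if (!is.numeric(i_v) || !is.numeric(q_v) || length(i_v) != length(q_v)) {
    abort("`i_v` and `q_v` must be numeric vectors of equal length.")
  }
  if (any(!is.finite(i_v)) || any(!is.finite(q_v))) {
    abort("channel samples must all be finite.")
  }
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  t <- (seq_along(i_v) - 1) / sample_rate
  new_record(tibble(t_s = t, i_v = i_v, q_v = q_v),
             c("quadrature_record", "tbl_df", "tbl", "data.frame"),
             sample_rate)
}

#' Wrap a raw phase series as a phase record
#'
#' @param phase_rad Numeric vector of (unwrapped) phase samples, rad.
#' @param sample_rate Sampling rate in Hz.
#' @param dc_removed Whether the series already had its DC removed.
#' @return A `phase_record` tibble (`t_s` starts at 0).
#' @examples
#' as_phase_record(sin(2 * pi * 0.25 * (0:999) / 200), 200)
#' @export
as_phase_record <- function(phase_rad, sample_rate, dc_removed = FALSE) {
  if (!is.numeric(phase_rad) || any(!is.finite(phase_rad))) {
    abort("`phase_rad` must be a finite numeric vector.")
  }
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  t <- (seq_along(phase_rad) - 1) / sample_rate
  new_phase_record(t, phase_rad, sample_rate, dc_removed = isTRUE(dc_removed))
}

#' Ground truth attached to a synthetic quadrature record
#'
#' @param record A `quadrature_record` from [synthesize_quadrature()].
#' @return The `displacement_record` used to synthesize it, or `NULL` for
#'   records read from disk.
#' @export
ground_truth <- function(record) {
  attr(record, "truth")
}
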