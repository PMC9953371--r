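#' @noRd
new_phase_record <- function(t, phase, sample_rate, dc_removed = FALSE, ...) {
  new_record(
    tibble(t_s = t, phase_rad = phase),
    c("phase_record", "tbl_df", "tbl", "data.frame"),
    sample_rate, dc_removed = dc_removed, ...
  )
}

#' Arctangent demodulation of a quadrature record
#'
#' Recovers the modulated phase as the four-quadrant arctangent
#' `atan2(Q, I)` per sample, then unwraps it (adding 2 pi corrections
#' wherever successive samples jump by more than pi) so chest excursions
#' beyond a half cycle stay continuous. The result is the total path phase:
#' a constant distance term plus `(4 pi / lambda)(x(t) + y(t))` plus
#' oscillator phase noise, modulo a global 2 pi multiple.
#'
#' `remove_channel_dc = TRUE` subtracts each channel's mean before the
#' arctangent. This is **off by default** and should stay off for
#' chest-motion records: the phase excursion of mm-scale breathing is a
#' fraction of a radian, the I/Q samples occupy a short arc of the
#' constellation circle, and the sample mean of an arc lies well inside
#' the circle -- subtracting it re-centers the arctangent on the wrong
#' point and manufactures strong harmonic distortion (empirically the
#' respiration harmonics then out-power the heartbeat line). It is only
#' useful when the phase excursion spans many full cycles, where the
#' channel means do converge to the true DC offsets.
#'
#' @param record A `quadrature_record`.
#' @param remove_channel_dc Subtract per-channel means before the
#'   arctangent (default `FALSE`; see Details).
#' @return A `phase_record` tibble with columns `t_s`, `phase_rad`;
#'   attribute `dc_removed` is `FALSE` (the *phase-stream* DC is still
#'   present -- see [remove_dc_streaming()]).
#' @examples
#' rec <- synthesize_quadrature(radar_config(), vital_profile(), duration = 10)
#' ph <- arctan_demodulate(rec)
#' @export
arctan_demodulate <- function(record, remove_channel_dc = FALSE) {
  stopifnot(inherits(record, "quadrature_record"))
  if (nrow(record) == 0L) abort("`record` is empty.")
  i <- record$i_v
  q <- record$q_v
  if (isTRUE(remove_channel_dc)) {
    i <- i - mean(i)
    q <- q - mean(q)
  }
  raw <- atan2(q, i)
  ph <- as.numeric(signal::unwrap(raw))
  new_phase_record(record$t_s, ph, sample_rate(record))
}

#' Streaming DC removal at the refresh cadence
#'
#' Emulates the deployed receiver's real-time DC removal: phase samples
#' arrive in blocks of `sample_rate / refresh_rate` samples (8 per 0.04 s
#' update at the defaults); each block is appended to a stored dataset whose
#' mean is recomputed at every update, and the block is emitted minus that
#' current mean. The stored dataset grows without bound by default;
#' `window` (in seconds) caps it to a sliding window.
#'
#' @param phase A `phase_record` whose sample rate matches `config`.
#' @param config A [radar_config()] supplying the refresh cadence.
#' @param window Optional sliding-window length in s; `NULL` (default)
#'   grows the buffer indefinitely.
#' @return A `phase_record` with `dc_removed = TRUE`.
#' @examples
#' rec <- synthesize_quadrature(radar_config(), vital_profile(), duration = 10)
#' ph <- remove_dc_streaming(arctan_demodulate(rec), radar_config())
#' @export
remove_dc_streaming <- function(phase, config, window = NULL) {
  stopifnot(inherits(phase, "phase_record"), inherits(config, "radar_config"))
  if (!isTRUE(all.equal(sample_rate(phase), config$sample_rate))) {
    abort("`phase` sample rate does not match `config$sample_rate`.")
  }
  x <- phase$phase_rad
  n <- length(x)
  block <- config$samples_per_refresh
  n_blocks <- ceiling(n / block)
  # cumulative sums give the growing-buffer mean at every block boundary
  ends <- pmin(seq_len(n_blocks) * block, n)
  csum <- cumsum(x)
  if (is.null(window)) {
    means <- csum[ends] / ends
  } else {
    check_number(window, "window", 0, strict = TRUE)
    wlen <- round(window * config$sample_rate)
    starts <- pmax(ends - wlen, 0L)
    lo <- c(0, csum)[starts + 1L]
    means <- (csum[ends] - lo) / (ends - starts)
  }
  lens <- diff(c(0L, ends))
  out <- x - rep(means, times = lens)
  new_phase_record(phase$t_s, out, sample_rate(phase), dc_removed = TRUE)
}

#' Small-signal single-channel demodulation
#'
#' Demonstrates why a single-channel receiver has null points. For small
#' chest motion the I channel is
#' `I ~= A cos(theta) - A sin(theta) * psi(t)` with `psi` the motion phase,
#' so `(I - mean(I)) / (-A sin(theta))` recovers `psi` -- but the
#' sensitivity `A |sin(theta)|` collapses to zero whenever the standoff
#' distance sits at a multiple of a quarter wavelength. The sensitivity is
#' attached so callers can watch the collapse; at an exact null the record
#' is flagged degenerate (attribute `degenerate`) and zero phase is
#' returned rather than dividing by ~0.
#'
#' @param record A `quadrature_record`.
#' @param config A [radar_config()]; `distance`, `wavelength` and
#'   `amplitude` set the operating point.
#' @return A `phase_record` with attributes `sensitivity`
#'   (`A |sin(theta)|`, V/rad) and `degenerate` (logical).
#' @examples
#' cfg <- radar_config(distance = 1.3 + 0.125 / 8)  # mid between nulls
#' rec <- synthesize_quadrature(cfg, vital_profile(), duration = 10)
#' ph <- single_channel_phase(rec, cfg)
#' attr(ph, "sensitivity")
#' @export
single_channel_phase <- function(record, config) {
  stopifnot(inherits(record, "quadrature_record"), inherits(config, "radar_config"))
  if (nrow(record) == 0L) abort("`record` is empty.")
  theta <- 4 * pi * config$distance / config$wavelength
  s <- sin(theta)
  sens <- config$amplitude * abs(s)
  i <- record$i_v
  if (abs(s) < 1e-6) {
    return(new_phase_record(record$t_s, rep(0, nrow(record)),
                            sample_rate(record),
                            sensitivity = sens, degenerate = TRUE))
  }
  ph <- (i - mean(i)) / (-config$amplitude * s)
  new_phase_record(record$t_s, ph, sample_rate(record),
                   sensitivity = sens, degenerate = FALSE)
}
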