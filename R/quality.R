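#' Robust peak-to-peak voltage swing
#'
#' The swing of a channel waveform, read as the difference between its 99th
#' and 1st percentiles rather than max minus min, so a single spike does
#' not inflate it. This is the quantity an operator eyeballs on the live
#' I/Q traces when judging whether a subject's posture gives enough signal.
#'
#' @param samples Non-empty numeric vector of channel voltages, V.
#' @return Swing in V (>= 0).
#' @examples
#' peak_swing(sin(seq(0, 20 * pi, length.out = 5000)))  # ~2
#' @export
peak_swing <- function(samples) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort("`samples` must be a non-empty numeric vector.")
  }
  qs <- quantile(samples, c(0.01, 0.99), names = FALSE, na.rm = FALSE)
  unname(qs[2] - qs[1])
}

#' Combined I/Q swing magnitude
#'
#' RMS combination `sqrt((i^2 + q^2) / 2)` of the two channel swings -- the
#' single number the acceptability threshold is applied to.
#'
#' @param i_swing,q_swing Channel swings in V, non-negative.
#' @return Combined magnitude in V.
#' @examples
#' combined_magnitude(3e-4, 1.5e-4)
#' @export
combined_magnitude <- function(i_swing, q_swing) {
  check_number(i_swing, "i_swing", 0)
  check_number(q_swing, "q_swing", 0)
  sqrt((i_swing^2 + q_swing^2) / 2)
}

#' SNR gain from an amplitude ratio
#'
#' `20 log10(ratio)` in dB: the received-voltage improvement between a
#' slouched and an upright subject of 5-10x corresponds to 14-20 dB.
#'
#' @param amplitude_ratio Positive amplitude (voltage) ratio.
#' @return Gain in dB.
#' @examples
#' snr_gain_db(10)  # 20 dB
#' snr_gain_db(5)   # ~13.98 dB
#' @export
snr_gain_db <- function(amplitude_ratio) {
  if (!is.numeric(amplitude_ratio) || any(!is.finite(amplitude_ratio)) ||
      any(amplitude_ratio <= 0)) {
    abort("`amplitude_ratio` must be positive and finite.")
  }
  20 * log10(amplitude_ratio)
}

#' Posture / signal-strength quality of a quadrature record
#'
#' Computes the per-channel swings, their combined magnitude, and labels
#' the record `"Good"` when the combined magnitude strictly exceeds the
#' acceptability threshold (3 mV by default): below that, the waveforms
#' are too weak for reliable vital-sign extraction and the subject should
#' sit up or be repositioned.
#'
#' @param record A non-empty `quadrature_record`.
#' @param threshold Acceptability threshold in V (default `3e-3`; the
#'   comparison is strict, so exactly-at-threshold is `"Bad"`).
#' @return A one-row tibble with columns `i_swing`, `q_swing`, `combined`
#'   (V) and `label` (`"Good"`/`"Bad"`).
#' @examples
#' rec <- synthesize_quadrature(radar_config(amplitude = 4e-3),
#'                              vital_profile(), duration = 20)
#' posture_quality(rec)
#' @export
posture_quality <- function(record, threshold = 3e-3) {
  stopifnot(inherits(record, "quadrature_record"))
  if (nrow(record) == 0L) abort("`record` is empty.")
  check_number(threshold, "threshold", 0)
  i_sw <- peak_swing(record$i_v)
  q_sw <- peak_swing(record$q_v)
  comb <- combined_magnitude(i_sw, q_sw)
  tibble(
    i_swing = i_sw, q_swing = q_sw, combined = comb,
    label = if (comb > threshold) "Good" else "Bad"
  )
}
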