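#' Plot a quadrature record
#'
#' Time traces of the I and Q channel voltages.
#'
#' @param object A `quadrature_record`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quadrature_record <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("i_v", "q_v"),
                            names_to = "channel", values_to = "volts")
  df$channel <- ifelse(df$channel == "i_v", "I", "Q")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$volts)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "voltage (V)",
                  title = "Quadrature baseband channels")
}

#' Plot a phase record
#'
#' @param object A `phase_record`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_record <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t_s, y = .data$phase_rad)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "phase (rad)",
                  title = if (isTRUE(attr(object, "dc_removed"))) {
                    "Demodulated phase (DC removed)"
                  } else {
                    "Demodulated phase"
                  })
}

#' Plot a streaming rate series
#'
#' Per-refresh-tick RR and HR estimates versus time.
#'
#' @param object A `rate_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_series <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("rr_bpm", "hr_bpm"),
                            names_to = "vital", values_to = "bpm")
  df$vital <- ifelse(df$vital == "rr_bpm", "RR", "HR")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$bpm,
                                   colour = .data$vital)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "rate (BPM)", colour = NULL,
                  title = "Streaming vital-sign estimates")
}

#' Boxplots of cohort measurement errors
#'
#' Signed RR/HR errors per group, in the style the trial results are
#' reported.
#'
#' @param results A `radar_trial` tibble from [run_cohort()].
#' @param group_by Optional covariate (see [error_stats()]).
#' @param bin_edges Optional cut points for continuous covariates.
#' @return A ggplot object.
#' @export
plot_error_boxplots <- function(results, group_by = NULL, bin_edges = NULL) {
  long <- tidy.radar_trial(results)
  if (!is.null(group_by)) {
    cols <- c(gender = "gender", posture = "posture", weight = "weight_lb",
              height = "height_in", age = "age_yr")
    col <- cols[[group_by]]
    if (is.null(col) || !col %in% names(long)) {
      abort(sprintf("unknown or missing covariate: %s", group_by))
    }
    v <- long[[col]]
    long$group <- if (group_by %in% c("gender", "posture")) {
      as.character(v)
    } else if (!is.null(bin_edges)) {
      as.character(cut(v, breaks = bin_edges, include.lowest = TRUE))
    } else {
      ifelse(v <= median(v), "low", "high")
    }
  } else {
    long$group <- "all"
  }
  long$metric <- ifelse(long$metric == "rr_error", "RR error", "HR error")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$error)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = group_by %||% NULL, y = "error (BPM)",
                  title = "Measured minus reference errors")
}
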