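#' Tidy trial results into long error records
#'
#' One row per subject and metric, ready for grouped summaries or ggplot2
#' boxplots.
#'
#' @param x A `radar_trial` tibble from [run_cohort()].
#' @param ... Unused.
#' @return A tibble with columns `id`, covariates, `metric`
#'   (`"rr_error"`/`"hr_error"`), `error` (signed, BPM) and `abs_error`.
#' @export
tidy.radar_trial <- function(x, ...) {
  covars <- intersect(c("id", "weight_lb", "height_in", "age_yr",
                        "gender", "posture"), names(x))
  x |>
    as_tibble() |>
    select(dplyr::all_of(c(covars, "rr_error", "hr_error"))) |>
    tidyr::pivot_longer(c("rr_error", "hr_error"),
                        names_to = "metric", values_to = "error") |>
    mutate(abs_error = abs(.data$error))
}

#' One-row summary of trial results
#'
#' @param x A `radar_trial` tibble from [run_cohort()].
#' @param ... Unused.
#' @return A one-row tibble: `n`, medians and sample SDs of the signed
#'   errors, and medians of the absolute errors, all in BPM.
#' @export
glance.radar_trial <- function(x, ...) {
  tibble(
    n = nrow(x),
    rr_median_error = median(x$rr_error, na.rm = TRUE),
    rr_sd_error = sd(x$rr_error, na.rm = TRUE),
    rr_median_abs_error = median(abs(x$rr_error), na.rm = TRUE),
    hr_median_error = median(x$hr_error, na.rm = TRUE),
    hr_sd_error = sd(x$hr_error, na.rm = TRUE),
    hr_median_abs_error = median(abs(x$hr_error), na.rm = TRUE)
  )
}
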