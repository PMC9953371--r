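#' Generate a synthetic patient cohort
#'
#' Draws subjects whose covariates emulate the clinical-trial population:
#' weight 123-285.8 lb, height 57-73 in, age 29-79 yr (all uniform), and a
#' gender split of 8 male / 12 female when `n = 20` (the trial's split),
#' otherwise as balanced as possible. True vital rates are uniform --
#' RR 12-25 BPM, HR 55-120 BPM by default -- and each subject carries its
#' own displacement amplitudes, noise levels and derived sub-seed so a
#' cohort is fully reproducible from one master seed.
#'
#' Covariates have, by construction, no effect on measurement difficulty;
#' `noise_weight_slope` is an explicit hook that scales a subject's thermal
#' noise linearly with centered weight, for power analyses of
#' covariate-effect detection.
#'
#' @param n Number of subjects (>= 0).
#' @param seed Master seed (integer) for reproducibility.
#' @param ranges Named list overriding any of the default sampling ranges
#'   `weight_lb`, `height_in`, `age_yr`, `rr_bpm`, `hr_bpm` (each a
#'   `c(lo, hi)` pair with `lo <= hi`).
#' @param resp_amplitude,heart_amplitude Chest displacement amplitudes, m.
#' @param thermal_std Per-channel thermal noise std, V.
#' @param phase_walk_std Oscillator phase-walk increment std, rad/sample.
#' @param bad_posture_fraction Fraction of subjects labeled `"Bad"`
#'   posture; their received amplitude is multiplied by
#'   `bad_posture_scale`.
#' @param bad_posture_scale Amplitude scale for `"Bad"` posture subjects
#'   (default 0.2, i.e. a 5x weaker return).
#' @param noise_weight_slope Covariate-effect hook (default 0 = none); the
#'   subject's thermal noise is multiplied by
#'   `1 + slope * (weight - midpoint) / halfrange`.
#' @return A tibble with one row per subject: `id`, `weight_lb`,
#'   `height_in`, `age_yr`, `gender`, `posture`, `rr_bpm`, `hr_bpm`,
#'   `resp_amplitude_m`, `heart_amplitude_m`, `amplitude_scale`,
#'   `thermal_std_v`, `phase_walk_std_rad`, `subject_seed`.
#' @examples
#' cohort <- generate_cohort(20, seed = 1)
#' range(cohort$weight_lb)
#' table(cohort$gender)
#' @export
generate_cohort <- function(n, seed = NULL, ranges = list(),
                            resp_amplitude = 4e-3, heart_amplitude = 3e-4,
                            thermal_std = 1e-4, phase_walk_std = 1e-3,
                            bad_posture_fraction = 0, bad_posture_scale = 0.2,
                            noise_weight_slope = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    abort("`n` must be a single non-negative count.")
  }
  n <- as.integer(n)
  defaults <- list(weight_lb = c(123, 285.8), height_in = c(57, 73),
                   age_yr = c(29, 79), rr_bpm = c(12, 25), hr_bpm = c(55, 120))
  bad <- setdiff(names(ranges), names(defaults))
  if (length(bad)) abort(paste0("unknown range name(s): ",
                                paste(bad, collapse = ", ")))
  rng <- utils::modifyList(defaults, ranges)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      abort(sprintf("range `%s` must be a finite c(lo, hi) with lo <= hi.", nm))
    }
  }
  if (n == 0L) {
    return(tibble(
      id = integer(), weight_lb = numeric(), height_in = numeric(),
      age_yr = numeric(), gender = character(), posture = character(),
      rr_bpm = numeric(), hr_bpm = numeric(), resp_amplitude_m = numeric(),
      heart_amplitude_m = numeric(), amplitude_scale = numeric(),
      thermal_std_v = numeric(), phase_walk_std_rad = numeric(),
      subject_seed = integer()
    ))
  }
  n_male <- if (n == 20L) 8L else n %/% 2L
  n_bad <- as.integer(round(bad_posture_fraction * n))
  with_seed_maybe(seed, {
    gender <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    posture <- sample(c(rep("Bad", n_bad), rep("Good", n - n_bad)))
    weight <- runif(n, rng$weight_lb[1], rng$weight_lb[2])
    height <- runif(n, rng$height_in[1], rng$height_in[2])
    age <- runif(n, rng$age_yr[1], rng$age_yr[2])
    rr <- runif(n, rng$rr_bpm[1], rng$rr_bpm[2])
    hr <- runif(n, rng$hr_bpm[1], rng$hr_bpm[2])
    sub_seed <- sample.int(.Machine$integer.max, n)
    mid <- mean(rng$weight_lb)
    halfrange <- max(diff(rng$weight_lb) / 2, .Machine$double.eps)
    tstd <- thermal_std * (1 + noise_weight_slope * (weight - mid) / halfrange)
    tibble(
      id = seq_len(n),
      weight_lb = weight, height_in = height, age_yr = age,
      gender = gender, posture = posture,
      rr_bpm = rr, hr_bpm = hr,
      resp_amplitude_m = resp_amplitude, heart_amplitude_m = heart_amplitude,
      amplitude_scale = ifelse(posture == "Bad", bad_posture_scale, 1),
      thermal_std_v = pmax(tstd, 0), phase_walk_std_rad = phase_walk_std,
      subject_seed = sub_seed
    )
  })
}

#' Run the full measurement pipeline on one synthetic subject
#'
#' Composes the modules the way a measurement session does: synthesize the
#' quadrature return from the subject's true physiology and noise model,
#' arctangent-demodulate, remove the phase DC at the refresh cadence, run
#' the streaming rate estimator, and take the median of the post-warm-up
#' per-tick estimates as the measured RR/HR. The reference values are the
#' subject's ground truth (`reference = "truth"`) or an emulated manual
#' count that rounds the true RR to a whole breath per minute
#' (`reference = "manual-count"`; the HR reference stays exact, as a
#' clinical monitor would provide it).
#'
#' @param subject A one-row tibble as produced by [generate_cohort()] (or a
#'   named list with the same fields).
#' @param config A [radar_config()]; the subject's `amplitude_scale`
#'   multiplies `config$amplitude`.
#' @param duration Measurement length in s (must be > `window_length`).
#' @param window_length Trailing estimation window in s.
#' @param rr_band,hr_band [band_spec()]s for the two rates.
#' @param reference `"truth"` or `"manual-count"`.
#' @param harmonic_suppression Passed to [estimate_rates_streaming()].
#' @return A one-row tibble: subject id and covariates, `measured_rr`,
#'   `measured_hr`, `reference_rr`, `reference_hr`, and the signed errors
#'   `rr_error`, `hr_error` (measured minus reference), all in BPM.
#' @examples
#' \donttest{
#' subj <- generate_cohort(1, seed = 42)
#' run_trial(subj, duration = 60)
#' }
#' @export
run_trial <- function(subject, config = radar_config(), duration = 120,
                      window_length = 30,
                      rr_band = band_respiration(), hr_band = band_heart(),
                      reference = c("truth", "manual-count"),
                      harmonic_suppression = FALSE) {
  reference <- match.arg(reference)
  s <- as.list(subject)
  if (duration <= window_length) {
    abort("`duration` must exceed `window_length`.")
  }
  cfg <- radar_config(
    carrier_frequency = config$carrier_frequency,
    propagation_speed = config$propagation_speed,
    sample_rate = config$sample_rate, refresh_rate = config$refresh_rate,
    distance = config$distance,
    amplitude = config$amplitude * (s$amplitude_scale %||% 1)
  )
  profile <- vital_profile(
    rr_bpm = s$rr_bpm, hr_bpm = s$hr_bpm,
    resp_amplitude = s$resp_amplitude_m %||% 4e-3,
    heart_amplitude = s$heart_amplitude_m %||% 3e-4
  )
  noise <- noise_spec(
    phase_walk_std = s$phase_walk_std_rad %||% 0,
    thermal_std = s$thermal_std_v %||% 0,
    seed = s$subject_seed %||% NULL
  )
  rec <- synthesize_quadrature(cfg, profile, noise, duration)
  rates <- rec |>
    arctan_demodulate() |>
    remove_dc_streaming(cfg) |>
    estimate_rates_streaming(cfg, rr_band = rr_band, hr_band = hr_band,
                             window_length = window_length,
                             harmonic_suppression = harmonic_suppression)
  post <- rates[rates$t_s >= window_length, , drop = FALSE]
  measured_rr <- median(post$rr_bpm, na.rm = TRUE)
  measured_hr <- median(post$hr_bpm, na.rm = TRUE)
  ref_rr <- if (reference == "manual-count") round(s$rr_bpm) else s$rr_bpm
  ref_hr <- s$hr_bpm
  tibble(
    id = s$id %||% NA_integer_,
    weight_lb = s$weight_lb %||% NA_real_,
    height_in = s$height_in %||% NA_real_,
    age_yr = s$age_yr %||% NA_real_,
    gender = s$gender %||% NA_character_,
    posture = s$posture %||% NA_character_,
    measured_rr = measured_rr, measured_hr = measured_hr,
    reference_rr = ref_rr, reference_hr = ref_hr,
    rr_error = measured_rr - ref_rr,
    hr_error = measured_hr - ref_hr
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a whole cohort through the measurement pipeline
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param ... Passed to [run_trial()] (config, duration, bands, ...).
#' @return A `radar_trial` tibble with one [run_trial()] row per subject.
#' @examples
#' \donttest{
#' results <- generate_cohort(3, seed = 1) |> run_cohort(duration = 60)
#' }
#' @export
run_cohort <- function(cohort, ...) {
  stopifnot(is.data.frame(cohort))
  rows <- purrr::map(seq_len(nrow(cohort)),
                     function(i) run_trial(cohort[i, , drop = FALSE], ...))
  out <- bind_rows(rows)
  class(out) <- c("radar_trial", class(out))
  out
}

#' Synthetic lab-accuracy experiment
#'
#' The bench-validation protocol in one call: a cohort of `n_trials`
#' subjects with RR uniform 10-25 BPM and HR uniform 55-110 BPM, default
#' displacement amplitudes, thermal noise at 10% of the received amplitude
#' and a 1e-3 rad/sample oscillator walk, each measured for `duration`
#' seconds with a `window_length` s trailing window. The benchmark for
#' this setting is a median absolute error within 0.5 BPM for RR and
#' 3 BPM for HR.
#'
#' @param n_trials Number of test cases (default 30).
#' @param seed Master seed.
#' @param duration,window_length Per-trial timing, s.
#' @param config A [radar_config()].
#' @param ... Further arguments to [run_trial()].
#' @return A `radar_trial` tibble (see [run_cohort()]).
#' @examples
#' \donttest{
#' res <- lab_accuracy_experiment(n_trials = 2, seed = 1, duration = 60)
#' median(abs(res$rr_error))
#' }
#' @export
lab_accuracy_experiment <- function(n_trials = 30, seed = 1, duration = 120,
                                    window_length = 30,
                                    config = radar_config(), ...) {
  cohort <- generate_cohort(
    n_trials, seed = seed,
    ranges = list(rr_bpm = c(10, 25), hr_bpm = c(55, 110)),
    thermal_std = 0.1 * config$amplitude, phase_walk_std = 1e-3
  )
  run_cohort(cohort, config = config, duration = duration,
             window_length = window_length, ...)
}

#' Error statistics of trial results
#'
#' Per-metric (RR and HR error) summaries in the style of the trial
#' analysis: median, sample standard deviation (n-1 denominator) and the
#' five-number boxplot summary, overall or split by a covariate. Gender
#' and posture group directly; the continuous covariates (weight, height,
#' age) are binned by `bin_edges` when supplied, otherwise split at the
#' cohort median into low/high halves.
#'
#' @param results A tibble with columns `rr_error`, `hr_error` (plus
#'   covariates if grouping), e.g. from [run_cohort()].
#' @param group_by Optional covariate: one of `"gender"`, `"posture"`,
#'   `"weight"`, `"height"`, `"age"`.
#' @param bin_edges Optional numeric cut points for a continuous
#'   covariate.
#' @param error `"signed"` (default, as boxplots are drawn) or
#'   `"absolute"` (as accuracy claims are quoted).
#' @return A tibble with columns `metric`, `group`, `n`, `median`, `sd`,
#'   `min`, `q1`, `q3`, `max`.
#' @examples
#' res <- tibble::tibble(rr_error = c(0.1, -0.2, 0.3),
#'                       hr_error = c(1, -2, 3),
#'                       gender = c("male", "female", "female"))
#' error_stats(res, group_by = "gender")
#' @export
error_stats <- function(results, group_by = NULL, bin_edges = NULL,
                        error = c("signed", "absolute")) {
  error <- match.arg(error)
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) abort("`results` is empty.")
  if (!all(c("rr_error", "hr_error") %in% names(results))) {
    abort("`results` must have columns `rr_error` and `hr_error`.")
  }
  grp <- rep("all", nrow(results))
  if (!is.null(group_by)) {
    cols <- c(gender = "gender", posture = "posture", weight = "weight_lb",
              height = "height_in", age = "age_yr")
    if (!group_by %in% names(cols)) {
      abort(sprintf("unknown `group_by` covariate: %s", group_by))
    }
    col <- cols[[group_by]]
    if (!col %in% names(results)) {
      abort(sprintf("`results` has no column `%s`.", col))
    }
    v <- results[[col]]
    if (group_by %in% c("gender", "posture")) {
      grp <- as.character(v)
    } else if (!is.null(bin_edges)) {
      grp <- as.character(cut(v, breaks = bin_edges, include.lowest = TRUE))
    } else {
      grp <- ifelse(v <= median(v), "low", "high")
    }
  }
  long <- tibble(
    metric = rep(c("rr_error", "hr_error"), each = nrow(results)),
    group = rep(grp, 2),
    value = c(results$rr_error, results$hr_error)
  )
  if (error == "absolute") long$value <- abs(long$value)
  long |>
    group_by(.data$metric, .data$group) |>
    summarise(
      n = dplyr::n(),
      median = median(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      min = min(.data$value, na.rm = TRUE),
      q1 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q3 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      max = max(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    arrange(.data$metric, .data$group)
}

#' Remove outlier trials
#'
#' Formalizes the post-hoc removal of a single pathological heart-rate
#' case: rule `"max-abs-hr"` drops the one result with the largest
#' absolute HR error; rule `"none"` is the identity.
#'
#' @param results A non-empty tibble with an `hr_error` column.
#' @param rule `"none"` or `"max-abs-hr"`.
#' @return `results`, possibly with one row removed.
#' @examples
#' res <- tibble::tibble(rr_error = 0, hr_error = c(1, -43, 2))
#' drop_outliers(res, "max-abs-hr")
#' @export
drop_outliers <- function(results, rule = c("none", "max-abs-hr")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) abort("`results` is empty.")
  if (rule == "none") return(results)
  results[-which.max(abs(results$hr_error)), , drop = FALSE]
}
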