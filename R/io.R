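#' Read and write record CSV files
#'
#' All records serialize to plain CSV with fixed headers: quadrature
#' records as `t_s,i_v,q_v`, phase records as `t_s,phase_rad` and rate
#' series as `t_s,rr_bpm,hr_bpm` (no-rate ticks as empty fields). Numbers
#' are written in scientific notation with 12 significant digits, locale
#' independent, so a write-then-read round trip is lossless at that
#' precision. The sample rate is recovered from the time column on read.
#'
#' @param record,phase,rates The record to write.
#' @param path File path.
#' @return Writers return the input invisibly; readers return the record.
#' @name record_io
NULL

fmt12 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.11e", x))
}

write_record_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (nm in names(df)[num]) out[[nm]] <- fmt12(df[[nm]])
  readr::write_csv(out, path, quote = "none")
}

rate_from_times <- function(t) {
  if (length(t) < 2L) abort(sprintf("record has fewer than 2 samples."))
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    abort("time column is not uniformly spaced.")
  }
  1 / mean(dt)
}

read_numeric_csv <- function(path, cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s lacks column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  df[cols]
}

#' @rdname record_io
#' @export
write_quadrature <- function(record, path) {
  stopifnot(inherits(record, "quadrature_record"))
  write_record_csv(record[c("t_s", "i_v", "q_v")], path)
  invisible(record)
}

#' @rdname record_io
#' @export
read_quadrature <- function(path) {
  df <- read_numeric_csv(path, c("t_s", "i_v", "q_v"))
  new_record(df, c("quadrature_record", "tbl_df", "tbl", "data.frame"),
             rate_from_times(df$t_s))
}

#' @rdname record_io
#' @param dc_removed Whether the stored phase already had its DC removed
#'   (stored records carry no flag; declare it on read).
#' @export
write_phase <- function(phase, path) {
  stopifnot(inherits(phase, "phase_record"))
  write_record_csv(phase[c("t_s", "phase_rad")], path)
  invisible(phase)
}

#' @rdname record_io
#' @export
read_phase <- function(path, dc_removed = FALSE) {
  df <- read_numeric_csv(path, c("t_s", "phase_rad"))
  new_record(df, c("phase_record", "tbl_df", "tbl", "data.frame"),
             rate_from_times(df$t_s), dc_removed = dc_removed)
}

#' @rdname record_io
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "rate_series"))
  write_record_csv(rates[c("t_s", "rr_bpm", "hr_bpm")], path)
  invisible(rates)
}

#' @rdname record_io
#' @export
read_rates <- function(path) {
  df <- read_numeric_csv(path, c("t_s", "rr_bpm", "hr_bpm"))
  out <- new_record(df, c("rate_series", "tbl_df", "tbl", "data.frame"),
                    rate_from_times(df$t_s))
  attr(out, "refresh_rate") <- attr(out, "sample_rate")
  out
}

#' Read and write run configuration files
#'
#' Run configurations are YAML with up to three top-level sections --
#' `radar`, `profile`, `noise` -- whose keys mirror the [radar_config()],
#' [vital_profile()] and [noise_spec()] argument names exactly. Absent
#' sections or keys fall back to the constructors' defaults.
#'
#' @param path File path.
#' @param config,profile,noise Objects to write.
#' @return `read_run_config()` returns
#'   `list(config = , profile = , noise = )`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_run_config(f, radar_config(), vital_profile(), noise_spec(seed = 1))
#' cfg <- read_run_config(f)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  build <- function(fn, section, drop = character()) {
    args <- y[[section]]
    if (is.null(args)) args <- list()
    args <- args[setdiff(names(args), drop)]
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      abort(sprintf("unknown key(s) in `%s`: %s", section,
                    paste(bad, collapse = ", ")))
    }
    do.call(fn, args)
  }
  list(
    config = build(radar_config, "radar", drop = c("wavelength",
                                                   "samples_per_refresh")),
    profile = build(vital_profile, "profile"),
    noise = build(noise_spec, "noise")
  )
}

#' @rdname read_run_config
#' @export
write_run_config <- function(path, config = radar_config(),
                             profile = vital_profile(),
                             noise = noise_spec()) {
  out <- list(
    radar = unclass(config)[c("carrier_frequency", "propagation_speed",
                              "sample_rate", "refresh_rate", "distance",
                              "amplitude")],
    profile = unclass(profile),
    noise = Filter(Negate(is.null), unclass(noise))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
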