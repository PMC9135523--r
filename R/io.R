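# Plain-text readers and writers: two-column CSVs for waveforms and
# signals (full double precision, lossless round trip), cohort CSVs, and a
# JSON sidecar for the acquisition geometry.

fmt_full <- function(x) sprintf("%.17g", x)

write_two_col_csv <- function(a, b, names, path) {
  lines <- c(paste(names, collapse = ","),
             paste(fmt_full(a), fmt_full(b), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

read_two_col_csv <- function(path, expected_names) {
  if (!file.exists(path))
    abort_ewt(sprintf("file not found: %s", path), "format_error")
  if (file.size(path) == 0)
    abort_ewt(sprintf("empty file: %s", path), "format_error")
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) abort_ewt(
                   sprintf("cannot parse CSV %s: %s", path, conditionMessage(e)),
                   "format_error"))
  if (!identical(names(df), expected_names))
    abort_ewt(sprintf("%s must have header `%s` (found `%s`)", path,
                      paste(expected_names, collapse = ","),
                      paste(names(df), collapse = ",")), "format_error")
  if (nrow(df) < 2L)
    abort_ewt(sprintf("%s has fewer than 2 data rows", path), "format_error")
  df
}

check_uniform_time <- function(t, path) {
  dt <- diff(t)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * max(abs(dt))) {
    bad <- which(abs(dt - stats::median(dt)) > 1e-9 * abs(stats::median(dt)))[1] + 1L
    abort_ewt(sprintf("%s: non-uniform time grid starting at data row %d", path, bad),
              "format_error")
  }
}

#' Write / read a velocity waveform as CSV
#'
#' Two columns `time,velocity` (seconds, m/s), full double precision so a
#' write-read round trip is lossless.
#'
#' @param waveform A [velocity_waveform].
#' @param path File path.
#' @return `write_waveform_csv()` returns `path` invisibly;
#'   `read_waveform_csv()` returns a [velocity_waveform].
#' @export
write_waveform_csv <- function(waveform, path) {
  write_two_col_csv(waveform$time, waveform$velocity, c("time", "velocity"), path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- read_two_col_csv(path, c("time", "velocity"))
  check_uniform_time(df$time, path)
  velocity_waveform(df$time, df$velocity)
}

#' Write / read a Doppler signal as CSV with a geometry sidecar
#'
#' Two columns `time,sample`; the acquisition geometry is stored in a JSON
#' sidecar `<path>.geom.json` (keys `carrier_freq_hz`, `angle_deg`,
#' `sound_speed_m_s`, `sample_rate_hz`, `snr_db`).  Reading restores the
#' geometry when the sidecar exists.
#'
#' @param signal A [doppler_signal].
#' @param path File path for the CSV.
#' @return `write_signal_csv()` returns `path` invisibly;
#'   `read_signal_csv()` returns a [doppler_signal].
#' @export
write_signal_csv <- function(signal, path) {
  t <- (seq_along(signal$samples) - 1) / signal$sample_rate
  write_two_col_csv(t, signal$samples, c("time", "sample"), path)
  if (!is.null(signal$geometry))
    write_geometry_json(signal$geometry, paste0(path, ".geom.json"))
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- read_two_col_csv(path, c("time", "sample"))
  check_uniform_time(df$time, path)
  fs <- 1 / mean(diff(df$time))
  sidecar <- paste0(path, ".geom.json")
  geom <- if (file.exists(sidecar)) read_geometry_json(sidecar) else NULL
  if (!is.null(geom)) geom$sample_rate <- fs
  doppler_signal(df$sample, fs, geometry = geom)
}

#' Write / read acquisition geometry as JSON
#'
#' @param geometry A [beam_geometry].
#' @param path File path.
#' @return `write_geometry_json()` returns `path` invisibly;
#'   `read_geometry_json()` returns a [beam_geometry].
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(list(carrier_freq_hz = geometry$carrier_freq,
                            angle_deg = geometry$angle_deg,
                            sound_speed_m_s = geometry$sound_speed,
                            sample_rate_hz = geometry$sample_rate,
                            snr_db = if (is.na(geometry$snr_db)) "none" else geometry$snr_db),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  if (!file.exists(path))
    abort_ewt(sprintf("file not found: %s", path), "format_error")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  snr <- j$snr_db
  snr <- if (is.null(snr) || identical(snr, "none")) NA_real_ else as.numeric(snr)
  suppressWarnings(beam_geometry(j$carrier_freq_hz, j$angle_deg, j$sound_speed_m_s,
                                 j$sample_rate_hz, snr))
}

#' Write / read a cohort table as CSV
#'
#' Columns in the canonical order: `subject_id`, `group`, `vs`, `vd`,
#' `v_mean`, `diameter`, `cross_section_area`, `mean_flow`, `ri`, `pi`,
#' `sd_ratio`.
#'
#' @param cohort A cohort `data.frame` from [make_cohort()].
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("subject_id", "group", "vs", "vd", "v_mean", "diameter",
            "cross_section_area", "mean_flow", "ri", "pi", "sd_ratio")
  utils::write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    abort_ewt(sprintf("file not found: %s", path), "format_error")
  df <- utils::read.csv(path)
  needed <- c("subject_id", "group", "vs", "vd", "v_mean", "diameter",
              "cross_section_area", "mean_flow", "ri", "pi", "sd_ratio")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    abort_ewt(paste("cohort CSV is missing columns:",
                    paste(missing_cols, collapse = ", ")), "format_error")
  class(df) <- c("cohort_table", "data.frame")
  df
}
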