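# Configuration-driven pipeline runner tying the stages together:
# simulate -> decompose -> estimate -> indices -> compare.  The same
# functions back the command-line script in inst/cli/ewtflow.R.

pipeline_stage_names <- c("simulate", "decompose", "estimate", "indices", "compare")

log_stage <- function(stage, detail, t0) {
  message(sprintf("[%s] %s (%.2f s)", stage, detail,
                  as.numeric(Sys.time()) - t0))
}

json_report <- function(payload, config, seed, path) {
  meta <- list(tool = "ewtflow",
               version = as.character(utils::packageVersion("ewtflow")),
               seed = seed,
               config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  jsonlite::write_json(c(meta, payload), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a configured analysis pipeline
#'
#' Executes the configured stage chain in canonical order
#' (`simulate`, `decompose`, `estimate`, `indices`, `compare`), passing
#' each stage's output to the next and writing all artifacts under
#' `config$out_dir`.  All randomness flows from the single `config$seed`,
#' which is embedded (with the package version and a config hash) in every
#' JSON output.  One log line per stage goes to `stderr`.
#'
#' Recognised configuration keys:
#' \describe{
#'   \item{`out_dir`}{Output directory (created if needed). Required.}
#'   \item{`seed`}{Root integer seed (default 1).}
#'   \item{`simulate`}{List: waveform parameters (`vs`, `vd`, `heart_rate`,
#'     `duration`, `sys_frac`), geometry parameters (`carrier_freq`,
#'     `angle_deg`, `sound_speed`, `sample_rate`, `snr_db`),
#'     `n_scatterers`, `profile`; or `cohort = list(n_fgr, n_control)` to
#'     generate a cohort table instead.}
#'   \item{`decompose`}{List: `n_segments`, `gamma`; needs a simulated or
#'     `signal_csv` input.}
#'   \item{`estimate`}{List: `method` (`"ewt"`/`"stft"`), `window_s`,
#'     `n_segments`, `gamma`.}
#'   \item{`indices`}{List: `diameter` (mm, optional), `heart_rate_hint`.}
#'   \item{`compare`}{List: `variables`, `variant`; needs a cohort from
#'     `simulate$cohort` or `cohort_csv`.}
#'   \item{`signal_csv`, `cohort_csv`}{Paths to pre-existing inputs used
#'     when the `simulate` stage is absent.}
#' }
#' Unknown keys are rejected.
#'
#' @param config Named list as above.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  allowed <- c("out_dir", "seed", "signal_csv", "cohort_csv", pipeline_stage_names)
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    abort_ewt(paste("unknown config keys:", paste(unknown, collapse = ", ")),
              "invalid_parameter")
  if (is.null(config$out_dir))
    abort_ewt("config$out_dir is required", "invalid_parameter")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  message(sprintf("[config] seed = %d, stages: %s", seed,
                  paste(intersect(pipeline_stage_names, names(config)), collapse = " -> ")))
  artifacts <- list()
  signal <- NULL
  cohort <- NULL

  if (!is.null(config$simulate)) {
    t0 <- as.numeric(Sys.time())
    sc <- config$simulate
    if (!is.null(sc$cohort)) {
      cohort <- make_cohort(n_fgr = sc$cohort$n_fgr %||% 40,
                            n_control = sc$cohort$n_control %||% 102,
                            seed = seed)
      artifacts$cohort_csv <- write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
      log_stage("simulate", sprintf("cohort with %d subjects -> cohort.csv", nrow(cohort)), t0)
    } else {
      wf <- umbilical_waveform(vs = sc$vs %||% 0.6, vd = sc$vd %||% 0.2,
                               heart_rate = sc$heart_rate %||% 145,
                               duration = sc$duration %||% 2,
                               sample_rate = sc$sample_rate %||% 5000,
                               sys_frac = sc$sys_frac %||% 0.7)
      geom <- suppressWarnings(beam_geometry(
        carrier_freq = sc$carrier_freq %||% 3.5e6,
        angle_deg = sc$angle_deg %||% 60,
        sound_speed = sc$sound_speed %||% 1540,
        sample_rate = sc$sample_rate %||% 5000,
        snr_db = sc$snr_db %||% NA_real_))
      signal <- simulate_doppler(wf, geom, n_scatterers = sc$n_scatterers %||% 20,
                                 profile = sc$profile %||% "uniform", seed = seed)
      artifacts$waveform_csv <- write_waveform_csv(wf, file.path(out_dir, "truth.csv"))
      artifacts$signal_csv <- write_signal_csv(signal, file.path(out_dir, "signal.csv"))
      log_stage("simulate", sprintf("%d samples -> signal.csv", length(signal$samples)), t0)
    }
  }
  if (is.null(signal) && !is.null(config$signal_csv)) {
    signal <- tryCatch(read_signal_csv(config$signal_csv),
                       ewtflow_error = function(e) abort_ewt(
                         sprintf("stage input failed for `%s`: %s",
                                 config$signal_csv, conditionMessage(e)), "format_error"))
  }
  if (is.null(cohort) && !is.null(config$cohort_csv))
    cohort <- read_cohort_csv(config$cohort_csv)

  if (!is.null(config$decompose)) {
    t0 <- as.numeric(Sys.time())
    if (is.null(signal)) abort_ewt("decompose stage needs a signal", "invalid_parameter")
    dc <- config$decompose
    modes <- ewt(signal$samples, n_segments = dc$n_segments %||% "auto",
                 gamma = dc$gamma, sample_rate = signal$sample_rate)
    seg <- modes$bank$seg
    for (k in seq_len(ncol(modes$modes))) {
      p <- file.path(out_dir, sprintf("mode_%d.csv", k))
      write_two_col_csv((seq_len(nrow(modes$modes)) - 1) / signal$sample_rate,
                        modes$modes[, k], c("time", "sample"), p)
      artifacts[[sprintf("mode_%d_csv", k)]] <- p
    }
    artifacts$segmentation_json <- json_report(
      list(n_segments = seg$n_segments,
           boundaries_normalized = seg$boundaries,
           boundaries_hz = seg$boundaries * signal$sample_rate / (2 * pi),
           gamma = modes$bank$gamma),
      config, seed, file.path(out_dir, "segmentation.json"))
    log_stage("decompose", sprintf("%d modes -> mode_*.csv", ncol(modes$modes)), t0)
  }

  estimate <- NULL
  if (!is.null(config$estimate)) {
    t0 <- as.numeric(Sys.time())
    if (is.null(signal)) abort_ewt("estimate stage needs a signal", "invalid_parameter")
    ec <- config$estimate
    method <- ec$method %||% "ewt"
    estimate <- if (method == "ewt") {
      estimate_velocity_ewt(signal, n_segments = ec$n_segments %||% "auto",
                            gamma = ec$gamma, window_s = ec$window_s %||% 0.01)
    } else if (method == "stft") {
      estimate_velocity_stft(signal, window_s = ec$window_s %||% 0.01)
    } else abort_ewt(sprintf("unknown estimation method `%s`", method), "invalid_parameter")
    artifacts$velocity_csv <- write_waveform_csv(estimate$waveform,
                                                 file.path(out_dir, "velocity.csv"))
    log_stage("estimate", sprintf("method %s -> velocity.csv%s", method,
                                  if (is.null(estimate$nrmse_vs_truth)) "" else
                                    sprintf(" (NRMSE %.4g)", estimate$nrmse_vs_truth)), t0)
  }

  if (!is.null(config$indices)) {
    t0 <- as.numeric(Sys.time())
    if (is.null(estimate)) abort_ewt("indices stage needs an estimate", "invalid_parameter")
    ic <- config$indices
    idx <- index_set(estimate$waveform,
                     heart_rate_hint = ic$heart_rate_hint %||% NA_real_,
                     diameter = ic$diameter)
    artifacts$indices_json <- json_report(idx, config, seed,
                                          file.path(out_dir, "indices.json"))
    log_stage("indices", sprintf("RI %.3f, PI %.3f -> indices.json", idx$ri, idx$pi), t0)
  }

  if (!is.null(config$compare)) {
    t0 <- as.numeric(Sys.time())
    if (is.null(cohort)) abort_ewt("compare stage needs a cohort", "invalid_parameter")
    cc <- config$compare
    cmp_args <- list(cohort = cohort, variant = cc$variant %||% "pooled")
    if (!is.null(cc$variables)) cmp_args$variables <- cc$variables
    cmp <- do.call(compare_cohort, cmp_args)
    p <- file.path(out_dir, "comparison.csv")
    utils::write.csv(cmp, p, row.names = FALSE)
    artifacts$comparison_csv <- p
    log_stage("compare", sprintf("%d variables -> comparison.csv", nrow(cmp)), t0)
  }

  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
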