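# End-to-end pipeline: notch -> FIR low-pass -> median baseline correction
# -> window difference -> threshold initialization -> adaptive MMT scan with
# error correction, plus optional scoring against reference annotations.

#' Pipeline configuration
#'
#' Bundles the stage configurations. Live threshold values are runtime
#' state, so only the coefficients are configured here.
#'
#' @param filter a [filter_config].
#' @param baseline a [baseline_config].
#' @param detector a [detector_config].
#' @param thresholds an [mmt_thresholds] (coefficients only).
#' @param compensate_delay subtract the FIR group delay (order/2 samples)
#'   so reported indices sit on the raw-input timeline (default TRUE —
#'   evaluation against annotations needs the raw timeline).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            baseline = baseline_config(),
                            detector = detector_config(),
                            thresholds = mmt_thresholds(),
                            compensate_delay = TRUE) {
  structure(list(filter = filter, baseline = baseline, detector = detector,
                 thresholds = thresholds,
                 compensate_delay = isTRUE(compensate_delay)),
            class = "pipeline_config")
}

#' Run the full detection pipeline
#'
#' @param input an [ecg_signal].
#' @param config a [pipeline_config].
#' @param annotations optional reference beats; when supplied, the result
#'   includes an `eval_result` (see [match_beats()]).
#' @param tolerance matching tolerance in seconds (with `annotations`).
#' @return list with `events` (detections; `r_index` on the raw timeline if
#'   `compensate_delay`), `delay` (samples subtracted) and `eval` (or
#'   `NULL`).
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         annotations = NULL, tolerance = 0.15) {
  stopifnot(inherits(input, "ecg_signal"),
            inherits(config, "pipeline_config"))
  events <- detect(input, config = config$detector,
                   thresholds = config$thresholds,
                   filter = config$filter, baseline = config$baseline,
                   preprocess = TRUE)
  delay <- if (config$compensate_delay) config$filter$fir_order %/% 2L else 0L
  if (delay > 0L && nrow(events)) {
    events$r_index <- pmax(0L, events$r_index - delay)
    events$s1 <- pmax(0L, events$s1 - delay)
    events$s2 <- pmax(0L, events$s2 - delay)
  }
  ev <- NULL
  if (!is.null(annotations)) {
    ref <- beat_indices(annotations)
    scope <- round(config$detector$warmup * input$fs)
    ev <- match_beats(events$r_index[events$r_index >= scope],
                      ref[ref >= scope], tolerance = tolerance,
                      fs = input$fs)
  }
  list(events = events, delay = delay, eval = ev)
}

#' Write detection events to CSV
#'
#' Columns: 0-based sample `index`, `time_s`, `amplitude_mV`.
#'
#' @param events event data.frame from [detect()] / [run_pipeline()].
#' @param path output path.
#' @param fs sampling rate used for the time column.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, fs) {
  df <- data.frame(index = events$r_index,
                   time_s = events$r_index / fs,
                   amplitude_mV = events$r_amplitude)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Flatten / rebuild for the YAML schema. Sub-config classes are restored on
# read so a dump -> load -> dump round trip is the identity.
config_to_list <- function(config) {
  list(
    filter = unclass(config$filter),
    baseline = unclass(config$baseline),
    detector = unclass(config$detector),
    thresholds = unclass(config$thresholds)[c("coef1", "coef2", "coef",
                                              "rate")],
    compensate_delay = config$compensate_delay
  )
}

config_from_list <- function(x) {
  fc <- do.call(filter_config,
                x$filter[names(x$filter) != "fir_coefficients"])
  th <- do.call(mmt_thresholds, x$thresholds)
  pipeline_config(
    filter = fc,
    baseline = do.call(baseline_config, x$baseline),
    detector = do.call(detector_config, x$detector),
    thresholds = th,
    compensate_delay = isTRUE(x$compensate_delay)
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a [pipeline_config];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}
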