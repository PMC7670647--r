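# Recording container and configuration I/O.
#
# Recordings are stored in the package's versioned container (an RDS
# serialization of the `synthetic_recording` structure with a schema
# check on read): hierarchical groups sensor_data, photodiode/{left,
# right}, eye/{x,y}, ground_truth and labels, exactly as produced by
# simulate_recording(). Trial tables travel as CSV, configurations and
# reports as JSON.

#' Write / read a recording container
#'
#' Lossless round trip of the full `synthetic_recording` (data, labels,
#' ground truth). `read_recording` validates the schema version and the
#' presence of every group, naming the offender on mismatch.
#'
#' @param recording A `synthetic_recording`.
#' @param path File path.
#' @return `read_recording` returns the `synthetic_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "synthetic_recording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "synthetic_recording")) {
    stop("not a recording container: ", path, call. = FALSE)
  }
  if (!identical(rec$schema_version, RECORDING_SCHEMA_VERSION)) {
    stop(
      sprintf(
        "container schema version %s does not match expected %s",
        rec$schema_version %||% "<missing>", RECORDING_SCHEMA_VERSION
      ),
      call. = FALSE
    )
  }
  required <- c("sensor_data", "photodiode", "eye", "channels", "trials", "ground_truth", "labels")
  missing_g <- setdiff(required, names(rec))
  if (length(missing_g)) {
    stop("container missing group(s): ", paste(missing_g, collapse = ", "), call. = FALSE)
  }
  for (side in c("left", "right")) {
    if (is.null(rec$photodiode[[side]])) {
      stop("container missing group: photodiode/", side, call. = FALSE)
    }
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Full configuration of one end-to-end cohort run: cohort size,
#' per-subject simulation parameters, subject-level random effects,
#' preprocessing thresholds, analysis bands, surrogate settings, and the
#' global seed. Serializable to JSON; a run is reproducible from the
#' config alone.
#'
#' @param n_subjects Cohort size (default 18).
#' @param n_trials Trials per subject.
#' @param n_channels Sensors per subject.
#' @param latency_ms Mean sensor latency across subjects.
#' @param latency_sd Between-subject latency SD (ms).
#' @param tag_mod Mean tagging power modulation by attention (default
#'   0.05, i.e. +5% attended).
#' @param alpha_mod Mean alpha power modulation magnitude (default 0.10,
#'   decreased contralaterally).
#' @param attention_sd Log-scale SD of the subject-level attention
#'   strength scaling both modulations (what induces the negative
#'   over-subject correlation between alpha and tagging AMI).
#' @param coupling_rho Trial-wise alpha/tagging factor coupling.
#' @param snr Tagging-to-noise RMS ratio.
#' @param artifact_rates Per-trial artifact probabilities.
#' @param amp_threshold_sd Amplitude-rejection threshold.
#' @param saccade_ms Saccade duration criterion.
#' @param alpha_band,tagging_band Analysis bands (Hz).
#' @param n_shifts Surrogates per channel.
#' @param seed Global integer seed.
#' @param output_dir Optional directory for stage outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 18, n_trials = 60, n_channels = 6,
                            latency_ms = 50, latency_sd = 4,
                            tag_mod = 0.05, alpha_mod = 0.10,
                            attention_sd = 0.4, coupling_rho = 0,
                            snr = 0.2,
                            artifact_rates = list(blink = 0.02, saccade = 0.02, sensor = 0.02),
                            amp_threshold_sd = 5, saccade_ms = 500,
                            alpha_band = c(8, 13), tagging_band = c(55, 75),
                            n_shifts = 100, seed = 1, output_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_subjects >= 1, cfg$n_trials >= 8, cfg$n_channels >= 2,
    cfg$tag_mod >= 0, cfg$tag_mod < 1, cfg$alpha_mod >= 0, cfg$alpha_mod < 1
  )
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$artifact_rates <- as.list(raw$artifact_rates)
  if (!is.null(raw$output_dir) && length(raw$output_dir) == 0) raw$output_dir <- NULL
  do.call(pipeline_config, raw)
}
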