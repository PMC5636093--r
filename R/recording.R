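#' Multi-channel EMG recording with stimulation-pulse markers
#'
#' Container for a surface-EMG record acquired during an epidural stimulation
#' (scES) ramp-up experiment: a time-by-channel sample matrix in microvolts,
#' the sampling rate, one label per muscle channel, the sample index of every
#' stimulation-pulse onset, and the stimulation parameter (voltage or
#' frequency) delivered at each pulse.
#'
#' @param samples Numeric matrix (time x channels) or vector (one channel),
#'   amplitudes in microvolts.
#' @param sampling_rate Sampling rate in Hz (the acquisition protocol uses
#'   2000 samples per second).
#' @param channel_labels Character vector of muscle names, one per column.
#' @param pulse_onsets Integer vector of 0-based sample indices of pulse
#'   onsets, strictly increasing, all within the record.
#' @param pulse_params Numeric vector, one stimulation parameter value per
#'   pulse (volts for intensity ramps, Hz for frequency ramps).
#' @param param_kind One of `"voltage"`, `"frequency"`, `"amplitude"`;
#'   the meaning of `pulse_params`.
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sampling_rate, channel_labels = NULL,
                          pulse_onsets = integer(), pulse_params = numeric(),
                          param_kind = c("voltage", "frequency", "amplitude")) {
  param_kind <- match.arg(param_kind)
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (time x channels)", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  sampling_rate <- as.numeric(sampling_rate)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(samples)))
    }
  }
  if (length(channel_labels) != ncol(samples)) {
    stop("one channel label per column is required", call. = FALSE)
  }
  pulse_onsets <- as.integer(round(pulse_onsets))
  if (length(pulse_onsets) > 0) {
    if (any(diff(pulse_onsets) <= 0)) {
      stop("`pulse_onsets` must be strictly increasing", call. = FALSE)
    }
    if (min(pulse_onsets) < 0 || max(pulse_onsets) >= nrow(samples)) {
      stop("`pulse_onsets` must lie within the record (0-based)", call. = FALSE)
    }
  }
  if (length(pulse_params) != length(pulse_onsets)) {
    stop("`pulse_params` must have one value per pulse onset", call. = FALSE)
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels, pulse_onsets = pulse_onsets,
         pulse_params = as.numeric(pulse_params), param_kind = param_kind),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d samples x %d channel(s) @ %g Hz (%.2f s), %d pulses (%s)\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate,
    nrow(x$samples) / x$sampling_rate, length(x$pulse_onsets), x$param_kind))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Stimulus-locked segment matrix (the EMG "image")
#'
#' The 2-D representation of one EMG channel: each row is the stretch of
#' samples between two consecutive stimulation pulses (one building block
#' \eqn{w_i}), columns are the intra-segment sample index. Rows carry the
#' stimulation parameter of their pulse so events (runs of pulses at one
#' voltage) can be recovered.
#'
#' @param values Numeric matrix, rows = segments in pulse order, columns =
#'   within-segment sample index, microvolts.
#' @param sampling_rate Hz.
#' @param row_param Numeric, stimulation parameter per row (or `NULL`).
#' @param row_event_id Integer event index per row (or `NULL`).
#' @param param_kind Meaning of `row_param`.
#'
#' @return An object of class `segment_matrix`.
#' @export
segment_matrix <- function(values, sampling_rate, row_param = NULL,
                           row_event_id = NULL,
                           param_kind = c("voltage", "frequency", "amplitude")) {
  param_kind <- match.arg(param_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.null(row_param) && length(row_param) != nrow(values)) {
    stop("`row_param` must have one value per row", call. = FALSE)
  }
  if (!is.null(row_event_id) && length(row_event_id) != nrow(values)) {
    stop("`row_event_id` must have one value per row", call. = FALSE)
  }
  structure(
    list(values = values, sampling_rate = as.numeric(sampling_rate),
         row_param = row_param, row_event_id = row_event_id,
         param_kind = param_kind),
    class = "segment_matrix"
  )
}

#' @export
print.segment_matrix <- function(x, ...) {
  cat(sprintf("<segment_matrix> %d segments x %d samples @ %g Hz (%s-labelled rows)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              if (is.null(x$row_param)) "un" else x$param_kind))
  invisible(x)
}

#' @export
dim.segment_matrix <- function(x) dim(x$values)
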