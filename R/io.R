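# Format double columns with 17 significant digits so every CSV write/read
# cycle is lossless at double precision (readr's default caps below that).
write_csv_precise <- function(df, path) {
  is_dbl <- vapply(df, is.double, logical(1))
  df[is_dbl] <- lapply(df[is_dbl], function(x) sprintf("%.17g", x))
  readr::write_csv(df, path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
}

#' Write a recording to CSV plus JSON sidecar
#'
#' The CSV holds `time_s` and one column per muscle channel (shortest
#' round-trip number formatting, so the write/read cycle is lossless at
#' double precision); the sidecar holds the sampling rate, pulse onsets,
#' per-pulse parameters and, when supplied, the simulation ground truth and
#' the generating spec (seed included).
#'
#' @param recording An [emg_recording()].
#' @param csv_path,sidecar_path Output paths.
#' @param truth Optional ground truth (single `ground_truth` or named list).
#' @param spec Optional generating spec.
#' @return Invisibly, `csv_path`.
#' @export
write_recording <- function(recording, csv_path, sidecar_path,
                            truth = NULL, spec = NULL) {
  stopifnot(inherits(recording, "emg_recording"))
  df <- tibble::as_tibble(recording$samples)
  df <- tibble::add_column(
    df, time_s = (seq_len(nrow(df)) - 1) / recording$sampling_rate,
    .before = 1L)
  write_csv_precise(df, csv_path)
  side <- list(sampling_rate = recording$sampling_rate,
               channel_labels = as.list(recording$channel_labels),
               pulse_onsets = recording$pulse_onsets,
               pulse_params = recording$pulse_params,
               param_kind = recording$param_kind)
  if (!is.null(truth)) side$ground_truth <- strip_class(truth)
  if (!is.null(spec)) side$spec <- strip_class(spec)
  write_json_file(side, sidecar_path)
  invisible(csv_path)
}

strip_class <- function(x) {
  if (inherits(x, "ground_truth") || inherits(x, "benchmark_spec") ||
      inherits(x, "session_spec")) {
    return(lapply(unclass(x), strip_class))
  }
  if (is.list(x)) return(lapply(x, strip_class))
  x
}

#' Read a recording from CSV plus JSON sidecar
#'
#' Inverse of [write_recording()]; validates column presence, onset
#' monotonicity and onset/parameter length agreement with descriptive
#' errors.
#'
#' @param csv_path,sidecar_path Input paths.
#' @return An [emg_recording()]; any stored ground truth and spec are
#'   attached as attributes `"truth"` and `"spec"`.
#' @export
read_recording <- function(csv_path, sidecar_path) {
  if (!file.exists(csv_path)) stop("missing CSV: ", csv_path, call. = FALSE)
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  }
  # base strtod parsing is correctly rounded, keeping the round-trip lossless
  df <- utils::read.csv(csv_path, check.names = FALSE)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  labels <- unlist(side$channel_labels)
  missing_cols <- setdiff(labels, names(df))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing channel column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  onsets <- as.integer(side$pulse_onsets)
  params <- as.numeric(side$pulse_params)
  if (length(onsets) > 1L && any(diff(onsets) <= 0)) {
    stop("sidecar pulse onsets are not strictly increasing", call. = FALSE)
  }
  if (length(params) != length(onsets)) {
    stop(sprintf("sidecar has %d pulse params for %d onsets",
                 length(params), length(onsets)), call. = FALSE)
  }
  rec <- emg_recording(as.matrix(df[, labels, drop = FALSE]),
                       side$sampling_rate, channel_labels = labels,
                       pulse_onsets = onsets, pulse_params = params,
                       param_kind = side$param_kind)
  attr(rec, "truth") <- side$ground_truth
  attr(rec, "spec") <- side$spec
  rec
}

#' Write a segment matrix to CSV plus JSON header
#'
#' @param seg A [segment_matrix()].
#' @param csv_path,header_path Output paths.
#' @return Invisibly, `csv_path`.
#' @export
write_segment_matrix <- function(seg, csv_path, header_path) {
  stopifnot(inherits(seg, "segment_matrix"))
  df <- tibble::as_tibble(seg$values, .name_repair = ~ paste0("s", seq_along(.x)))
  write_csv_precise(df, csv_path)
  write_json_file(list(sampling_rate = seg$sampling_rate,
                       row_param = seg$row_param,
                       row_event_id = seg$row_event_id,
                       param_kind = seg$param_kind,
                       n_rows = nrow(seg$values),
                       n_cols = ncol(seg$values)),
                  header_path)
  invisible(csv_path)
}

#' Read a segment matrix written by [write_segment_matrix()]
#'
#' @param csv_path,header_path Input paths.
#' @return A [segment_matrix()].
#' @export
read_segment_matrix <- function(csv_path, header_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  hd <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  vals <- unname(as.matrix(df))
  segment_matrix(vals, hd$sampling_rate,
                 row_param = if (is.null(hd$row_param)) NULL else
                   as.numeric(hd$row_param),
                 row_event_id = if (is.null(hd$row_event_id)) NULL else
                   as.integer(hd$row_event_id),
                 param_kind = hd$param_kind)
}

#' Serialize a detection result to JSON
#'
#' @param detection A `detection_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_detection <- function(detection, path) {
  stopifnot(inherits(detection, "detection_result"))
  out <- list(method = detection$method,
              segment_active = as.integer(detection$segment_active),
              statistic = detection$statistic,
              threshold_h = detection$threshold_h,
              v_s0 = detection$v_s0,
              onset_ms = detection$onset_ms,
              baseline_rows = detection$baseline_rows,
              params = detection$params)
  if (!is.null(detection$event_table)) {
    out$events <- as.list(detection$event_table)
  }
  write_json_file(out, path)
  invisible(path)
}
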