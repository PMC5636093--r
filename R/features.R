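#' Peak-to-peak amplitude and min-max interval of a segment
#'
#' `vpp` is the absolute difference between the highest and lowest sample;
#' `t_pp_ms` the absolute time between the maximum and the minimum. Ties are
#' broken by the earliest index.
#'
#' @param segment Numeric vector.
#' @param sampling_rate Hz.
#' @return List with `vpp` (uV) and `t_pp_ms` (ms).
#' @export
peak_to_peak <- function(segment, sampling_rate) {
  if (length(segment) == 0L) stop("empty segment", call. = FALSE)
  i_max <- which.max(segment)
  i_min <- which.min(segment)
  list(vpp = segment[i_max] - segment[i_min],
       t_pp_ms = abs(i_max - i_min) / sampling_rate * 1000)
}

#' Integrated EMG of a segment
#'
#' Area under the rectified segment: `sum(|x_k|) * (1000 / sampling_rate)`,
#' in uV.ms.
#'
#' @param segment Numeric vector.
#' @param sampling_rate Hz.
#' @return iEMG in uV.ms.
#' @export
integrated_emg <- function(segment, sampling_rate) {
  if (length(segment) == 0L) stop("empty segment", call. = FALSE)
  sum(abs(segment)) * 1000 / sampling_rate
}

#' Normalize peak-to-peak amplitudes across a left/right muscle pair
#'
#' Fills `vpp_norm = vpp / max(vpp)` where the maximum is taken over both
#' tables jointly, so the largest response of the pair maps to exactly 1.
#'
#' @param left,right Feature tables from [build_feature_table()].
#' @return List with updated `left` and `right` tables.
#' @export
normalize_vpp <- function(left, right) {
  if (nrow(left) == 0L || nrow(right) == 0L) {
    stop("both tables must be nonempty", call. = FALSE)
  }
  pair_max <- max(c(left$vpp, right$vpp))
  if (pair_max == 0) {
    warning("all-zero peak-to-peak amplitudes; norms set to 0", call. = FALSE)
    left$vpp_norm <- 0
    right$vpp_norm <- 0
  } else {
    left$vpp_norm <- left$vpp / pair_max
    right$vpp_norm <- right$vpp / pair_max
  }
  list(left = left, right = right)
}

#' Per-segment evoked-potential feature table
#'
#' Computes the feature set for every segment of the matrix: peak-to-peak
#' amplitude, min-max interval, integrated EMG, binary activation flag and
#' onset latency (copied from the detection result; latency is reported only
#' for detected-active segments). Features are unconditional: they are
#' computed for inactive segments too, only the flags and latencies differ.
#'
#' @param seg A [segment_matrix()].
#' @param detection A `detection_result` for the same matrix.
#' @return A tibble with one row per segment: `segment`, `event_id`,
#'   `param`, `active`, `vpp`, `vpp_norm` (NA until [normalize_vpp()]),
#'   `t_pp_ms`, `latency_ms`, `iemg`.
#' @export
build_feature_table <- function(seg, detection) {
  stopifnot(inherits(seg, "segment_matrix"),
            inherits(detection, "detection_result"))
  n <- nrow(seg$values)
  if (length(detection$segment_active) != n) {
    stop("detection result does not match the segment matrix", call. = FALSE)
  }
  pp <- lapply(seq_len(n), function(i) {
    peak_to_peak(seg$values[i, ], seg$sampling_rate)
  })
  event_id <- if (!is.null(detection$event_table) &&
                  !is.null(seg$row_param)) {
    ev <- group_events(seg, min_pulses = 1L)
    ids <- integer(n)
    for (k in seq_len(nrow(ev))) ids[ev$rows[[k]]] <- ev$event_id[k]
    ids
  } else {
    rep(NA_integer_, n)
  }
  tibble::tibble(
    segment = seq_len(n),
    event_id = event_id,
    param = if (is.null(seg$row_param)) NA_real_ else seg$row_param,
    active = detection$segment_active,
    vpp = vapply(pp, `[[`, numeric(1), "vpp"),
    vpp_norm = NA_real_,
    t_pp_ms = vapply(pp, `[[`, numeric(1), "t_pp_ms"),
    latency_ms = ifelse(detection$segment_active, detection$onset_ms,
                        NA_real_),
    iemg = apply(seg$values, 1L, integrated_emg,
                 sampling_rate = seg$sampling_rate)
  )
}

#' Per-event feature summary
#'
#' Means of the per-segment features over each event's pulses.
#'
#' @param features Feature table from [build_feature_table()].
#' @return A tibble with one row per event: `event_id`, `param`, `n_rows`,
#'   `mean_vpp`, `mean_iemg`, `n_active`.
#' @export
summarize_events <- function(features) {
  if (all(is.na(features$event_id))) {
    stop("feature table carries no event ids", call. = FALSE)
  }
  ids <- sort(unique(features$event_id))
  rows <- lapply(ids, function(id) which(features$event_id == id))
  tibble::tibble(
    event_id = ids,
    param = vapply(rows, function(r) features$param[r][1L], numeric(1)),
    n_rows = lengths(rows),
    mean_vpp = vapply(rows, function(r) mean(features$vpp[r]), numeric(1)),
    mean_iemg = vapply(rows, function(r) mean(features$iemg[r]), numeric(1)),
    n_active = vapply(rows, function(r) sum(features$active[r]), integer(1))
  )
}
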