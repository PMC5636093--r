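#' Segment one EMG channel into the stimulus-locked segment matrix
#'
#' Cuts the channel at every stimulation-pulse onset and stacks the
#' inter-pulse stretches as rows of a rectangular matrix. Segments are
#' half-open `[onset, next onset)` in 0-based sample indices; every row is
#' truncated to the minimum inter-onset gap so the matrix is rectangular
#' (this preserves the early-response region where detection happens). The
#' final pulse contributes a row only if a full minimum gap of samples
#' remains after it.
#'
#' @param recording An [emg_recording()].
#' @param channel Column index or muscle label.
#' @return A [segment_matrix()] whose rows carry the per-pulse stimulation
#'   parameter.
#' @export
segment_by_onsets <- function(recording, channel = 1L) {
  stopifnot(inherits(recording, "emg_recording"))
  if (is.character(channel)) {
    channel <- match(channel, recording$channel_labels)
    if (is.na(channel)) stop("unknown channel label", call. = FALSE)
  }
  x <- recording$samples[, channel]
  onsets <- recording$pulse_onsets # 0-based
  n <- length(x)
  if (length(onsets) < 2L) {
    stop("at least 2 pulse onsets are required to segment", call. = FALSE)
  }
  gaps <- diff(onsets)
  min_gap <- min(gaps)
  # last pulse keeps its row only if a full min_gap of samples follows it
  keep_last <- (onsets[length(onsets)] + min_gap) <= n
  n_rows <- length(onsets) - 1L + as.integer(keep_last)
  vals <- matrix(NA_real_, nrow = n_rows, ncol = min_gap)
  for (i in seq_len(n_rows)) {
    start <- onsets[i] + 1L # to 1-based
    vals[i, ] <- x[start:(start + min_gap - 1L)]
  }
  params <- recording$pulse_params[seq_len(n_rows)]
  segment_matrix(vals, recording$sampling_rate, row_param = params,
                 param_kind = recording$param_kind)
}

#' Group segment rows into stimulation events
#'
#' An event is a maximal run of consecutive pulses delivered at the same
#' stimulation parameter value; the protocol delivers at least five pulses
#' per voltage step, so runs shorter than `min_pulses` raise a warning.
#'
#' @param seg A [segment_matrix()] with `row_param` populated.
#' @param min_pulses Minimum expected pulses per event (default 5).
#' @return A tibble with one row per event: `event_id`, `param`, `n_rows`,
#'   `first_row`, `last_row`, and a list-column `rows` of member row indices.
#' @export
group_events <- function(seg, min_pulses = 5L) {
  stopifnot(inherits(seg, "segment_matrix"))
  v <- seg$row_param
  if (is.null(v)) stop("`row_param` is not populated; cannot group events",
                       call. = FALSE)
  if (length(v) == 0L) {
    return(tibble::tibble(event_id = integer(), param = numeric(),
                          n_rows = integer(), first_row = integer(),
                          last_row = integer(), rows = list()))
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (any(r$lengths < min_pulses)) {
    warning(sprintf("%d event(s) have fewer than %d pulses",
                    sum(r$lengths < min_pulses), min_pulses), call. = FALSE)
  }
  tibble::tibble(
    event_id = seq_along(r$values),
    param = r$values,
    n_rows = r$lengths,
    first_row = starts,
    last_row = ends,
    rows = lapply(seq_along(r$values), function(i) starts[i]:ends[i])
  )
}

#' Render the segment matrix as a 2-D heat image and 3-D surface description
#'
#' The heat image follows the mapping-figure convention: x is time within the
#' segment (ms), y is the stimulation parameter of each row (V or Hz), and
#' colour is amplitude (uV). The surface description carries the same grid as
#' plain vectors/matrix for external 3-D plotting.
#'
#' @param seg A [segment_matrix()].
#' @return A list with `heat` (a ggplot) and `surface`
#'   (list of `time_ms`, `row_param`, `values`).
#' @export
render_views <- function(seg) {
  stopifnot(inherits(seg, "segment_matrix"))
  if (length(seg$values) == 0L) stop("empty segment matrix", call. = FALSE)
  nr <- nrow(seg$values); nc <- ncol(seg$values)
  time_ms <- (seq_len(nc) - 1) / seg$sampling_rate * 1000
  ylab <- switch(seg$param_kind,
                 voltage = "Stimulation voltage (V)",
                 frequency = "Stimulation frequency (Hz)",
                 amplitude = "Impulse amplitude")
  param <- seg$row_param
  ylab_use <- if (is.null(param)) "Segment" else ylab
  df <- tibble::tibble(
    time_ms = rep(time_ms, each = nr),
    row = rep(seq_len(nr), times = nc),
    value = as.vector(seg$values)
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$row,
                                         fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(
      breaks = pretty(seq_len(nr)),
      labels = if (is.null(param)) ggplot2::waiver() else
        function(b) {
          b <- b[b >= 1 & b <= nr]
          format(param[b], digits = 3)
        }
    ) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Evoked potential duration (ms)", y = ylab_use,
                  fill = "Amplitude (µV)") +
    ggplot2::theme_minimal()
  list(heat = gg,
       surface = list(time_ms = time_ms, row_param = param,
                      values = seg$values))
}
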