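#' Evoked-potential template waveform
#'
#' Builds the unit-amplitude activation shape used by the simulator. The
#' default is a biphasic waveform: one full sinusoid cycle under a Hann
#' window, which starts and ends at exactly zero, integrates to exactly zero
#' (antisymmetric about its midpoint), and is normalized to peak absolute
#' amplitude 1.
#'
#' @param duration_ms Template duration in milliseconds (default 30, a
#'   typical short-latency evoked-response width).
#' @param sampling_rate Hz.
#' @param shape `"biphasic"` (Hann-windowed sine cycle) or `"monophasic"`
#'   (Hann bump).
#' @return An object of class `ep_template` with fields `samples`,
#'   `duration_ms`, `sampling_rate`, `shape`.
#' @export
make_ep_template <- function(duration_ms = 30, sampling_rate = 2000,
                             shape = c("biphasic", "monophasic")) {
  shape <- match.arg(shape)
  if (!is.numeric(duration_ms) || length(duration_ms) != 1L ||
      !is.finite(duration_ms) || duration_ms <= 0) {
    stop("`duration_ms` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  n <- round(duration_ms / 1000 * sampling_rate)
  if (n < 4) stop("template too short at this sampling rate", call. = FALSE)
  t <- (seq_len(n) - 1) / (n - 1)
  w <- sin(pi * t)^2 # Hann window, zero at both ends
  s <- switch(shape,
              biphasic = sin(2 * pi * t) * w,
              monophasic = w)
  s <- s / max(abs(s))
  structure(list(samples = s, duration_ms = duration_ms,
                 sampling_rate = sampling_rate, shape = shape),
            class = "ep_template")
}

#' Specification of the simulated benchmark signal
#'
#' Describes the synthetic record used to stress detectors across SNR: 50
#' inter-pulse segments of which the first 20 are silent; each of the
#' remaining segments carries one template scaled by a linearly increasing
#' impulse amplitude (`ramp_slope * n` for the n-th active segment), plus
#' stationary additive white Gaussian noise at a requested SNR. The first
#' `n_baseline` segments serve as the detector baseline.
#'
#' The impulse train has unit spacing on the template's own time scale, so
#' consecutive segments are contiguous and the template spans most of each
#' segment (default: 80-sample segments holding the 60-sample template after
#' a 5 ms latency margin) — unlike the 500 ms inter-pulse interval of a real
#' 2 Hz ramp, where the response occupies a small fraction of the segment.
#'
#' @param n_segments Total segments (default 50).
#' @param n_silent Leading segments with no evoked potential (default 20).
#' @param n_baseline Leading segments used as detection baseline (default 10).
#' @param segment_length Samples per segment (default 80: the 30 ms template
#'   plus the latency margin at 2000 Hz).
#' @param ramp_slope Amplitude increment per active-segment index
#'   (default 0.01).
#' @param snr_db Requested SNR in dB; `Inf` means noiseless.
#' @param impulse_offset_ms Response latency: template insertion offset after
#'   each pulse onset (default 5 ms).
#' @param sampling_rate Hz (default 2000).
#' @param seed RNG seed for the noise draw.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_segments = 50L, n_silent = 20L, n_baseline = 10L,
                           segment_length = 80L, ramp_slope = 0.01,
                           snr_db = Inf, impulse_offset_ms = 5,
                           sampling_rate = 2000, seed = 1L) {
  if (!(n_baseline <= n_silent && n_silent <= n_segments)) {
    stop("need n_baseline <= n_silent <= n_segments", call. = FALSE)
  }
  if (ramp_slope <= 0) stop("`ramp_slope` must be positive", call. = FALSE)
  if (segment_length < 2) stop("`segment_length` too small", call. = FALSE)
  structure(list(n_segments = as.integer(n_segments),
                 n_silent = as.integer(n_silent),
                 n_baseline = as.integer(n_baseline),
                 segment_length = as.integer(segment_length),
                 ramp_slope = ramp_slope, snr_db = snr_db,
                 impulse_offset_ms = impulse_offset_ms,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Add white Gaussian noise at a requested SNR
#'
#' Draws i.i.d. zero-mean Gaussian noise with variance set so that
#' `10*log10(P_signal / P_noise) = snr_db`, where the signal power is the
#' mean square over `active_region` (by default the whole signal). Computing
#' power over the active region only keeps silent segments from diluting the
#' signal power and hence the difficulty implied by a given SNR. Noise is
#' added over the entire record (stationary background).
#'
#' @param signal Numeric vector.
#' @param snr_db Requested SNR in dB; `+Inf` returns the signal unchanged.
#' @param seed Optional RNG seed (`set.seed` is called when non-NULL).
#' @param active_region Indices over which signal power is computed.
#' @return `signal` plus noise.
#' @export
add_noise_at_snr <- function(signal, snr_db, seed = NULL,
                             active_region = NULL) {
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  if (is.null(active_region)) active_region <- seq_along(signal)
  p_sig <- mean(signal[active_region]^2)
  if (!is.finite(p_sig) || p_sig == 0) {
    stop("signal has zero power over the active region; SNR is undefined",
         call. = FALSE)
  }
  noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
  if (!is.null(seed)) set.seed(seed)
  signal + rnorm(length(signal), mean = 0, sd = noise_sd)
}

#' Simulate the benchmark signal with known ground truth
#'
#' Constructs the clean signal as the template convolved with a train of
#' Dirac impulses, one per active segment, the n-th (1-indexed over active
#' segments) scaled by `ramp_slope * n`; the first `n_silent` segments stay
#' zero. White Gaussian noise is then added at the requested SNR (power
#' convention of [add_noise_at_snr()], active region = post-silent samples).
#'
#' @param spec A [benchmark_spec()].
#' @param template An [make_ep_template()] template; defaults to the 30 ms
#'   biphasic shape at the spec's sampling rate.
#' @return List with `recording` (an [emg_recording()], single channel
#'   `"SIM"`) and `truth` (class `ground_truth`: per-segment `active`,
#'   `onset_sample` within segment, `amplitude`, plus the stored `clean` and
#'   `noise` components for SNR re-estimation).
#' @export
simulate_benchmark_signal <- function(spec, template = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (is.null(template)) {
    template <- make_ep_template(sampling_rate = spec$sampling_rate)
  }
  tpl <- template$samples
  offset <- round(spec$impulse_offset_ms / 1000 * spec$sampling_rate)
  if (offset + length(tpl) > spec$segment_length) {
    stop("template (plus offset) does not fit within a segment",
         call. = FALSE)
  }
  n_active <- spec$n_segments - spec$n_silent
  len <- spec$n_segments * spec$segment_length
  clean <- numeric(len)
  amps <- spec$ramp_slope * seq_len(n_active)
  for (j in seq_len(n_active)) {
    seg0 <- (spec$n_silent + j - 1L) * spec$segment_length
    clean[seg0 + offset + seq_along(tpl)] <- amps[j] * tpl
  }
  active_start <- spec$n_silent * spec$segment_length + 1L
  noisy <- add_noise_at_snr(clean, spec$snr_db, seed = spec$seed,
                            active_region = active_start:len)
  onsets <- (seq_len(spec$n_segments) - 1L) * spec$segment_length
  seg_amp <- c(rep(0, spec$n_silent), amps)
  rec <- emg_recording(matrix(noisy, ncol = 1L), spec$sampling_rate,
                       channel_labels = "SIM", pulse_onsets = onsets,
                       pulse_params = seg_amp, param_kind = "amplitude")
  truth <- structure(
    list(active = c(rep(FALSE, spec$n_silent), rep(TRUE, n_active)),
         onset_sample = ifelse(seg_amp > 0, offset, NA_integer_),
         amplitude = seg_amp,
         clean = clean, noise = noisy - clean),
    class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Specification of a mock intensity ramp-up mapping session
#'
#' Describes a full multi-muscle voltage ramp: the stimulation voltage steps
#' up a ladder with `pulses_per_event` pulses per level at `frequency` Hz;
#' each muscle has a true recruitment threshold, above which every pulse
#' evokes a template response whose amplitude grows linearly with the
#' suprathreshold voltage (`amp_gain` uV per volt above one step below
#' threshold), on top of stationary Gaussian background noise.
#'
#' @param muscles Channel labels; default the 14 mapped leg muscles
#'   (left/right SOL, MG, TA, VL, RF, MH, GL).
#' @param voltage_ladder Strictly increasing voltages (default 0.5-10 V in
#'   0.5 V steps).
#' @param pulses_per_event Pulses per voltage level, at least 5.
#' @param thresholds Named numeric, true threshold voltage per muscle;
#'   default spreads thresholds over the middle of the ladder.
#' @param frequency Stimulation frequency in Hz (default 2).
#' @param noise_sd Background noise SD in uV (default 2).
#' @param amp_gain Response gain in uV per volt (default 50).
#' @param impulse_offset_ms Response latency after the pulse (default 10 ms).
#' @param sampling_rate Hz (default 2000).
#' @param seed RNG seed.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(muscles = c("LSOL", "RSOL", "LMG", "RMG", "LTA",
                                     "RTA", "LVL", "RVL", "LRF", "RRF",
                                     "LMH", "RMH", "LGL", "RGL"),
                         voltage_ladder = seq(0.5, 10, by = 0.5),
                         pulses_per_event = 5L, thresholds = NULL,
                         frequency = 2, noise_sd = 2, amp_gain = 50,
                         impulse_offset_ms = 10, sampling_rate = 2000,
                         seed = 1L) {
  if (any(diff(voltage_ladder) <= 0)) {
    stop("`voltage_ladder` must be strictly increasing", call. = FALSE)
  }
  if (pulses_per_event < 5L) {
    stop("`pulses_per_event` must be at least 5 (protocol minimum)",
         call. = FALSE)
  }
  if (is.null(thresholds)) {
    nl <- length(voltage_ladder)
    pick <- round(seq(0.25, 0.75, length.out = length(muscles)) * nl)
    thresholds <- setNames(voltage_ladder[pmin(pmax(pick, 1L), nl)], muscles)
  }
  if (is.null(names(thresholds)) || !all(muscles %in% names(thresholds))) {
    stop("`thresholds` must be named with every muscle", call. = FALSE)
  }
  out_of_ladder <- thresholds[muscles] > max(voltage_ladder) |
    thresholds[muscles] < min(voltage_ladder)
  if (any(out_of_ladder)) {
    warning(sprintf("threshold outside the ladder for %s; never activates",
                    paste(muscles[out_of_ladder], collapse = ", ")),
            call. = FALSE)
  }
  structure(list(muscles = muscles, voltage_ladder = voltage_ladder,
                 pulses_per_event = as.integer(pulses_per_event),
                 thresholds = thresholds[muscles], frequency = frequency,
                 noise_sd = noise_sd, amp_gain = amp_gain,
                 impulse_offset_ms = impulse_offset_ms,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "session_spec")
}

#' Simulate a full mock mapping session
#'
#' @param spec A [session_spec()].
#' @param template Optional [make_ep_template()]; defaults to 30 ms biphasic.
#' @return List with `recording` (multi-channel [emg_recording()] with
#'   per-pulse voltages) and `truth`, a named list per muscle of
#'   `ground_truth` objects (per-pulse `active`, `onset_sample`, `amplitude`,
#'   and the true `v_threshold`).
#' @export
simulate_mapping_session <- function(spec, template = NULL) {
  stopifnot(inherits(spec, "session_spec"))
  if (is.null(template)) {
    template <- make_ep_template(sampling_rate = spec$sampling_rate)
  }
  tpl <- template$samples
  gap <- round(spec$sampling_rate / spec$frequency)
  offset <- round(spec$impulse_offset_ms / 1000 * spec$sampling_rate)
  if (offset + length(tpl) > gap) {
    stop("template does not fit in the inter-pulse interval", call. = FALSE)
  }
  volts <- rep(spec$voltage_ladder, each = spec$pulses_per_event)
  n_pulses <- length(volts)
  onsets <- (seq_len(n_pulses) - 1L) * gap
  len <- n_pulses * gap
  step <- min(diff(spec$voltage_ladder))
  set.seed(spec$seed)
  samples <- matrix(NA_real_, nrow = len, ncol = length(spec$muscles))
  truth <- vector("list", length(spec$muscles))
  names(truth) <- spec$muscles
  for (m in seq_along(spec$muscles)) {
    thr <- spec$thresholds[[m]]
    active <- volts >= thr
    amp <- ifelse(active, spec$amp_gain * (volts - thr + step), 0)
    clean <- numeric(len)
    for (i in which(active)) {
      clean[onsets[i] + offset + seq_along(tpl)] <- amp[i] * tpl
    }
    noise <- rnorm(len, 0, spec$noise_sd)
    samples[, m] <- clean + noise
    truth[[m]] <- structure(
      list(active = active,
           onset_sample = ifelse(active, offset, NA_integer_),
           amplitude = amp, v_threshold = thr),
      class = "ground_truth")
  }
  rec <- emg_recording(samples, spec$sampling_rate,
                       channel_labels = spec$muscles, pulse_onsets = onsets,
                       pulse_params = volts, param_kind = "voltage")
  list(recording = rec, truth = truth)
}
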