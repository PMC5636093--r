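# Shared fixture builders; everything is generated in code, no stored data.

# A segment matrix with given per-row SDs around zero (seeded), used to
# exercise the detectors without a full simulation.
toy_segment_matrix <- function(row_sd, width = 200, sampling_rate = 2000,
                               row_param = NULL, seed = 1) {
  set.seed(seed)
  vals <- t(vapply(row_sd, function(s) rnorm(width, 0, s), numeric(width)))
  segment_matrix(vals, sampling_rate, row_param = row_param)
}

# A small noiseless recording: constant gap, linear samples for exact
# reconstruction checks.
ramp_recording <- function(n = 10000, gap = 1000, sampling_rate = 2000) {
  onsets <- seq(0, n - gap, by = gap)
  emg_recording(seq_len(n), sampling_rate, channel_labels = "m1",
                pulse_onsets = onsets,
                pulse_params = rep(1, length(onsets)),
                param_kind = "voltage")
}

# Small mapping-session spec kept cheap for unit tests.
tiny_session_spec <- function(..., muscles = c("LSOL", "RSOL"),
                              voltage_ladder = seq(0.5, 4, by = 0.5),
                              thresholds = c(LSOL = 2.0, RSOL = 3.0),
                              noise_sd = 1, seed = 7) {
  session_spec(muscles = muscles, voltage_ladder = voltage_ladder,
               thresholds = thresholds, noise_sd = noise_sd, seed = seed, ...)
}

withr_like_tempdir <- function() {
  d <- tempfile("scesmap-test-")
  dir.create(d)
  d
}

expect_file_equal <- function(a, b) {
  expect_identical(readBin(a, "raw", file.info(a)$size),
                   readBin(b, "raw", file.info(b)$size))
}
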