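test_that("EP template satisfies its construction invariants", {
  tpl <- make_ep_template(duration_ms = 30, sampling_rate = 2000)
  expect_length(tpl$samples, 60)
  expect_equal(max(abs(tpl$samples)), 1)
  expect_equal(tpl$samples[1], 0)
  expect_equal(tpl$samples[length(tpl$samples)], 0)
  # biphasic shape is antisymmetric about its midpoint: zero net area
  expect_equal(sum(tpl$samples), 0, tolerance = 1e-12)

  mono <- make_ep_template(shape = "monophasic")
  expect_true(all(mono$samples >= 0))
  expect_equal(max(mono$samples), 1)

  expect_error(make_ep_template(duration_ms = 0), "positive")
  expect_error(make_ep_template(sampling_rate = -1), "positive")
})

test_that("benchmark signal has the stated silent/active structure", {
  spec <- benchmark_spec(snr_db = Inf, seed = 3)
  sim <- simulate_benchmark_signal(spec)
  seg <- segment_by_onsets(sim$recording, 1)
  nonzero <- apply(seg$values, 1, function(r) any(r != 0))
  # 50 segments, the first 20 with no evoked potential
  expect_identical(sum(nonzero), 30L)
  expect_true(all(!nonzero[1:20]))
  # clean peak of the n-th active segment is ramp_slope * n (template peak 1)
  peaks <- apply(abs(seg$values), 1, max)
  expect_equal(peaks[21:50], 0.01 * (1:30), tolerance = 1e-12)
  # ground truth agrees exactly with the clean signal's support
  expect_identical(sim$truth$active, nonzero)
  expect_identical(which(sim$truth$active), 21:50)
})

test_that("benchmark simulation is seed-reproducible", {
  spec <- benchmark_spec(snr_db = 0, seed = 11)
  a <- simulate_benchmark_signal(spec)
  b <- simulate_benchmark_signal(spec)
  expect_identical(a$recording$samples, b$recording$samples)
  c <- simulate_benchmark_signal(benchmark_spec(snr_db = 0, seed = 12))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("additive noise realizes the requested SNR", {
  # large record so the realized power estimate is tight
  spec <- benchmark_spec(segment_length = 200, snr_db = 0, seed = 5)
  sim <- simulate_benchmark_signal(spec)
  tr <- sim$truth
  active <- (spec$n_silent * spec$segment_length + 1):length(tr$clean)
  realized <- 10 * log10(mean(tr$clean[active]^2) / mean(tr$noise^2))
  expect_lt(abs(realized - 0), 0.5)

  spec$snr_db <- -10
  tr <- simulate_benchmark_signal(spec)$truth
  ratio <- mean(tr$noise^2) / mean(tr$clean[active]^2)
  expect_equal(ratio, 10, tolerance = 0.15)

  # noiseless sentinel: output identical to input
  x <- sin(seq(0, 10, length.out = 500))
  expect_identical(add_noise_at_snr(x, Inf), x)
  expect_error(add_noise_at_snr(numeric(100), 0), "zero power")
})

test_that("benchmark spec validation catches inconsistent parameters", {
  expect_error(benchmark_spec(n_silent = 60), "n_silent")
  expect_error(benchmark_spec(n_baseline = 25, n_silent = 20), "n_baseline")
  expect_error(benchmark_spec(ramp_slope = 0), "positive")
  tpl <- make_ep_template(duration_ms = 100)
  expect_error(simulate_benchmark_signal(benchmark_spec(), tpl),
               "does not fit")
})

test_that("mapping session follows the ladder/threshold construction", {
  spec <- tiny_session_spec()
  sim <- simulate_mapping_session(spec)
  rec <- sim$recording
  # 2 Hz stimulation at 2000 Hz sampling: 1000-sample inter-onset gap
  expect_true(all(diff(rec$pulse_onsets) == 1000))
  # per-pulse voltages repeat the ladder pulses_per_event times
  expect_identical(rec$pulse_params,
                   rep(spec$voltage_ladder, each = 5))
  # ground truth: active exactly at and above each muscle's threshold
  expect_identical(sim$truth$LSOL$active, rec$pulse_params >= 2.0)
  expect_identical(sim$truth$RSOL$active, rec$pulse_params >= 3.0)
  # protocol minimum of five pulses per voltage
  expect_error(tiny_session_spec(pulses_per_event = 4), "at least 5")
  # threshold outside ladder: warn, never activates
  expect_warning(
    sp <- tiny_session_spec(thresholds = c(LSOL = 2, RSOL = 99)),
    "never activates")
  expect_true(all(!simulate_mapping_session(sp)$truth$RSOL$active))
})
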