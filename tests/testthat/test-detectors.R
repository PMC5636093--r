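test_that("Gaussian MLE fit uses the divide-by-N deviation and a floor", {
  f <- fit_gaussian_mle(c(1, -1, 1, -1))
  expect_equal(f$mu, 0)
  expect_equal(f$sigma, 1)
  expect_warning(g <- fit_gaussian_mle(rep(2, 10)), "floored")
  expect_equal(g$sigma, 1e-6)
  expect_error(fit_gaussian_mle(1), "at least 2")
  # Monte-Carlo consistency at n = 1e5
  set.seed(1)
  h <- fit_gaussian_mle(rnorm(1e5, 0, 2))
  expect_lt(abs(h$sigma - 2), 0.02)
})

test_that("segment models are fit on the early-response window", {
  seg <- toy_segment_matrix(c(1, 1, 5), width = 1000)
  m <- build_models(seg, fraction = 1 / 8)
  expect_identical(m$n, rep(125L, 3))
  full <- build_models(seg, fraction = 1)
  expect_identical(full$n, rep(1000L, 3))
  expect_error(build_models(seg, fraction = 0), "\\(0, 1\\]")
  expect_error(build_models(toy_segment_matrix(1, width = 8), 1 / 8),
               "fewer than 2")
  # supplied common mean shifts the deviation computation
  seg1 <- segment_matrix(matrix(c(1, 1, 1, 1), 1, 4), 2000)
  expect_equal(build_models(seg1, fraction = 1, mu = 0)$sigma, 1)
})

test_that("baseline model pools the first event's windows", {
  set.seed(3)
  seg <- toy_segment_matrix(rep(5, 10), width = 800,
                            row_param = rep(c(1, 2), each = 5), seed = 3)
  base <- baseline_model(seg, events = group_events(seg))
  expect_lt(abs(base$mu - 0), 3 * 5 / sqrt(500)) # 3 s.e.
  expect_lt(abs(base$sigma - 5), 3 * 5 / sqrt(1000))
  expect_identical(base$n, 500L) # 5 rows x 100-sample windows
  expect_error(baseline_model(seg, baseline_rows = integer()), "empty")
})

test_that("per-sample log-likelihood ratio matches direct evaluation", {
  expect_equal(llr_sample(c(-3, 0, 7), 0, 1, 1), c(0, 0, 0))
  expect_equal(llr_sample(0.5, 0.5, 1, 2), log(1 / 2))
  expect_equal(llr_sample(2, 0, 1, 2),
               log(0.5) + 0.5 * 4 * (1 - 0.25)) # = 0.8068528...
  expect_equal(llr_sample(2, 0, 1, 2), 0.80685281944, tolerance = 1e-10)
})

test_that("closed-form CUSUM matches its printed coefficients", {
  expect_equal(cusum_segment(1, 1, 1, 500), 0)
  # window of 101 samples, sigma_i = 2 sigma_0
  expect_equal(cusum_segment(2, 1, 1, 101), 101 * log(0.5) + 50 * 3)
  expect_equal(cusum_segment(2, 1, 1, 101), 79.99212895, tolerance = 1e-7)
  # the statistic is a divergence: a segment quieter than baseline also
  # scores positive for a long window (0.693n - 0.375(n-1) > 0)
  expect_gt(cusum_segment(0.5, 1, 1, 200), 0)
  expect_equal(cusum_segment(0.5, 1, 1, 200),
               200 * log(2) + 99.5 * (0.25 - 1))
  expect_error(cusum_segment(1, 1, 5, 5), "exceed")
  # symmetric variant uses n/2 on the variance term
  expect_equal(cusum_segment(2, 1, 1, 101, symmetric = TRUE),
               101 * log(0.5) + 50.5 * 3)
})

test_that("closed form tracks the direct per-sample LLR sum within 5%", {
  set.seed(8)
  for (sig in c(1.5, 2, 3)) {
    y <- rnorm(500, 0, sig)
    sigma_i <- sqrt(mean(y^2)) # MLE about the common mean 0
    direct <- sum(llr_sample(y, 0, 1, sigma_i))
    closed <- cusum_segment(sigma_i, 1, 1, 500)
    expect_lt(abs(closed - direct) / abs(direct), 0.05)
  }
})

test_that("dynamic threshold is baseline max plus sample SD", {
  expect_equal(dynamic_threshold(c(1, 2, 3)), 4)
  expect_equal(dynamic_threshold(c(0, 0, 0, 4)), 6)
  expect_equal(dynamic_threshold(rep(7, 5)), 7)
  expect_error(dynamic_threshold(3), "at least 2")
})

test_that("detection is scale-equivariant", {
  seg <- toy_segment_matrix(c(rep(1, 5), 1, 1, 4, 4, 4), width = 400,
                            row_param = rep(c(1, 2), each = 5), seed = 5)
  d1 <- detect_aglr(seg, compute_onsets = FALSE)
  seg2 <- segment_matrix(seg$values * 37.5, seg$sampling_rate,
                         row_param = seg$row_param)
  d2 <- detect_aglr(seg2, compute_onsets = FALSE)
  expect_equal(d1$statistic, d2$statistic, tolerance = 1e-9)
  expect_identical(d1$segment_active, d2$segment_active)
  expect_identical(d1$v_s0, d2$v_s0)
})

test_that("the 50% event quorum decides activation and V_s0", {
  # event 2: 3 of 5 rows loud -> active; event 3: 2 of 5 -> inactive
  sds <- c(rep(1, 5), 8, 8, 8, 1, 1, 8, 8, 1, 1, 1)
  seg <- toy_segment_matrix(sds, width = 640,
                            row_param = rep(c(1, 2, 3), each = 5), seed = 2)
  det <- detect_aglr(seg, fraction = 1, compute_onsets = FALSE)
  expect_identical(det$event_table$active, c(FALSE, TRUE, FALSE))
  expect_identical(det$event_table$n_active, c(0L, 3L, 2L))
  expect_identical(det$v_s0, 2)
  # baseline segments can never exceed their own max-plus-sd threshold
  expect_true(all(!det$segment_active[1:5]))
})

test_that("threshold voltage is recovered on noisy mapping sessions", {
  # the 5-value baseline makes the dynamic threshold a noisy max-plus-sd
  # estimate, so occasional sub-threshold events fire spuriously; recovery
  # errors must only ever be undershoots (false alarms), never missed
  # activation above the true threshold
  hits <- 0L
  for (s in 1:25) {
    spec <- tiny_session_spec(muscles = "M1", thresholds = c(M1 = 3.0),
                              voltage_ladder = seq(0.5, 6, by = 0.5),
                              noise_sd = 2, seed = 100 + s)
    sim <- simulate_mapping_session(spec)
    seg <- segment_by_onsets(sim$recording, 1)
    det <- detect_aglr(seg, compute_onsets = FALSE)
    hits <- hits + as.integer(identical(det$v_s0, 3.0))
    expect_lte(det$v_s0, 3.0)
    # every truly active segment is detected at this SNR
    truth <- sim$truth$M1$active
    expect_true(all(det$segment_active[truth]))
  }
  expect_gte(hits, 20L) # oracle-measured recovery with these seeds: 21/25
})

test_that("TKEO transform matches its algebra", {
  expect_equal(tkeo_transform(rep(3, 10)), rep(0, 8))
  expect_equal(tkeo_transform(as.numeric(1:10)), rep(1, 8))
  expect_equal(tkeo_transform(c(0, 2, 0)), 4)
  expect_error(tkeo_transform(c(1, 2)), "at least 3")
})

test_that("TKEO detector thresholds the per-segment energy maxima", {
  tpl <- make_ep_template()$samples
  sds <- rep(0.5, 10)
  seg <- toy_segment_matrix(sds, width = 200,
                            row_param = rep(c(1, 2), each = 5), seed = 6)
  seg$values[8, 50 + seq_along(tpl)] <- seg$values[8, 50 + seq_along(tpl)] +
    40 * tpl
  det <- detect_tkeo(seg)
  expect_true(det$segment_active[8])
  expect_identical(sum(det$segment_active[1:5]), 0L)
  expect_identical(det$method, "tkeo")
  # all-constant matrix: psi identically zero, nothing activates
  flat <- segment_matrix(matrix(1, 6, 50), 2000, row_param = rep(1:2, each = 3))
  expect_warning(df <- detect_tkeo(flat), "fewer than 5")
  expect_true(all(!df$segment_active))
})

test_that("onset detection localizes a clean template at 10 ms", {
  set.seed(4)
  tpl <- make_ep_template()$samples # 60 samples at 2 kHz
  width <- 500
  noise_sd <- 0.5
  base_rows <- matrix(rnorm(5 * width, 0, noise_sd), 5, width)
  active <- rnorm(width, 0, noise_sd)
  active[20 + seq_along(tpl)] <- active[20 + seq_along(tpl)] + 60 * tpl
  seg <- segment_matrix(rbind(base_rows, active), 2000)
  base <- baseline_model(seg, baseline_rows = 1:5, fraction = 1)
  on_ms <- detect_onset(seg$values[6, ], base, 2000, fraction = 1)
  expect_lt(abs(on_ms - 10), 1)
  # noise-only segment forced through: none-sentinel with warning
  expect_warning(miss <- detect_onset(base_rows[1, ], base, 2000,
                                      sigma_i = base$sigma * 1.0001),
                 "no onset")
  expect_true(is.na(miss))
})

test_that("onsets are reported on the interpolated 10 kHz grid", {
  set.seed(14)
  tpl <- make_ep_template()$samples
  width <- 400
  base_rows <- matrix(rnorm(4 * width, 0, 0.5), 4, width)
  active <- rnorm(width, 0, 0.5)
  active[30 + seq_along(tpl)] <- active[30 + seq_along(tpl)] + 50 * tpl
  seg <- segment_matrix(rbind(base_rows, active), 2000)
  base <- baseline_model(seg, baseline_rows = 1:4, fraction = 1)
  on_ms <- detect_onset(seg$values[5, ], base, 2000, fraction = 1)
  # 10 kHz resolution: onset is a multiple of 0.1 ms, finer than the 0.5 ms
  # native sample spacing
  expect_equal(on_ms * 10, round(on_ms * 10), tolerance = 1e-9)
})
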