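test_that("pixel objective evaluates the printed form", {
  p <- ggmrf_params()
  # candidate equal to observed and every neighbour: both terms vanish
  expect_equal(pixel_objective(5, 5, c(5, 5, 5), p), 0)
  # data term only: |0-1|^2 = 1, prior terms are |0-0|^1.01 = 0
  expect_equal(pixel_objective(0, 1, c(0, 0), p), 1)
  # strictly convex in the candidate for q = 2, p > 1: unique minimizer
  grid <- seq(-2, 2, length.out = 401)
  cost <- pixel_objective(grid, 1, c(-1, 0.5), p)
  d1 <- diff(cost)
  expect_true(all(diff(d1) > -1e-10)) # non-decreasing slope
  expect_identical(sum(diff(sign(d1)) != 0), 1L) # single sign change

  expect_error(pixel_objective(0, 1, numeric(0), p), "nonempty")
})

test_that("denoising is the identity on constants and for zero sweeps", {
  m <- matrix(3.5, 8, 8)
  expect_equal(ggmrf_denoise(m), m, ignore_attr = TRUE)
  r <- matrix(rnorm(64), 8, 8)
  expect_equal(ggmrf_denoise(r, ggmrf_params(tol = Inf)), r,
               ignore_attr = TRUE)
  expect_error(ggmrf_denoise(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
  expect_error(ggmrf_denoise(matrix(1, 1, 5)), "at least 2x2")
})

test_that("an isolated impulse is shrunk and output stays in input range", {
  m <- matrix(0, 9, 9)
  m[5, 5] <- 100
  out <- ggmrf_denoise(m)
  expect_lt(out[5, 5], 100)
  expect_true(all(out >= 0 & out <= 100))
  for (s in 1:5) {
    r <- matrix(rnorm(100, sd = 10), 10, 10)
    o <- ggmrf_denoise(r, ggmrf_params(max_iters = 5, tol = 1e-4))
    expect_true(all(o >= min(r) - 1e-9 & o <= max(r) + 1e-9))
  }
})

test_that("per-pixel minimizer matches a dense grid search", {
  # run ICM to coordinate-wise convergence, then check >= 100 pixels against
  # an independent dense-grid minimization of the pixel objective
  set.seed(42)
  p <- ggmrf_params(max_iters = 300, tol = 1e-10)
  checked <- 0L
  for (rep in 1:3) {
    obs <- matrix(rnorm(49, sd = 5), 7, 7)
    est <- ggmrf_denoise(obs, p)
    nr <- nrow(obs); nc <- ncol(obs)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        nb <- c()
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          nb <- c(nb, est[min(max(i + di, 1), nr), min(max(j + dj, 1), nc)])
        }
        lo <- min(obs[i, j], nb); hi <- max(obs[i, j], nb)
        grid <- seq(lo, hi, length.out = 2001)
        best <- grid[which.min(pixel_objective(grid, obs[i, j], nb, p))]
        step <- (hi - lo) / 2000
        expect_lt(abs(est[i, j] - best), step + 1e-8)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 100L)
})

test_that("coordinate-descent sweeps monotonically decrease the objective", {
  set.seed(9)
  obs <- matrix(rnorm(144, sd = 3), 12, 12)
  p0 <- ggmrf_params(tol = 0)
  objs <- vapply(1:6, function(k) {
    p <- ggmrf_params(max_iters = k, tol = 0)
    scesmap:::ggmrf_objective(ggmrf_denoise(obs, p), obs, p0)
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-8))
  expect_lt(objs[6], scesmap:::ggmrf_objective(obs, obs, p0))
})

test_that("smoothing preserves the latency of a clean template", {
  tpl <- make_ep_template()$samples
  width <- 120
  row <- numeric(width)
  row[30 + seq_along(tpl)] <- tpl
  m <- outer(seq(0.5, 1.5, length.out = 10), row) * 100
  out <- ggmrf_denoise(m)
  for (i in 1:10) {
    expect_lte(abs(which.max(out[i, ]) - which.max(m[i, ])), 1)
  }
})

test_that("SNR estimation from the smoothed decomposition is exact", {
  sm <- matrix(rnorm(1000), 10, 100)
  e <- matrix(rnorm(1000), 10, 100)
  e <- e * sqrt(sum(sm^2) / sum(e^2)) # equal powers
  expect_equal(estimate_snr(sm + e, sm), 0)
  e10 <- e * sqrt(10)
  expect_equal(estimate_snr(sm + e10, sm), -10)
  expect_identical(estimate_snr(sm, sm), Inf)
  expect_identical(estimate_snr(e, matrix(0, 10, 100)), -Inf)
  expect_error(estimate_snr(sm, matrix(0, 5, 5)), "shapes")
})

test_that("parameter validation enforces the model's ranges", {
  expect_error(ggmrf_params(p = 0.5), "1.01")
  expect_error(ggmrf_params(q = 3), "1 or 2")
  expect_error(ggmrf_params(b = -1), "positive")
})
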