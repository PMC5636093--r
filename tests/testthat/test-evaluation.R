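test_that("confusion tabulates element-wise", {
  expect_identical(confusion(rep(1, 6), rep(1, 6)),
                   list(tp = 6L, tn = 0L, fp = 0L, fn = 0L))
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  expect_identical(confusion(c(1, 0), c(0, 1)),
                   list(tp = 0L, tn = 0L, fp = 1L, fn = 1L))
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("metrics reproduce hand-computed values on all 2x2 patterns", {
  # every (pred, truth) pattern over two segments: 16 cases
  for (p1 in 0:1) for (p2 in 0:1) for (t1 in 0:1) for (t2 in 0:1) {
    pred <- c(p1, p2); truth <- c(t1, t2)
    cc <- confusion(pred, truth)
    m <- metrics(cc)
    v <- setNames(m$value, m$metric)
    tp <- sum(pred & truth); tn <- sum(!pred & !truth)
    fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    expect_equal(v[["accuracy"]], 100 * (tp + tn) / 2)
    if (tp + fn > 0) expect_equal(v[["sensitivity"]], 100 * tp / (tp + fn))
    else expect_true(is.na(v[["sensitivity"]]))
    if (tn + fp > 0) expect_equal(v[["specificity"]], 100 * tn / (tn + fp))
    else expect_true(is.na(v[["specificity"]]))
    if (2 * tp + fp + fn > 0) {
      expect_equal(v[["dice"]], 100 * 2 * tp / (2 * tp + fp + fn))
    } else {
      expect_true(is.na(v[["dice"]]))
    }
  }
})

test_that("worked confusion example and undefined-ratio flagging", {
  m <- metrics(list(tp = 90, fn = 10, tn = 80, fp = 20))
  v <- setNames(m$value, m$metric)
  expect_equal(v[["sensitivity"]], 90)
  expect_equal(v[["specificity"]], 80)
  expect_equal(v[["accuracy"]], 85)
  expect_equal(v[["dice"]], 85.7142857, tolerance = 1e-7)
  # no positives at all: sensitivity undefined, flagged not 100
  m0 <- metrics(list(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_false(m0$defined[m0$metric == "sensitivity"])
  expect_true(is.na(m0$value[m0$metric == "sensitivity"]))
})

test_that("Dice equals the precision/recall harmonic form", {
  set.seed(2)
  for (i in 1:20) {
    cc <- list(tp = sample(1:50, 1), tn = sample(0:50, 1),
               fp = sample(0:50, 1), fn = sample(0:50, 1))
    v <- setNames(metrics(cc)$value, metrics(cc)$metric)
    prec <- cc$tp / (cc$tp + cc$fp)
    rec <- cc$tp / (cc$tp + cc$fn)
    expect_equal(v[["dice"]], 100 * 2 * prec * rec / (prec + rec))
  }
})

test_that("five-number summary uses linear quartile interpolation", {
  expect_equal(unname(five_number_summary(1:5)), c(1, 2, 3, 4, 5))
  expect_equal(unname(five_number_summary(7)), rep(7, 5))
  expect_equal(unname(five_number_summary(c(1, 2, 3, 4))),
               c(1, 1.75, 2.5, 3.25, 4))
  expect_error(five_number_summary(numeric()), "empty")
})

test_that("SNR sweep is deterministic and perfect in the noiseless limit", {
  suppressWarnings({
    a <- snr_sweep(snr_db = Inf, n_reps = 1, base_seed = 5)
    b <- snr_sweep(snr_db = Inf, n_reps = 1, base_seed = 5)
  })
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$mean_accuracy == 100))
})

test_that("detector accuracy does not degrade as SNR rises", {
  tab <- snr_sweep(snr_db = c(-10, 10), n_reps = 8, base_seed = 3)
  for (d in unique(tab$detector)) {
    lo <- tab[tab$detector == d & tab$snr_db == -10, ]
    hi <- tab[tab$detector == d & tab$snr_db == 10, ]
    se <- sqrt(lo$sd_accuracy^2 + hi$sd_accuracy^2) / sqrt(8)
    expect_gte(hi$mean_accuracy, lo$mean_accuracy - 2 * se)
    expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 100))
  }
})
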