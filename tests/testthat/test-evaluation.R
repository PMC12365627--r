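test_that("confusion metrics evaluate the standard formulas exactly", {
  perfect <- confusion_metrics(tibble::tibble(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  m <- confusion_metrics(tibble::tibble(TP = 20, TN = 21, FP = 0, FN = 1))
  expect_equal(m$sensitivity, 20 / 21)            # 95.24%
  expect_equal(round(100 * m$sensitivity, 2), 95.24)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 21 / 22)
  expect_equal(m$accuracy, 41 / 42)
  expect_equal(m$sensitivity + (m$FN / (m$TP + m$FN)), 1)  # sens + FNR = 1

  und <- confusion_metrics(tibble::tibble(TP = 0, TN = 5, FP = 2, FN = 0))
  expect_true(is.na(und$sensitivity))
  expect_false(is.na(und$specificity))
  expect_error(confusion_metrics(tibble::tibble(TP = -1, TN = 1, FP = 1, FN = 1)),
               "nonnegative")
})

test_that("Mann-Whitney U matches enumeration and the large-sample approximation", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 1 / 3)
  expect_equal(r$p.value, oracle_u_exact(c(1, 2), c(3, 4)))

  # identical multisets: U = n1*n2/2 by symmetry
  x <- c(1, 2, 2, 5)
  expect_equal(rank_sum_test(x, x)$U, 8)

  # exact vs normal approximation at n1 = n2 = 5
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5, 0.5)
    exact <- rank_sum_test(a, b, exact_max = 10)
    approx <- rank_sum_test(a, b, exact_max = 0)
    expect_equal(exact$p.value, oracle_u_exact(a, b))
    expect_lt(abs(exact$p.value - approx$p.value), 0.05)
  }

  # tie-free case agrees with the reference implementation
  set.seed(14)
  a <- rnorm(12); b <- rnorm(15, 1)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(rank_sum_test(a, b)$U, unname(ref$statistic))

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("ROC curves anchor, stay monotone and integrate to the rank AUC", {
  sep <- ev_roc(c(5, 6, 7, 1, 2, 3), rep(c("cvd", "healthy"), each = 3), "cvd")
  expect_equal(attr(sep, "auc"), 1.0)
  expect_equal(sep$tpr[1], 0); expect_equal(sep$fpr[1], 0)
  expect_equal(utils::tail(sep$tpr, 1), 1); expect_equal(utils::tail(sep$fpr, 1), 1)
  expect_true(all(diff(sep$tpr) >= 0))
  expect_true(all(diff(sep$fpr) >= 0))

  # AUC = U/(n1 n2) on tie-free data
  set.seed(15)
  sc <- rnorm(60)
  lab <- rep(c("healthy", "cvd"), 30)
  r <- ev_roc(sc, lab, "cvd")
  U <- rank_sum_test(sc[lab == "cvd"], sc[lab == "healthy"])$U
  expect_equal(attr(r, "auc"), U / (30 * 30), tolerance = 1e-12)

  # independent scores: AUC near 1/2
  set.seed(16)
  r2 <- ev_roc(rnorm(1000), sample(rep(c("a", "b"), 500)), "b")
  expect_lt(abs(attr(r2, "auc") - 0.5), 0.05)
  ci <- attr(r2, "ci95")
  expect_true(ci[1] < 0.5 && ci[2] > 0.5)

  expect_error(ev_roc(1:5, rep("a", 5)), "both classes")
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- c(rnorm(40, 1), rnorm(40))
  lab <- rep(c("cvd", "healthy"), each = 40)
  ours <- attr(ev_roc(sc, lab, "cvd"), "auc")
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("healthy", "cvd"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("box statistics use interpolated quartiles with min/max whiskers", {
  b <- box_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3); expect_equal(b$q1, 2); expect_equal(b$q3, 4)
  expect_equal(b$whisker_low, 1); expect_equal(b$whisker_high, 5)

  one <- box_stats(7)
  expect_true(all(unlist(one[c("min", "q1", "median", "q3", "max", "mean")]) == 7))

  set.seed(18)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1))
    b <- box_stats(x)
    expect_equal(b$q1, oracle_quartile(x, 0.25))
    expect_equal(b$median, oracle_quartile(x, 0.5))
    expect_equal(b$q3, oracle_quartile(x, 0.75))
    expect_true(b$min <= b$q1 && b$q1 <= b$median &&
                  b$median <= b$q3 && b$q3 <= b$max)
  }
  expect_error(box_stats(numeric(0)), "non-empty")
})

test_that("band reports recover group differences at the disease bands", {
  ds <- ev_simulate_spectra(tibble::tibble(fraction = "small",
                                           state = c("healthy", "cvd"), n = 20),
                            seed = 19)
  clean <- ev_preprocess(ds)
  rep_ <- band_report(clean, c(960), group = "state")
  expect_equal(unique(rep_$band), 960)
  m_cvd <- rep_$mean[rep_$group == "cvd"]
  m_h <- rep_$mean[rep_$group == "healthy"]
  expect_gt(m_cvd, m_h)
  expect_lt(rep_$p.value[1], 0.05)

  # identical groups: duplicated spectra under both labels give p = 1
  h <- ev_simulate_spectra(tibble::tibble(fraction = "small",
                                          state = "healthy", n = 20), seed = 20)
  m <- ev_intensities(h)
  same <- ev_dataset(rbind(m, m), ev_wavenumbers(h),
                     tibble::tibble(sample_id = sprintf("d%02d", 1:40),
                                    state = rep(c("healthy", "cvd"), each = 20)))
  rep0 <- band_report(same, 960, group = "state")
  expect_gte(rep0$p.value[1], 0.5)

  multi <- band_report(clean, c(851, 960, 1003, 1656), group = "state")
  expect_equal(nrow(multi), 8)  # band x group
  expect_true(all(multi$p.adjusted >= multi$p.value - 1e-12))
  expect_error(band_report(clean, 5000), "outside")
})
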