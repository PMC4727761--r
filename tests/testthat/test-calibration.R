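test_that("SEP follows the pinned n-denominator formula", {
  expect_equal(sep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sep(c(0, 0, 0, 0), c(1, -1, 1, -1)), 1.0)
  expect_equal(sep(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_error(sep(1:3, 1:4), "equal length")

  set.seed(1)
  y <- rnorm(10); yh <- rnorm(10)
  for (a in c(0.5, 2, -3)) {
    expect_equal(sep(a * y, a * yh), abs(a) * sep(y, yh), tolerance = 1e-12)
  }
})

test_that("SEP percent scales by the property mean and gates QC strictly at 15", {
  expect_equal(sep_percent(0.5, c(4, 6)), 10)
  expect_equal(sep_percent(0, c(1, 2)), 0)
  expect_error(sep_percent(1, c(0, 0)), "positive")
  expect_error(sep_percent(1, c(-2, 1)), "positive")

  expect_equal(qc_verdict(13.54), "QUANTIFY")
  expect_equal(qc_verdict(18.51), "ESTIMATE_ONLY")
  expect_equal(qc_verdict(14.999), "QUANTIFY")
  expect_equal(qc_verdict(15.0), "ESTIMATE_ONLY")
  expect_equal(qc_verdict(0), "QUANTIFY")
})

test_that("explained variance and correlation match arithmetic oracles", {
  y <- c(1, 2, 3)
  expect_equal(variance_explained(y, y), 100)
  expect_equal(variance_explained(y, rep(2, 3)), 0)
  expect_equal(variance_explained(y, c(1, 2, 4)), 50)
  expect_error(variance_explained(rep(1, 3), y), "zero variance")

  expect_equal(correlation_r(y, y), 1)
  expect_equal(correlation_r(y, -y + 5), -1)
  expect_equal(correlation_r(y, c(1, 2, 4)), 0.9820, tolerance = 1e-3)
  expect_error(correlation_r(rep(1, 3), y), "zero variance")

  # exact least-squares rescaling: variance == 100 * r^2
  set.seed(2)
  yt <- rnorm(30)
  yp <- yt * 2 + rnorm(30, sd = 0.5)
  fitted_ls <- fitted(lm(yt ~ yp))
  expect_equal(variance_explained(yt, fitted_ls),
               100 * correlation_r(yt, fitted_ls)^2, tolerance = 1e-10)
})

test_that("cross-validation handles degenerate and duplicated inputs", {
  set.seed(3)
  X <- matrix(rnorm(50), 10)
  y <- rnorm(10)
  c0 <- cross_validate(X, y, 0)
  expect_equal(nrow(c0), 1)
  loo_mean <- vapply(1:10, function(i) mean(y[-i]), numeric(1))
  expect_equal(c0$sep, sep(y, loo_mean))

  Xd <- rbind(X, X); yd <- c(y, y)
  cd <- cross_validate(Xd, yd, 4)
  expect_true(all(is.finite(cd$sep)))

  expect_error(cross_validate(X, y, 9), "max_lv")
  expect_error(cross_validate(X[1:2, ], y[1:2], 0), "3 samples")
})

test_that("LOO cross-validation equals the n-refits brute-force loop bitwise", {
  d <- small_design(seed = 13)
  dat <- generate_calibration_set(d)   # 15 samples
  des <- apply_recipe(dat$set, default_recipes()$total)
  y <- dat$reference$total
  max_lv <- 6
  curve <- cross_validate(des$matrix, y, max_lv)
  preds <- attr(curve, "predictions")

  brute <- matrix(NA_real_, length(y), max_lv + 1)
  for (i in seq_along(y)) {
    for (k in 0:max_lv) {
      fit <- fit_pls1(des$matrix[-i, , drop = FALSE], y[-i], k)
      brute[i, k + 1] <- as.numeric(
        predict(fit, des$matrix[i, , drop = FALSE]))
    }
  }
  expect_identical(preds, brute)
  expect_identical(curve$sep,
                   vapply(0:max_lv, function(k) sep(y, brute[, k + 1]),
                          numeric(1)))
})

test_that("k-fold CV is seeded and reproducible", {
  set.seed(4)
  X <- matrix(rnorm(200), 20)
  y <- drop(X %*% rnorm(10)) + rnorm(20, sd = 0.1)
  a <- cross_validate(X, y, 4, cv_kfold(5, seed = 99))
  b <- cross_validate(X, y, 4, cv_kfold(5, seed = 99))
  expect_identical(a$sep, b$sep)
  expect_error(cv_kfold(5), "seed")
})

test_that("optimal LV selection is the argmin with ties toward fewer LVs", {
  curve <- data.frame(n_lv = 0:4, sep = c(5, 3, 1, 2, 4))
  class(curve) <- c("sep_curve", "data.frame")
  expect_equal(select_optimal_lv(curve), 2)

  tie <- data.frame(n_lv = 0:2, sep = c(3, 1, 1))
  class(tie) <- c("sep_curve", "data.frame")
  expect_equal(select_optimal_lv(tie), 1)

  expect_error(select_optimal_lv(data.frame()), "empty")
})

test_that("noiseless three-component mixtures are recovered at exactly 3 LVs", {
  d <- noiseless_design()
  dat <- generate_calibration_set(d)
  for (a in c("daidzin", "genistin", "glycitin")) {
    curve <- cross_validate(dat$set$matrix, dat$reference[[a]], 6)
    expect_equal(select_optimal_lv(curve), 3)
    expect_lt(curve$sep[curve$n_lv == 3], 1e-6)
    expect_true(all(curve$sep[curve$n_lv == 3] <= curve$sep + 1e-15))
  }
})

test_that("calibrate_analyte produces a consistent, deterministic report", {
  d <- noiseless_design()
  dat <- generate_calibration_set(d)
  rec <- preprocess_recipe(step_offset())
  res <- calibrate_analyte(dat$set, dat$reference, "genistin", rec, max_lv = 5)
  expect_gt(res$report$variance, 99.999)
  expect_gt(res$report$r, 0.99999)
  expect_equal(res$report$qc, "QUANTIFY")
  expect_equal(res$report$sep_percent,
               100 * res$report$sep / mean(res$report$y_reference),
               tolerance = 1e-9)

  res2 <- calibrate_analyte(dat$set, dat$reference, "genistin", rec, max_lv = 5)
  expect_identical(res$report, res2$report)

  flat <- dat$reference
  flat$genistin <- rep(0.05, nrow(flat))
  flat$total <- flat$daidzin + flat$genistin + flat$glycitin
  expect_error(
    calibrate_analyte(dat$set, flat, "genistin", rec, max_lv = 5),
    "zero variance")

  tiny <- spectra_set(dat$set$grid, dat$set$matrix[1:3, ],
                      dat$set$sample_ids[1:3])
  expect_error(calibrate_analyte(tiny, dat$reference, "genistin", rec, 5),
               ">= 5")
})

test_that("training metrics are reported alongside CV metrics on request", {
  d <- small_design(seed = 21)
  dat <- generate_calibration_set(d)
  res <- calibrate_analyte(dat$set, dat$reference, "total",
                           default_recipes()$total, max_lv = 6,
                           training_metrics = TRUE)
  expect_true(is.numeric(res$report$training_variance))
  expect_gte(res$report$training_variance, res$report$variance - 1e-9)
  expect_s3_class(as.data.frame(res$report), "data.frame")
})
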