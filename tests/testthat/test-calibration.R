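noise_free_setup <- function() {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0)
  list(d = d,
       Xc = sp$absorbance[d$calibration_ids, ], Yc = calibration_set(d),
       Xv = sp$absorbance[d$validation_ids, ], Yv = validation_set(d))
}

test_that("PCR and PLS recover a noise-free six-component system exactly", {
  s <- noise_free_setup()
  for (m in c("pcr", "pls")) {
    fit <- calibrate(s$Xc, s$Yc, method = m, ncomp = 6)
    expect_lt(max(abs(predict(fit, s$Xv) - s$Yv)), 1e-6)
    expect_lt(max(abs(fit$fitted - s$Yc)), 1e-6)
  }
})

test_that("at full rank PCR and PLS predictions equal ordinary least squares", {
  inst <- small_instance()
  oracle <- ols_predictions(inst$X, inst$Y, inst$X)
  for (m in c("pcr", "pls")) {
    fit <- calibrate(inst$X, inst$Y, method = m, ncomp = ncol(inst$X))
    expect_equal(predict(fit, inst$X), oracle, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("constant responses give zero coefficients and mean predictions", {
  inst <- small_instance()
  Y <- matrix(5, nrow(inst$X), 2)
  for (m in c("pcr", "pls")) {
    fit <- calibrate(inst$X, Y, method = m, ncomp = 2)
    expect_lt(max(abs(coef(fit))), 1e-10)
    expect_true(all(abs(predict(fit, inst$X) - 5) < 1e-10))
  }
})

test_that("requesting more latent variables than the rank is an error", {
  s <- noise_free_setup()   # rank 6 data
  expect_error(calibrate(s$Xc, s$Yc, method = "pcr", ncomp = 10), "rank")
  expect_error(calibrate(s$Xc, s$Yc, method = "pls", ncomp = 10), "rank")
})

test_that("predicting at the spectral mean returns the response mean for every method", {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0.002, seed = 5)
  X <- sp$absorbance[d$calibration_ids, ]
  Y <- calibration_set(d)
  for (m in c("pcr", "pls", "ann")) {
    fit <- calibrate(X, Y, method = m, ncomp = 6, epochs = 50)
    expect_equal(drop(predict(fit, colMeans(X))), colMeans(Y),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("univariate Beer-Lambert: one PLS factor on rank-1 data recovers the slope", {
  conc <- seq(2, 10, length.out = 8)
  s <- gaussian_pure_spectrum(list(c(250, 5, 0.1)))$sensitivity
  X <- outer(conc, s)
  fit <- calibrate(X, matrix(conc), method = "pls", ncomp = 1)
  expect_lt(max(abs(predict(fit, X) - conc)), 1e-8)
})

test_that("leave-one-out RMSECV finds the true dimensionality of clean data", {
  s <- noise_free_setup()
  sel <- select_ncomp(s$Xc, s$Yc, max_ncomp = 8, method = "pcr")
  expect_length(sel$rmsecv, 8)
  expect_lt(sel$rmsecv[6], 1e-6)
  expect_lte(sel$chosen, 6)
  expect_equal(dim(sel$per_analyte), c(8, 6))
})

test_that("RMSECV is high at one factor and plateaus near the component count under noise", {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0.002, seed = 21)
  sel <- select_ncomp(sp$absorbance[d$calibration_ids, ], calibration_set(d),
                      max_ncomp = 10, method = "pls")
  expect_gt(sel$rmsecv[1], 10 * min(sel$rmsecv))
  expect_gte(sel$chosen, 5)
  expect_lt(sel$rmsecv[6] / sel$rmsecv[1], 0.05)
})

test_that("select_ncomp validates its bounds", {
  s <- noise_free_setup()
  expect_error(select_ncomp(s$Xc, s$Yc, max_ncomp = 0), ">= 1")
  expect_error(select_ncomp(s$Xc, s$Yc, max_ncomp = 16), "n - 2")
})

test_that("trained linear network matches the least-squares oracle on clean data", {
  s <- noise_free_setup()
  fit <- calibrate(s$Xc, s$Yc, method = "ann", epochs = 20000, seed = 2)
  expect_lt(max(abs(predict(fit, s$Xv) - s$Yv)), 1e-3)
})

test_that("network training is seeded, recorded, and never beats least squares in sample", {
  inst <- small_instance()
  f1 <- calibrate(inst$X, inst$Y, method = "ann", epochs = 200, seed = 9)
  f2 <- calibrate(inst$X, inst$Y, method = "ann", epochs = 200, seed = 9)
  expect_identical(f1$weights, f2$weights)
  expect_length(f1$mse_history, 200)
  expect_true(all(diff(f1$mse_history) <= 1e-12))
  f3 <- calibrate(inst$X, inst$Y, method = "ann", epochs = 1, seed = 9)
  expect_length(f3$mse_history, 1)
  # affine subsumption: the network cannot do better than OLS on its
  # training data
  ols_mse <- mean((ols_predictions(inst$X, inst$Y, inst$X) - inst$Y)^2)
  expect_gte(tail(f1$mse_history, 1), ols_mse - 1e-12)
  expect_error(calibrate(inst$X, inst$Y, method = "ann", epochs = 0), "epochs")
})

test_that("a fixed oversized learning rate triggers the divergence error", {
  inst <- small_instance()
  expect_error(calibrate(inst$X, inst$Y, method = "ann", epochs = 500,
                         learning_rate = 1e6),
               "diverged")
})

test_that("model JSON serialisation preserves predictions", {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0.002, seed = 5)
  fit <- calibrate(sp$absorbance[d$calibration_ids, ], calibration_set(d),
                   method = "pls", ncomp = 8)
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  fit2 <- read_model_json(path)
  expect_equal(predict(fit2, sp$absorbance[d$validation_ids, ]),
               predict(fit, sp$absorbance[d$validation_ids, ]),
               tolerance = 1e-12)
})
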