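test_that("fnnls handles trivial and projection cases", {
  # unconstrained optimum already non-negative
  set.seed(1)
  Z <- matrix(rnorm(20), 5, 4)
  xtrue <- c(1, 2, 0.5, 3)
  b <- Z %*% xtrue
  expect_equal(fnnls(Z, b), xtrue, tolerance = 1e-8)
  # identity projection clips negatives
  expect_equal(fnnls(diag(3), c(1, -2, 3)), c(1, 0, 3))
  expect_error(fnnls(matrix(c(1, NA), 1, 2), 1), "finite")
})

test_that("fnnls agrees with brute-force active-set enumeration", {
  set.seed(77)
  for (rep in 1:100) {
    Z <- matrix(rnorm(12), 4, 3)
    b <- rnorm(4)
    x <- fnnls(Z, b)
    oracle <- brute_force_nnls(Z, b)
    expect_true(all(x >= 0))
    expect_lte(sum((Z %*% x - b)^2), oracle$objective + 1e-8)
    expect_equal(x, oracle$x, tolerance = 1e-6)
  }
})

test_that("SIMPLISMA finds exclusive channels in a two-component mixture", {
  # two components, each with a wavelength where only it absorbs
  g <- wavelength_grid()
  s1 <- gaussian_pure_spectrum(list(c(238, 2, 1)))$sensitivity
  s2 <- gaussian_pure_spectrum(list(c(260, 2, 1)))$sensitivity
  set.seed(3)
  C <- cbind(runif(10, 1, 5), runif(10, 1, 5))
  A <- C %*% rbind(s1, s2)
  si <- simplisma(A, 2)
  expect_setequal(round(si$wavelengths), c(238, 260))
  # one component: the single purest channel maximises sigma/(mu+alpha)
  si1 <- simplisma(A, 1)
  mu <- colMeans(A); sg <- sqrt(colMeans(sweep(A, 2, mu)^2))
  alpha <- 0.05 * max(mu)
  expect_identical(si1$indices, which.max(sg / (mu + alpha)))
})

test_that("SIMPLISMA rejects a constant matrix", {
  expect_error(simplisma(matrix(1, 5, 361), 2), "degenerate")
})

test_that("ALS from the true spectra leaves exact bilinear data unchanged", {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0)
  S_true <- sapply(pure_spectra_library(), function(p) p$sensitivity)
  dec <- mcr_als(sp, 6, S0 = S_true)
  expect_lte(dec$lof_percent, 1e-6)
  expect_gte(dec$r2_percent, 100 - 1e-8)
  expect_true(all(dec$C >= 0))
  expect_true(all(dec$S >= 0))
})

test_that("ALS with SIMPLISMA start resolves the library at zero noise", {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0)
  dec <- mcr_als(sp, 6)
  S_true <- sapply(pure_spectra_library(), function(p) p$sensitivity)
  al <- align_components(dec$S, S_true)
  expect_setequal(al$order, 1:6)          # a clean permutation
  expect_true(all(al$correlation >= 0.999))
})

test_that("rank-1 ALS reconstruction equals the truncated SVD", {
  conc <- seq(1, 9, length.out = 7)
  s <- gaussian_pure_spectrum(list(c(250, 6, 0.1)))$sensitivity
  A <- outer(conc, s)
  dec <- mcr_als(A, 1, max_iter = 200)
  sv <- svd(A)
  A1 <- sv$d[1] * outer(sv$u[, 1], sv$v[, 1])
  expect_lt(max(abs(tcrossprod(dec$C, dec$S) - A1)), 1e-8)
})

test_that("lack of fit never increases along the ALS iterations", {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0.002, seed = 13)
  dec <- mcr_als(sp, 6, max_iter = 40)
  expect_true(all(diff(dec$lof_history) <= 1e-12))
})

test_that("explained variance and lack of fit satisfy their exact identity", {
  d <- default_design()
  for (ns in c(0.001, 0.005)) {
    dec <- mcr_als(simulate_spectra(d, noise_sd = ns, seed = 17), 6,
                   max_iter = 30)
    expect_equal(dec$r2_percent, 100 * (1 - (dec$lof_percent / 100)^2),
                 tolerance = 1e-12)
  }
})

test_that("resolved S columns are unit norm and constraints hold", {
  d <- default_design()
  dec <- mcr_als(simulate_spectra(d, noise_sd = 0.002, seed = 19), 6,
                 max_iter = 30)
  expect_equal(unname(colSums(dec$S^2)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(dec$C >= 0))
  expect_true(all(dec$S >= 0))
})

test_that("quantitation from resolved profiles is exact on clean data", {
  # pure-spectra initialisation: the decomposition itself is then exact and
  # any quantitation error would come from the pseudo-univariate step
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0)
  S_true <- sapply(pure_spectra_library(), function(p) p$sensitivity)
  dec <- mcr_als(sp, 6, S0 = S_true)
  qr_ <- mcr_quantify(dec, d$calibration_ids, calibration_set(d))
  expect_lt(max(abs(qr_$predictions[d$validation_ids, ] - validation_set(d))),
            1e-6)
  # calibration rows recover themselves
  expect_lt(max(abs(qr_$predictions[d$calibration_ids, ] -
                      calibration_set(d))), 1e-6)
})

test_that("quantitation is invariant to component permutation and rescaling", {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0.002, seed = 23)
  dec <- mcr_als(sp, 6, max_iter = 50)
  perm <- c(3, 1, 6, 2, 5, 4)
  scale <- c(2, 0.5, 1.5, 3, 0.25, 1)
  dec2 <- dec
  dec2$C <- dec$C[, perm] %*% diag(scale)
  dec2$S <- sweep(dec$S[, perm], 2, scale, `/`)
  q1 <- mcr_quantify(dec, d$calibration_ids, calibration_set(d))
  q2 <- mcr_quantify(dec2, d$calibration_ids, calibration_set(d))
  expect_equal(q2$predictions, q1$predictions, tolerance = 1e-9)
})

test_that("ambiguous alignment of components to analytes is detected", {
  d <- default_design()
  sp <- simulate_spectra(d, noise_sd = 0)
  dec <- mcr_als(sp, 6)
  dec$C <- dec$C[, c(1, 1, 2, 3, 4, 5)]   # duplicate component
  expect_error(mcr_quantify(dec, d$calibration_ids, calibration_set(d)),
               "ambiguous")
})
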