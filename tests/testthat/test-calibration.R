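# Saturation-exponential calibration, inversion, error budget, LOD.
# Frozen constants come from a 40-digit arbitrary-precision evaluation of
# the same closed forms.

test_that("the forward model passes the origin, saturates, and matches the oracle", {
  expect_equal(saturation_model(355.7, 0.069, 0), 0)
  expect_equal(saturation_model(355.7, 0.069, 1e9), 355.7)
  expect_equal(saturation_model(355.7, 0.069, 10), 177.28939223320405,
               tolerance = 1e-14)
  C <- seq(0, 80, by = 5)
  expect_true(all(diff(saturation_model(355.7, 0.069, C)) > 0))
})

test_that("full fit recovers noiseless parameters and interpolates two points", {
  C <- c(5, 10, 20, 40, 75)
  pts <- calibration_points(C, saturation_model(355.7, 0.069, C))
  fit <- fit_full(pts)
  expect_equal(fit$A, 355.7, tolerance = 1e-6)
  expect_equal(fit$B, 0.069, tolerance = 1e-6)

  two <- calibration_points(c(10, 40), saturation_model(300, 0.05, c(10, 40)))
  f2 <- fit_full(two)
  expect_equal(f2$A, 300, tolerance = 1e-6)
  expect_equal(f2$B, 0.05, tolerance = 1e-6)
  expect_lt(f2$rss, 1e-12)

  # zero-concentration points are excluded
  with0 <- calibration_points(c(0, C), c(12, saturation_model(355.7, 0.069, C)))
  expect_equal(fit_full(with0)$A, 355.7, tolerance = 1e-6)
  expect_error(fit_full(calibration_points(c(0, 0), c(0, 1))), "nonzero")
})

test_that("noisy fits are unbiased within simulation error", {
  withr::local_seed(42)
  C <- c(5, 10, 20, 40, 75)
  truth <- saturation_model(355.7, 0.069, C)
  est <- t(replicate(50, {
    fit <- fit_full(calibration_points(C, truth + rnorm(5, 0, 5)))
    c(fit$A, fit$B)
  }))
  expect_lt(abs(mean(est[, 1]) - 355.7), 3 * sd(est[, 1]) / sqrt(50))
  expect_lt(abs(mean(est[, 2]) - 0.069), 3 * sd(est[, 2]) / sqrt(50))
})

test_that("fixed-B fit matches its closed form", {
  B <- 0.069
  C <- c(40, 60, 75)
  pts <- calibration_points(C, saturation_model(355.7, B, C))
  fit <- fit_A_fixed_B(pts, B)
  expect_equal(fit$A, 355.7, tolerance = 1e-12)
  expect_equal(fit$B, B)

  # single point: A = I / (1 - exp(-B C))
  one <- calibration_points(30, 250)
  f1 <- fit_A_fixed_B(one, B, include_origin = FALSE)
  expect_equal(f1$A, 250 / (1 - exp(-B * 30)), tolerance = 1e-12)
  # the (0, 0) anchor is a zero-regressor point: same optimum, larger n
  f1o <- fit_A_fixed_B(one, B, include_origin = TRUE)
  expect_equal(f1o$A, f1$A, tolerance = 1e-12)
  expect_equal(f1o$n, 2L)
  expect_error(fit_A_fixed_B(calibration_points(0, 0), B), "nonzero")
})

test_that("inversion is the exact algebraic inverse and validates range", {
  fit <- calibration_fit(355.7, 0.069)
  qi0 <- quant_input(0)
  expect_equal(invert_concentration(fit, qi0), 0)
  # inversion at the published worked-example inputs; direct evaluation
  # (the quoted 241 ng/mL result is not reproducible from those inputs,
  # see the methods vignette)
  expect_equal(invert_concentration(fit, quant_input(267)),
               322.04702368437698, tolerance = 1e-12)
  # round trip through the forward model with the D, k scaling
  for (Cx in c(3, 50, 241, 700)) {
    I <- saturation_model(355.7, 0.069, Cx * 0.1 / 1.6)
    expect_equal(invert_concentration(fit, quant_input(I)), Cx,
                 tolerance = 1e-12)
  }
  expect_error(invert_concentration(fit, quant_input(356)), "aturated")
  expect_error(invert_concentration(fit, quant_input(-1)), "I_x < 0")
  expect_equal(invert_concentration(fit, quant_input(-1),
                                    allow_negative = TRUE), 0)
  # monotone in I_x, decreasing in A
  Cs <- vapply(c(50, 150, 250, 340), function(I)
    invert_concentration(fit, quant_input(I)), numeric(1))
  expect_true(all(diff(Cs) > 0))
  expect_gt(invert_concentration(calibration_fit(300, 0.069), quant_input(200)),
            invert_concentration(calibration_fit(400, 0.069), quant_input(200)))
})

test_that("quadrature propagation matches analytic partials and Monte Carlo", {
  fit <- calibration_fit(355.7, 0.069, dA = 16.3, dB = 0.006)
  qi <- quant_input(267)
  pe <- propagate_error(fit, qi)
  expect_gt(pe$dC_x, 0)
  # B's relative contribution is dB/B, below the design bound of 10%
  Cx <- invert_concentration(fit, qi)
  expect_equal(pe$contributions[["B"]] / Cx, 0.006 / 0.069,
               tolerance = 1e-12)
  expect_lt(pe$contributions[["B"]] / Cx, 0.10)

  # partials against central differences of the inversion
  eps <- 1e-6
  dA_fd <- (invert_concentration(calibration_fit(355.7 + eps, 0.069), qi) -
            invert_concentration(calibration_fit(355.7 - eps, 0.069), qi)) /
    (2 * eps)
  dB_fd <- (invert_concentration(calibration_fit(355.7, 0.069 + 1e-9), qi) -
            invert_concentration(calibration_fit(355.7, 0.069 - 1e-9), qi)) /
    2e-9
  expect_equal(pe$contributions[["A"]] / fit$dA, abs(dA_fd),
               tolerance = 1e-6)
  expect_equal(pe$contributions[["B"]] / fit$dB, abs(dB_fd),
               tolerance = 1e-6)

  # zero input uncertainties give a zero budget
  pe0 <- propagate_error(calibration_fit(355.7, 0.069), qi)
  expect_equal(pe0$dC_x, 0)

  # first-order correctness: Monte Carlo with small dA, dB
  withr::local_seed(13)
  small <- calibration_fit(355.7, 0.069, dA = 1, dB = 5e-4)
  draws <- replicate(4e4, {
    invert_concentration(calibration_fit(355.7 + rnorm(1, 0, small$dA),
                                         0.069 + rnorm(1, 0, small$dB)), qi)
  })
  expect_equal(sd(draws), propagate_error(small, qi)$dC_x, tolerance = 0.05)
})

test_that("detection limit inverts the negative control and flags samples", {
  fit <- calibration_fit(355.7, 0.069)
  expect_equal(detection_limit(fit, 0), 0)
  # choose the negative-control fluorescence that puts c_min at 5 ng/mL
  I_neg <- saturation_model(355.7, 0.069, 5 * 0.1 / 1.6)
  expect_equal(detection_limit(fit, I_neg), 5, tolerance = 1e-12)
  qr <- quantify_sample(fit, quant_input(saturation_model(355.7, 0.069,
                                                          3 * 0.1 / 1.6)),
                        c_min = 5)
  expect_equal(qr$C_x, 3, tolerance = 1e-9)
  expect_false(qr$in_range)
  cs <- vapply(c(1, 5, 20, 80), function(I) detection_limit(fit, I),
               numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("calibration tables round-trip through CSV", {
  pts <- calibration_points(c(0, 5, 20), c(1.2, 100, 280))
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(pts, path)
  expect_equal(as.data.frame(read_calibration_csv(path)),
               as.data.frame(pts))
})
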