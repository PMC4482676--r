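basis20 <- build_basis()  # default: 21-point grid, knots 350-590, referent 650

test_that("the spectral basis has five centred, full-rank columns", {
  expect_equal(dim(basis20$matrix), c(21, 5))
  expect_equal(qr(basis20$matrix)$rank, 5)
  # the basis vanishes at the referent wavelength
  expect_equal(unname(evaluate_basis(basis20, 650)[1, ]), rep(0, 5),
               tolerance = 1e-12)
  # natural condition: linear (zero second difference) beyond the outer knots
  lo <- evaluate_basis(basis20, c(300, 320, 340))
  hi <- evaluate_basis(basis20, c(660, 680, 700))
  expect_equal(unname(lo[1, ] - 2 * lo[2, ] + lo[3, ]), rep(0, 5),
               tolerance = 1e-10)
  expect_equal(unname(hi[1, ] - 2 * hi[2, ] + hi[3, ]), rep(0, 5),
               tolerance = 1e-10)
  # configurations that do not yield five spectral terms are refused
  expect_error(build_basis(knots = c(410, 470, 530, 590)), "expected 5")
  expect_error(build_basis(referent = 500), "last knot")
  expect_error(build_basis(knots = c(350, 410, 470, 530, 710)), "boundary")
})

test_that("spectrum predictors are linear and pinned at the referent", {
  g <- seq(300, 700, by = 10)  # grid containing the referent
  b <- build_basis(grid = g)
  zero <- reflectance_spectrum(g, rep(0, length(g)), normalized = TRUE)
  expect_equal(unname(spectrum_predictors(zero, b)), rep(0, 5))
  at650 <- reflectance_spectrum(g, as.numeric(g == 650), normalized = TRUE)
  expect_equal(unname(spectrum_predictors(at650, b)), rep(0, 5),
               tolerance = 1e-12)
  set.seed(8)
  r1 <- runif(length(g)); r2 <- runif(length(g))
  s1 <- reflectance_spectrum(g, r1, normalized = TRUE)
  s2 <- reflectance_spectrum(g, r2, normalized = TRUE)
  s12 <- reflectance_spectrum(g, r1 + r2, normalized = TRUE)
  expect_equal(spectrum_predictors(s12, b),
               spectrum_predictors(s1, b) + spectrum_predictors(s2, b),
               tolerance = 1e-12)
  misaligned <- reflectance_spectrum(g + 5, r1, normalized = TRUE)
  expect_error(spectrum_predictors(misaligned, b), "align")
})

test_that("a noiseless linear response is fit exactly", {
  cm <- generate_community(community_config(n_species = 40, seed = 17))
  preds <- t(sapply(cm$spectra, function(s) {
    spectrum_predictors(visible_percent(s), basis20)
  }))
  theta <- c(0.02, -0.03, 0.01, 0.015, -0.02)
  vi <- 0.3 + preds %*% theta + 0.2 * log10(cm$records$area_to_weight)
  fit <- suppressWarnings(  # lm flags the intentionally perfect fit
    fit_spectral_model(cm$spectra, voc = 10^as.vector(vi),
                       area_to_weight = cm$records$area_to_weight,
                       basis = basis20))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[paste0("s", 1:5)]), theta,
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["log_saw"]), 0.2, tolerance = 1e-8)
  expect_equal(fit$f_df[1], 5)
  expect_equal(fit$f_df[2], 40 - 7)
})

test_that("the fit is invariant to a constant offset added to the spectra", {
  cm <- generate_community(community_config(n_species = 30, seed = 23))
  shifted <- lapply(cm$spectra, function(s) {
    reflectance_spectrum(s$wavelength, s$reflectance + 0.1)
  })
  f1 <- fit_spectral_model(cm$spectra, cm$records$voc,
                           cm$records$area_to_weight, basis20)
  f2 <- fit_spectral_model(shifted, cm$records$voc,
                           cm$records$area_to_weight, basis20)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("delta-method band variances match a Monte-Carlo oracle", {
  cm <- generate_community(community_config(n_species = 120, seed = 29))
  fit <- fit_spectral_model(cm)
  set.seed(30)
  draws <- rmvn(2e4, fit$coefficients, fit$covariance)
  for (bd in c("uv", "blue", "green", "red")) {
    eff <- band_effect(fit, bd)
    rng <- list(uv = c(300, 400), blue = c(400, 500),
                green = c(500, 600), red = c(600, 701))[[bd]]
    rows <- fit$basis$grid >= rng[1] & fit$basis$grid < rng[2]
    cvec <- setNames(numeric(7), names(fit$coefficients))
    cvec[colnames(fit$basis$matrix)] <-
      colMeans(fit$basis$matrix[rows, , drop = FALSE])
    mc <- as.vector(draws %*% cvec)
    expect_equal(eff$cumulative_coefficient, sum(cvec * fit$coefficients),
                 tolerance = 1e-12)
    expect_lt(abs(var(mc) - eff$std_error^2) / eff$std_error^2, 0.05)
    expect_gte(eff$std_error, 0)
  }
})

test_that("injected colour-odour effects are recovered up to spline smoothing", {
  ## The generating blue effect enters through the blue band sum (a step
  ## function over wavelength), which the 5-df natural spline cannot
  ## represent exactly: the estimable blue-band coefficient is the
  ## spline-projected effect, about 0.84 of the injected step height.
  ## The SA:W covariate is correctly specified, so it is recovered unbiasedly.
  reps <- 30
  saw_hit <- 0; blue_est <- numeric(reps)
  for (i in seq_len(reps)) {
    cm <- generate_community(community_config(n_species = 200, seed = 400 + i))
    fit <- fit_spectral_model(cm)
    est <- fit$coefficients["log_saw"]
    se <- sqrt(fit$covariance["log_saw", "log_saw"])
    if (abs(est - 0.5) <= 2 * se) saw_hit <- saw_hit + 1
    blue_est[i] <- band_effect(fit, "blue")$cumulative_coefficient
  }
  expect_gte(saw_hit, 26)               # ~95% nominal coverage
  expect_true(all(blue_est < 0))        # direction always recovered
  expect_gt(mean(blue_est), -0.045)     # magnitude on the injected scale
  expect_lt(mean(blue_est), -0.020)
})

test_that("the spectral F test holds its size under the null", {
  reps <- 200
  rej <- 0
  for (i in seq_len(reps)) {
    cm <- generate_community(community_config(n_species = 56,
                                              blue_voc_effect = 0,
                                              seed = 7000 + i))
    fit <- fit_spectral_model(cm)
    if (fit$f_p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.01)
  expect_lt(rej / reps, 0.10)
})
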