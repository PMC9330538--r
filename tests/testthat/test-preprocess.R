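test_that("wavenumber calibration recovers known channel maps", {
  ref <- c(651.6, 857.9, 1168.5, 1323.9, 1648.4) # acetaminophen bands
  # peaks already on the reference axis: identity map
  ident <- calibrate_wavenumber(ref, ref, degree = 1)
  expect_equal(ident$coefficients, c(0, 1), tolerance = 1e-9)
  # constructed affine map c = (w - 500) / 1.7 inverts to slope 1.7
  channels <- (ref - 500) / 1.7
  fit <- calibrate_wavenumber(channels, ref, degree = 1)
  expect_equal(fit$coefficients, c(500, 1.7), tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_equal(predict(fit, channels), ref, tolerance = 1e-9)
  expect_error(calibrate_wavenumber(c(1, 2), c(600, 700), degree = 3),
               "at least")
  expect_error(calibrate_wavenumber(c(1, 2, 3), c(700, 600, 800)),
               "ascending")
})

test_that("fingerprint crop retains the closed window and rejects empty results", {
  w <- seq(400, 2000, by = 2)
  d <- one_spectrum(w, seq_along(w))
  cropped <- crop_fingerprint(d, 600, 1800)
  expect_true(all(cropped$wavenumbers >= 600 & cropped$wavenumbers <= 1800))
  expect_true(all(c(600, 1800) %in% cropped$wavenumbers))
  # cropping to the existing range is the identity
  same <- crop_fingerprint(d, 400, 2000)
  expect_equal(same$intensities, d$intensities)
  expect_error(crop_fingerprint(crop_fingerprint(d, 600, 1800), 1900, 2000),
               "does not overlap")
})

test_that("iterative polynomial background subtraction has the right fixed points", {
  w <- default_grid()
  x <- (w - mean(w)) / 600
  poly5 <- 3 + 2 * x - x^2 + 0.5 * x^3 - 0.2 * x^4 + 0.1 * x^5
  d <- one_spectrum(w, poly5)
  out <- subtract_background(d)
  expect_lt(max(abs(out$intensities)), 1e-6 * max(abs(poly5)))
  # constant spectrum maps to zero
  flat <- subtract_background(one_spectrum(w, rep(2, length(w))))
  expect_lt(max(abs(flat$intensities)), 1e-9)
  expect_error(subtract_background(one_spectrum(w, c(NA, poly5[-1]))),
               "non-finite")
})

test_that("background subtraction preserves an injected Gaussian peak", {
  w <- default_grid()
  x <- (w - mean(w)) / 600
  baseline <- 5 + 1.5 * x - 0.8 * x^2 + 0.3 * x^3
  h <- 2
  peak <- h * exp(-(w - 1200)^2 / (2 * 6^2))
  out <- subtract_background(one_spectrum(w, baseline + peak))
  recovered <- max(out$intensities)
  expect_lt(abs(recovered - h) / h, 0.05)
})

test_that("background subtraction is invariant to adding a polynomial", {
  w <- default_grid()
  set.seed(4)
  x <- (w - mean(w)) / 600
  spec <- abs(rnorm(length(w))) + exp(-(w - 1400)^2 / 50)
  poly <- 4 - 2 * x + x^2 + 0.4 * x^5
  # iterate to convergence: the clip-refit map is exactly equivariant under
  # adding a fittable polynomial, so the converged outputs must agree
  a <- subtract_background(one_spectrum(w, spec), max_iter = 500, tol = 1e-9)
  b <- subtract_background(one_spectrum(w, spec + poly), max_iter = 500,
                           tol = 1e-9)
  expect_lt(max(abs(a$intensities - b$intensities)),
            1e-6 * max(abs(spec + poly)))
})

test_that("median filter matches a brute-force windowed median", {
  w <- default_grid()
  set.seed(8)
  y <- rnorm(length(w))
  filtered <- median_filter(one_spectrum(w, y), window = 3)
  padded <- c(y[1], y, y[length(y)])
  oracle <- vapply(seq_along(y), function(i) median(padded[i:(i + 2)]),
                   numeric(1))
  expect_equal(drop(filtered$intensities), oracle)
  # window 1 is the identity
  expect_equal(drop(median_filter(one_spectrum(w, y), 1)$intensities), y)
  # a single-channel spike is removed, the rest untouched
  flat <- rep(1, length(w)); flat[100] <- 50
  despiked <- median_filter(one_spectrum(w, flat), 5)
  expect_equal(drop(despiked$intensities), rep(1, length(w)))
  expect_error(median_filter(one_spectrum(w, y), 4), "odd")
})

test_that("vector normalization yields exactly unit-norm spectra", {
  w <- default_grid()
  v <- c(3, 4, rep(0, length(w) - 2))
  out <- vector_normalize(one_spectrum(w, v))
  expect_equal(drop(out$intensities)[1:2], c(0.6, 0.8), tolerance = 1e-12)
  # idempotence
  again <- vector_normalize(out)
  expect_equal(again$intensities, out$intensities, tolerance = 1e-12)
  set.seed(2)
  r <- vector_normalize(one_spectrum(w, abs(rnorm(length(w)))))
  expect_equal(sum(r$intensities^2), 1, tolerance = 1e-12)
  expect_error(vector_normalize(one_spectrum(w, rep(0, length(w)))),
               "all-zero")
})

test_that("the preprocessing chain returns unit-norm spectra close to the clean mixtures", {
  lib <- default_library()
  design <- cohort_design(spectra_per_mouse = 6, spectra_per_mouse_sd = 0,
                          baseline_scale = 0, noise_sd = 0, seed = 21)
  sim <- simulate_cohort(design, lib)
  clean <- preprocess_dataset(sim$dataset)
  norms <- sqrt(rowSums(clean$intensities^2))
  expect_equal(unname(norms), rep(1, n_spectra(clean)), tolerance = 1e-9)
  direct <- sim$dataset$intensities /
    sqrt(rowSums(sim$dataset$intensities^2))
  # RMS deviation relative to each spectrum's peak amplitude: the chain's
  # residual distortion (median flattening of band tops, slight baseline
  # erosion) must stay below 2% of the strongest band
  rms <- sqrt(rowMeans((clean$intensities - direct)^2)) /
    apply(direct, 1, max)
  expect_lt(max(rms), 0.02)
  expect_match(tail(clean$provenance, 1), "normalize")
})

test_that("preprocessing a noisy cohort yields unit norms and is deterministic", {
  co <- cohort_small()
  norms <- sqrt(rowSums(co$clean$intensities^2))
  expect_equal(unname(norms), rep(1, n_spectra(co$clean)), tolerance = 1e-9)
  again <- preprocess_dataset(subset_spectra(co$raw, 1:5))
  # agreement to floating-point noise: per-spectrum results do not depend
  # on which other spectra share the batch
  expect_equal(again$intensities, co$clean$intensities[1:5, ],
               tolerance = 1e-10)
})

test_that("an empty dataset passes through the chain untouched", {
  w <- default_grid()
  empty <- spectra_dataset(
    w, matrix(numeric(0), 0, length(w)),
    data.frame(spectrum_id = character(0), mouse_id = character(0),
               group = character(0))
  )
  out <- preprocess_dataset(empty)
  expect_equal(n_spectra(out), 0)
})
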