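test_that("threshold filtering flags samples below the power cutoff", {
  sp <- interferogram(1:4, c(0.2, 1.0, 0.2, 1.0))
  kept <- filter_by_threshold(sp, 0.5)
  expect_identical(kept$included, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(max(kept$power), 1.0)  # global maximum untouched

  all_in <- filter_by_threshold(sp, 0)
  expect_true(all(all_in$included))

  peak2 <- interferogram(1:5, c(0.05, 2, 0.09, 0.11, 1))
  expect_identical(filter_by_threshold(peak2, 0.05)$included,
                   c(FALSE, TRUE, FALSE, TRUE, TRUE))

  expect_error(filter_by_threshold(interferogram(1:3, c(0, 0, 0)), 0.05),
               "degenerate")
  expect_error(filter_by_threshold(sp, 1), "threshold")
})

test_that("local maxima follow strict interior comparison with plateaus once", {
  mono <- interferogram(1:10, 1:10)
  expect_equal(nrow(find_local_maxima(mono)), 0L)

  sp <- interferogram(1:5, c(0, 1, 0, 2, 0))
  mx <- find_local_maxima(sp)
  expect_equal(mx$wavelength, c(2, 4))
  expect_equal(max(mx$power), 2)

  plateau <- interferogram(1:7, c(0, 1, 1, 1, 0, 2, 0))
  mxp <- find_local_maxima(plateau)
  expect_equal(mxp$wavelength, c(2, 6))  # leftmost plateau point only

  expect_equal(nrow(find_local_maxima(interferogram(1:2, c(1, 2)))), 0L)
})

test_that("peak detection matches an exhaustive scan on random signals", {
  set.seed(4711)
  for (rep in 1:40) {
    n <- sample(3:50, 1)
    p <- round(runif(n), 2)  # rounding induces plateaus
    sp <- interferogram(seq_len(n), p)
    got <- find_local_maxima(sp)
    want <- brute_force_maxima(sp$wavelength, sp$power)
    expect_equal(got, want, info = sprintf("case %d (n=%d)", rep, n))
  }
})

test_that("maxima spacing statistics reduce to order statistics of gaps", {
  mx <- data.frame(wavelength = c(1540, 1543, 1549), power = c(1, 1, 1))
  st <- maxima_distance_stats(mx)
  expect_equal(unname(st), c(4.5, 6, 3, 4.5))
  expect_equal(unname(maxima_distance_stats(mx[1, ])), rep(0, 4))
})

test_that("amplitude factor is the ratio of simulation to measured maxima", {
  a <- interferogram(1:3, c(0, 2, 0))
  expect_equal(amplitude_factor(a, a), 1)
  b <- interferogram(1:3, c(0, 0.004, 0))
  expect_equal(amplitude_factor(b, a), 500)
  half <- interferogram(1:3, c(0, 1, 0))
  expect_equal(amplitude_factor(half, a), 2)
  expect_error(amplitude_factor(interferogram(1:3, c(-1, 0, -1)), a),
               "degenerate")
})

test_that("Simpson areas reproduce closed forms", {
  # 1 + cos over whole periods integrates to the window width
  x <- seq(0, 6, length.out = 601)  # 3 periods of period 2
  y <- 1 + cos(pi * x)
  expect_equal(simpson_integral(x, y), 6, tolerance = 1e-8)
  # cubic integrated exactly by Simpson
  xs <- seq(0, 1, length.out = 11)
  expect_equal(simpson_integral(xs, xs^3), 0.25, tolerance = 1e-12)
  expect_error(simpson_integral(xs[1:10], xs[1:10]), "odd")
})

test_that("distortion applies the printed area formula literally", {
  w <- seq(0, 1, length.out = 101)
  const2 <- interferogram(w, rep(2, 101))  # area 2
  const4 <- interferogram(w, rep(4, 101))  # area 4
  expect_equal(distortion(const2, const4, f = 0.25), abs(1 - 0.5) / 4)
  # self-comparison with f = 1: D = |1 - A|/A with A the common area
  expect_equal(distortion(const4, const4, 1), abs(1 - 4) / 4)
  expect_error(
    distortion(interferogram(1:3, 1:3), interferogram(11:13, 1:3), 1),
    "incompatible")
})

test_that("axial shift is the signed offset of the global maxima", {
  m <- cavity_model(refractive_index = 1.35, noise_sd = 0)
  th <- theoretical_interferogram(m)
  expect_equal(axial_shift(th, th), 0)
  # shift the spectrum by a whole number of grid steps (+1.5 nm)
  step <- diff(th$wavelength)[1L]
  k <- round(1.5 / step)
  shifted <- interferogram(th$wavelength + k * step, th$power)
  expect_equal(axial_shift(shifted, th), k * step, tolerance = 1e-9)
  expect_equal(axial_shift(th, shifted), -axial_shift(shifted, th))
})

test_that("RMSE matches closed forms on shared grids", {
  a <- interferogram(1:4, c(0, 1, 0, 1))
  b <- interferogram(1:4, c(1, 0, 1, 0))
  expect_equal(signal_rmse(a, b, 1), 1)
  expect_equal(signal_rmse(a, a, 1), 0)
  offset <- interferogram(1:4, c(0, 1, 0, 1) + 0.3)
  expect_equal(signal_rmse(offset, a, 1), 0.3, tolerance = 1e-12)
})

test_that("feature rows carry the full 18-column layout", {
  m <- cavity_model(refractive_index = 1.33, noise_sd = 0)
  th <- theoretical_interferogram(m)
  row <- extract_features(th, m)
  expect_named(row, paste0("F", 1:18))
  expect_equal(row$F4, 1)
  expect_equal(row$F10, 0)
  expect_equal(row$F11, 0)
  expect_equal(row$F3, 0.05)
  expect_equal(row$F12, 280)
  expect_equal(c(row$F13, row$F14), c(1530, 1570))
  expect_equal(row$F14 - row$F13, 40)
  expect_equal(row$F15, max(th$power) - min(th$power))
  expect_true(row$F13 <= row$F16 && row$F16 <= row$F14)
  expect_true(is.na(row$F18))
  # literal area formula: self-comparison leaves D = |1 - A|/A
  area <- simpson_integral(th$wavelength, th$power)
  expect_equal(row$F9, abs(1 - area) / area, tolerance = 1e-9)
})

test_that("feature extraction is scale invariant where physics demands", {
  m <- cavity_model(refractive_index = 1.41)
  sp <- synthetic_interferogram(m, seed = 21)
  base <- extract_features(sp, m)
  scaled_sp <- interferogram(sp$wavelength, sp$power * 3.7, sp$metadata)
  scaled <- extract_features(scaled_sp, m)
  inv <- paste0("F", c(1, 5:11, 13, 14, 16, 17))
  expect_equal(scaled[inv], base[inv], tolerance = 1e-9)
  expect_equal(scaled$F2, 3.7 * base$F2)
  expect_equal(scaled$F15, 3.7 * base$F15)
  expect_equal(scaled$F4, base$F4 / 3.7)
  # f rescales the measured maximum onto the simulated one exactly
  ssmax <- max(theoretical_interferogram(m)$power)
  expect_equal(scaled$F4 * max(scaled_sp$power), ssmax, tolerance = 1e-12)
  # purity: identical inputs give identical rows
  expect_identical(extract_features(sp, m), base)
})

test_that("feature tables attach provenance and honour spectrum metadata", {
  spectra <- generate_fixtures(seed = 8, scale = "small")
  expect_length(spectra, 6L)
  tab <- extract_feature_table(spectra, small_model())
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("label_index", "replicate", "seed",
                    paste0("F", 1:18)) %in% names(tab)))
  # per-liquid refractive index drives the reference: F17 differs across liquids
  expect_gt(length(unique(tab$F17)), 1L)
})
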