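test_that("two-point calibration interpolates the marker anchors exactly", {
  cal <- calibrate_gradient(markers_two_point())
  # independent closed form for the line through (log10 66, 23), (log10 200, 15)
  slope_expected <- (15 - 23) / (log10(200) - log10(66))
  expect_equal(cal$slope, slope_expected)
  expect_equal(cal$intercept, 23 - slope_expected * log10(66))
  expect_equal(cal$slope, -16.6152, tolerance = 1e-4)
  expect_equal(cal$intercept, 53.2324, tolerance = 1e-4)
  # each marker predicts its own fraction
  expect_equal(predict_fraction(cal, c(66, 200)), c(23, 15))
  # one decade of mass spacing gives the slope directly
  decade <- calibrate_gradient(
    data.frame(mass_kda = c(66, 660), peak_fraction = c(23, 13))
  )
  expect_equal(decade$slope, -10)
})

test_that("calibration rejects degenerate marker sets", {
  expect_error(
    calibrate_gradient(data.frame(mass_kda = 66, peak_fraction = 23)),
    "at least 2"
  )
  expect_error(
    calibrate_gradient(
      data.frame(mass_kda = c(66, 66), peak_fraction = c(23, 15))
    ),
    "distinct"
  )
  expect_warning(
    calibrate_gradient(
      data.frame(mass_kda = c(66, 200), peak_fraction = c(15, 23))
    ),
    "slope"
  )
})

test_that("the 140-kDa marker lands on its published fraction", {
  cal <- calibrate_gradient(markers_two_point())
  f140 <- predict_fraction(cal, 140)
  expect_equal(round(f140), 18)
  expect_equal(f140, 17.57, tolerance = 0.01)
})

test_that("mass/fraction prediction round-trips through the calibration", {
  for (markers in list(markers_two_point(), markers_three_point())) {
    cal <- calibrate_gradient(markers)
    masses <- c(33, 66, 132, 198, 264)
    expect_equal(predict_mass(cal, predict_fraction(cal, masses)), masses,
                 tolerance = 1e-9)
  }
  # three anchors cannot sit exactly on one line; residuals stay sub-fraction
  cal3 <- calibrate_gradient(markers_three_point())
  expect_identical(length(cal3$residuals), 3L)
  expect_lt(max(abs(cal3$residuals)), 0.5)
  expect_error(predict_fraction(cal3, -1), "positive")
})

test_that("tidy and glance summarise the calibration fit", {
  cal <- calibrate_gradient(markers_three_point())
  td <- tidy(cal)
  expect_equal(td$estimate, c(cal$intercept, cal$slope))
  g <- glance(cal)
  expect_identical(g$n_markers, 3L)
  expect_lt(g$max_abs_residual, 0.5)
})

test_that("peak detection recovers noise-free generator peaks", {
  cal <- calibrate_gradient(markers_three_point())
  one <- simulate_gradient_profile(gradient_design(
    species = data.frame(mass_kda = 66, abundance = 1),
    calibration = cal, noise_sd = 0
  ))
  pk <- detect_peaks(one)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$fraction - predict_fraction(cal, 66)), 0.25)

  two <- simulate_gradient_profile(wildtype_gradient_design(noise_sd = 0))
  pk2 <- detect_peaks(two)
  expect_identical(nrow(pk2), 2L)
  expect_lt(abs(pk2$fraction[1] - predict_fraction(cal, 132)), 0.5)
  expect_lt(abs(pk2$fraction[2] - predict_fraction(cal, 66)), 0.5)
})

test_that("flat profiles yield no peaks and inputs are validated", {
  flat <- tibble::tibble(fraction = 1:31, intensity = 0)
  expect_identical(nrow(detect_peaks(flat)), 0L)
  const <- tibble::tibble(fraction = 1:31, intensity = 2)
  expect_identical(nrow(detect_peaks(const)), 0L)
  prof <- tibble::tibble(fraction = 1:31, intensity = runif(31))
  expect_error(detect_peaks(prof, smoothing_window = 4), "odd")
  expect_error(detect_peaks(prof, smoothing_window = 31), "odd")
  expect_error(
    detect_peaks(tibble::tibble(fraction = c(1, 3), intensity = c(0, 1))),
    "contiguous"
  )
})

test_that("peak count is monotone nonincreasing in the prominence threshold", {
  prof <- simulate_gradient_profile(wildtype_gradient_design(seed = 42))
  counts <- vapply(
    c(0.01, 0.05, 0.1, 0.2, 0.5, 0.9),
    function(thr) nrow(detect_peaks(prof, min_prominence = thr)),
    integer(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("seeded noisy profiles localise peaks within half a fraction", {
  cal <- calibrate_gradient(markers_three_point())
  centers <- predict_fraction(cal, c(132, 66))
  hits <- vapply(1:50, function(seed) {
    prof <- simulate_gradient_profile(wildtype_gradient_design(seed = seed))
    pk <- detect_peaks(prof)
    nrow(pk) == 2 && all(abs(pk$fraction - centers) <= 0.5)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("detected maxima agree with an independent peak finder", {
  prof <- simulate_gradient_profile(wildtype_gradient_design(seed = 8))
  pk <- detect_peaks(prof)
  # pracma::findpeaks on the same smoothed trace, same relative threshold
  s <- vapply(1:31, function(i) {
    mean(prof$intensity[max(1, i - 1):min(31, i + 1)])
  }, numeric(1))
  ref <- pracma::findpeaks(s, minpeakheight = 0.1 * max(s))
  expect_setequal(pk$index, ref[, 2])
})

test_that("oligomer orders follow the calibration and tolerance contract", {
  cal <- calibrate_gradient(markers_two_point())
  prof <- simulate_gradient_profile(gradient_design(
    species = data.frame(mass_kda = c(66, 132), abundance = c(1, 0.6)),
    calibration = cal, noise_sd = 0
  ))
  pk <- detect_peaks(prof)
  assigned <- assign_oligomer_states(pk, cal, subunit_mass = 66)
  expect_identical(sort(assigned$order), c(1L, 2L))
  expect_true(all(assigned$assigned))
  # zero tolerance rejects anything off the exact multiple
  strict <- assign_oligomer_states(pk, cal, subunit_mass = 66, tolerance = 0)
  expect_true(any(is.na(strict$order)))
  # empty input passes through
  empty <- assign_oligomer_states(detect_peaks(
    tibble::tibble(fraction = 1:31, intensity = 0)
  ), cal, 66)
  expect_identical(nrow(empty), 0L)
})

test_that("assignments are invariant to uniform intensity rescaling", {
  prof <- simulate_gradient_profile(wildtype_gradient_design(seed = 21))
  cal <- calibrate_gradient(markers_three_point())
  scaled <- dplyr::mutate(prof, intensity = intensity * 37.5)
  a1 <- assign_oligomer_states(detect_peaks(prof), cal, 66)
  a2 <- assign_oligomer_states(detect_peaks(scaled), cal, 66)
  expect_equal(a1$fraction, a2$fraction)
  expect_identical(a1$order, a2$order)
})
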