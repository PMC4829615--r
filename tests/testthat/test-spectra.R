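test_that("an on-grid sinusoid concentrates all amplitude at its frequency", {
  n <- 220; tr <- 2.6
  f0 <- 11 / (n * tr)
  x <- cos(2 * pi * f0 * (0:(n - 1)) * tr)
  sp <- amplitude_spectrum(x, tr)
  peak <- which.max(sp$amplitude)
  expect_equal(sp$freqs[peak], f0)
  expect_equal(sp$amplitude[peak], 1, tolerance = 1e-10)
  expect_lt(max(sp$amplitude[-peak]), 1e-9 * sp$amplitude[peak])
})

test_that("frequency grid matches the acquisition arithmetic", {
  sp <- amplitude_spectrum(rnorm(220), 2.6)
  expect_equal(diff(sp$freqs)[1L], 1 / (220 * 2.6))
  expect_equal(max(sp$freqs), 110 / (220 * 2.6))  # ~0.1923 Hz
  expect_length(sp$freqs, 111L)
})

test_that("zero series yields an all-zero spectrum and NaN input errors", {
  sp <- amplitude_spectrum(numeric(100), 2.6)
  expect_true(all(sp$amplitude == 0))
  expect_error(amplitude_spectrum(c(rnorm(99), NA), 2.6), "missing")
})

test_that("one-sided amplitudes satisfy the Parseval energy identity", {
  set.seed(7)
  for (n in c(128L, 221L)) {  # even and odd lengths
    x <- rnorm(n)
    sp <- amplitude_spectrum(x, 2.6)
    a <- sp$amplitude
    half <- floor(n / 2)
    interior <- 2:(half + if (n %% 2L == 0L) 0L else 1L)
    energy <- sum(a[interior]^2) / 2 + a[1L]^2 +
      if (n %% 2L == 0L) a[half + 1L]^2 else 0
    expect_equal(energy, mean(x^2), tolerance = 1e-8)
  }
})

test_that("Gaussian smoothing has the right impulse response and conserves mass", {
  sp <- flat_spectrum(440, 2.6, value = 0)
  sp$amplitude[100L] <- 1
  sm <- smooth_spectrum(sp, 2)
  prof <- dnorm(-8:8, sd = 2); prof <- prof / sum(prof)
  expect_equal(sm$smoothed[92:108], prof, tolerance = 1e-12)
  # flat stays flat
  fl <- smooth_spectrum(flat_spectrum(440, 2.6, 3), 2)
  expect_equal(fl$smoothed, rep(3, length(fl$freqs)), tolerance = 1e-10)
  # interior mass conservation within 1%
  set.seed(1)
  ra <- flat_spectrum(440, 2.6)
  ra$amplitude <- abs(rnorm(length(ra$freqs)))
  rs <- smooth_spectrum(ra, 2)
  idx <- seq(ceiling(0.05 * length(ra$freqs)), floor(0.95 * length(ra$freqs)))
  expect_equal(sum(rs$smoothed[idx]), sum(ra$amplitude[idx]),
               tolerance = 0.01)
  expect_error(smooth_spectrum(ra, 0), "positive")
})

test_that("bin resampling interpolates the smoothed spectrum exactly on linear input", {
  sp <- flat_spectrum(220, 2.6, 2)
  sm <- smooth_spectrum(sp, 2)
  expect_equal(resample_to_bins(sm), rep(2, 34L), tolerance = 1e-9)
  lin <- flat_spectrum(220, 2.6)
  lin$amplitude <- 5 * lin$freqs + 1
  lsm <- smooth_spectrum(lin, 2)
  lsm$smoothed <- lin$amplitude  # exactly linear input to the interpolation
  expect_equal(resample_to_bins(lsm), 5 * bin_grid()$centers + 1,
               tolerance = 1e-12)
  expect_error(resample_to_bins(lsm, bin_grid(0.009, 0.3, 0.0015)),
               "Nyquist")
})

test_that("fALFF of a flat spectrum is the bandwidth ratio; a slow-5 tone dominates", {
  sm <- smooth_spectrum(flat_spectrum(2200, 2.6), 2)
  sch <- band_scheme(max(sm$freqs))
  expect_equal(band_falff(sm, get_band(sch, "slow5"), get_band(sch, "full")),
               0.017 / 0.1923, tolerance = 0.02)
  # sinusoid at ~0.02 Hz over a tiny broadband floor
  n <- 220; tr <- 2.6
  x <- cos(2 * pi * (11 / (n * tr)) * (0:(n - 1)) * tr) +
    rnorm(n, sd = 1e-4)
  expect_gt(measure_falff(x, tr), 0.9)
  # numerator equal to denominator gives exactly 1
  expect_equal(band_falff(sm, get_band(sch, "full"), get_band(sch, "full")),
               1.0)
  expect_error(band_falff(smooth_spectrum(amplitude_spectrum(numeric(100), 2.6), 2),
                          get_band(sch, "slow5"), get_band(sch, "full")),
               "degenerate")
})

test_that("disjoint-band fALFF is additive and invariant to positive rescaling", {
  set.seed(3)
  x <- synth_component_timecourse(0.8, 1.1, 0.3, 220, 2.6)
  sp <- smooth_spectrum(amplitude_spectrum(x, 2.6), 2)
  sch <- band_scheme(max(sp$freqs))
  full <- get_band(sch, "full")
  s5 <- band_falff(sp, get_band(sch, "slow5"), full)
  s4 <- band_falff(sp, get_band(sch, "slow4"), full)
  rest <- band_falff(sp, get_band(sch, "resting"), full)
  expect_equal(s5 + s4, rest, tolerance = 1e-12)
  expect_equal(measure_falff(17.3 * x, 2.6), measure_falff(x, 2.6),
               tolerance = 1e-12)
})

test_that("slow-5 share behaves at its extremes and for flat spectra", {
  # spectra with all resting-band mass in one slow band (constructed, so the
  # extremes are exact)
  sch <- band_scheme(0.1923)
  base <- smooth_spectrum(flat_spectrum(220, 2.6, 0), 2)
  in5 <- band_mask(base$freqs, get_band(sch, "slow5"))
  in4 <- band_mask(base$freqs, get_band(sch, "slow4"))
  all5 <- base; all5$smoothed[in5] <- 1
  expect_equal(slow5_share(all5, sch), 1.0)
  all4 <- base; all4$smoothed[in4] <- 1
  expect_equal(slow5_share(all4, sch), 0.0)
  # generated narrow-band series: smoothing leaks a little mass across the
  # 0.027-Hz edge, so the extremes soften
  tone5 <- synth_component_timecourse(1, 0, 0, 220, 2.6, seed = 1)
  sp5 <- smooth_spectrum(amplitude_spectrum(tone5, 2.6), 2)
  expect_gt(slow5_share(sp5, band_scheme(max(sp5$freqs))), 0.9)
  tone4 <- synth_component_timecourse(0, 1, 0, 220, 2.6, seed = 1)
  sp4 <- smooth_spectrum(amplitude_spectrum(tone4, 2.6), 2)
  expect_lt(slow5_share(sp4, band_scheme(max(sp4$freqs))), 0.05)
  flat <- smooth_spectrum(flat_spectrum(2200, 2.6), 2)
  expect_equal(slow5_share(flat, band_scheme(max(flat$freqs))),
               0.017 / 0.063, tolerance = 0.02)
})

test_that("composite spectra average members and preserve fALFF linearity", {
  a <- smooth_spectrum(flat_spectrum(220, 2.6, 1), 2)
  b <- smooth_spectrum(flat_spectrum(220, 2.6, 3), 2)
  comp <- combine_component_spectra(list(a, b))
  expect_equal(comp$smoothed, rep(2, length(a$freqs)), tolerance = 1e-10)
  same <- combine_component_spectra(list(a, a))
  expect_equal(same$amplitude, a$amplitude)
  # equal-denominator members: composite fALFF equals the mean member fALFF
  set.seed(9)
  x1 <- synth_component_timecourse(1.0, 0.8, 0.1, 220, 2.6)
  x2 <- synth_component_timecourse(0.6, 1.2, 0.1, 220, 2.6)
  s1 <- smooth_spectrum(amplitude_spectrum(x1, 2.6), 2)
  s2 <- smooth_spectrum(amplitude_spectrum(x2, 2.6), 2)
  sch <- band_scheme(max(s1$freqs))
  d1 <- sum(s1$smoothed); d2 <- sum(s2$smoothed)
  s2$smoothed <- s2$smoothed * d1 / d2  # equalize denominator mass
  cmp <- combine_component_spectra(list(s1, s2))
  f1 <- band_falff(s1, get_band(sch, "slow5"), get_band(sch, "full"))
  f2 <- band_falff(s2, get_band(sch, "slow5"), get_band(sch, "full"))
  expect_equal(band_falff(cmp, get_band(sch, "slow5"), get_band(sch, "full")),
               (f1 + f2) / 2, tolerance = 1e-12)
  bad <- smooth_spectrum(flat_spectrum(256, 2.6), 2)
  expect_error(combine_component_spectra(list(a, bad)), "grids")
})

test_that("measured mean slow-5 fALFF increases with the planted slow-5 amplitude", {
  set.seed(21)
  ladder <- c(0.5, 1, 2)
  means <- vapply(ladder, function(a5) {
    mean(replicate(30, measure_falff(
      synth_component_timecourse(a5, 1, 0.2, 220, 2.6), 2.6)))
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
})
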