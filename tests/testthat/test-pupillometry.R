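test_that("moment-based ellipse fit recovers rendered areas", {
  fr <- 10
  # filled circle of radius 10 px -> area ~ 100*pi
  tr <- pupil_trace(0:1 / fr, rep(pi * 100, 2), sampling_rate = fr)
  masks <- render_pupil_masks(tr, image_size = c(64, 64))
  fit <- fit_ellipse_area(masks[, , 1])
  expect_true(fit$valid)
  expect_equal(fit$area, 100 * pi, tolerance = 0.01)
  expect_equal(fit$area, sum(masks[, , 1]), tolerance = 0.02) # pixel count
  # ellipse a = 20, b = 10 -> area ~ 200*pi, against the pixel-count oracle
  tr2 <- pupil_trace(0:1 / fr, rep(pi * 200, 2), sampling_rate = fr)
  m2 <- render_pupil_masks(tr2, image_size = c(96, 96), aspect = 2)
  fit2 <- fit_ellipse_area(m2[, , 1])
  expect_equal(fit2$area, 200 * pi, tolerance = 0.02)
  expect_equal(sort(fit2$axes), c(10, 20), tolerance = 0.03)
  # empty frame -> invalid marker, not an error
  empty <- fit_ellipse_area(matrix(0L, 32, 32))
  expect_false(empty$valid)
  expect_true(is.na(empty$area))
})

test_that("mask rendering round-trips a varying trace within quantization", {
  fr <- 5
  areas <- seq(60, 400, length.out = 8)
  tr <- pupil_trace((seq_along(areas) - 1) / fr, areas, sampling_rate = fr)
  masks <- render_pupil_masks(tr, image_size = c(64, 64))
  rec <- masks_to_trace(masks, fr)
  expect_equal(rec$area, areas, tolerance = 0.05)
  expect_error(render_pupil_masks(
    pupil_trace(0:1 / fr, rep(1e6, 2), sampling_rate = fr),
    image_size = c(32, 32)), "larger than frame")
})

test_that("zero-phase low-pass keeps PLR-band signal and kills jitter", {
  fr <- 30
  t <- seq(0, 20, by = 1 / fr)
  base <- 10
  amp_of <- function(x) (max(x) - min(x)) / 2
  const <- lowpass_pupil(pupil_trace(t, rep(base, length(t))), 1.5)
  expect_equal(const$area, rep(base, length(t)), tolerance = 1e-6)
  slow <- pupil_trace(t, base + sin(2 * pi * 0.55 * t))
  expect_gte(amp_of(lowpass_pupil(slow, 1.5)$area[100:500]), 0.95)
  fast <- pupil_trace(t, base + sin(2 * pi * 10 * t))
  expect_lte(amp_of(lowpass_pupil(fast, 1.5)$area[100:500]), 0.1)
  expect_error(lowpass_pupil(slow, 15), "Nyquist")
})

test_that("kinetics detector locates a constructed ramp onset exactly", {
  fr <- 30
  t <- seq(0, 8, by = 1 / fr)
  area <- rep(10, length(t))
  drop_idx <- t >= 3.3 # stimulus onset 3.0, constriction starts 0.3 s later
  area[drop_idx] <- 10 - pmin(4, 4 * (t[drop_idx] - 3.3) / 1.2)
  kin <- plr_kinetics(pupil_trace(t, area), stim_onset_s = 3,
                      peak_smooth_s = 0)
  expect_lt(abs(kin$onset_latency_s - 0.3), 1.5 / fr)
  expect_lt(abs(kin$time_to_peak_s - 1.5), 1.5 / fr)
  expect_equal(kin$constriction_amplitude_frac, 0.4, tolerance = 1e-6)
  # flat trace -> invalid, no error
  flat <- plr_kinetics(pupil_trace(t, rep(10, length(t))), 3)
  expect_false(flat$valid)
})

test_that("kinetics are translation-equivariant and scale-invariant", {
  fr <- 30
  t <- seq(0, 10, by = 1 / fr)
  shape <- function(t0) {
    a <- rep(1, length(t))
    idx <- t >= t0
    a[idx] <- 1 - 0.3 * pmin(1, (t[idx] - t0) / 1.2) *
      exp(-(t[idx] - t0 - 1.2) / 4 * ((t[idx] - t0) > 1.2))
    a
  }
  k1 <- plr_kinetics(pupil_trace(t, shape(3.4)), 3)
  k2 <- plr_kinetics(pupil_trace(t, shape(4.4)), 4)
  expect_equal(k1$onset_latency_s, k2$onset_latency_s, tolerance = 1e-9)
  expect_equal(k1$time_to_peak_s, k2$time_to_peak_s, tolerance = 1e-9)
  k3 <- plr_kinetics(pupil_trace(t, 7.3 * shape(3.4)), 3)
  expect_equal(k1$constriction_amplitude_frac,
               k3$constriction_amplitude_frac, tolerance = 1e-9)
})

test_that("PFI is the normalized amplitude difference and antisymmetric", {
  kin <- function(amp) {
    structure(list(onset_latency_s = 0.5, time_to_peak_s = 1.7,
                   constriction_amplitude_frac = amp, baseline_mean = 1,
                   valid = TRUE), class = "plr_kinetics")
  }
  expect_equal(pupil_facilitation_index(kin(0.3), kin(0.3)), 0)
  # A_both = 1.381 * A_contra inverts to PFI ~ 0.16
  expect_equal(pupil_facilitation_index(kin(0.1381), kin(0.1)), 0.16,
               tolerance = 0.001)
  expect_lt(pupil_facilitation_index(kin(0.2), kin(0.3)), 0)
  expect_equal(pupil_facilitation_index(kin(0.2), kin(0.3)),
               -pupil_facilitation_index(kin(0.3), kin(0.2)))
  bad <- structure(list(valid = FALSE), class = "plr_kinetics")
  expect_error(pupil_facilitation_index(bad, kin(0.3)), "valid")
})

test_that("FFT tracking fraction behaves on known spectra", {
  fr <- 30
  t <- seq(0, 30, by = 1 / fr)
  pure <- pupil_trace(t, 10 + sin(2 * pi * 0.55 * t))
  expect_gt(fft_tracking_fraction(pure, 0.55), 90)
  # white noise: expected fraction ~ band width / total width above floor
  set.seed(1)
  fracs <- replicate(20, {
    fft_tracking_fraction(pupil_trace(t, 10 + rnorm(length(t), 0, 0.1)), 2)
  })
  expected <- 100 * 0.1 / (fr / 2 - 0.25)
  expect_equal(mean(fracs), expected, tolerance = 0.35)
  expect_true(all(fracs >= 0 & fracs <= 100))
  expect_error(fft_tracking_fraction(pure, 0.2), "floor")
})

test_that("invalid frames are interpolated only across short gaps", {
  fr <- 10
  t <- (0:99) / fr
  a <- 10 + sin(t)
  a[20:22] <- NA          # 0.3 s gap: interpolated
  a[60:75] <- NA          # 1.6 s gap: dropped
  tr <- interpolate_invalid(pupil_trace(t, a), max_gap_s = 0.5)
  expect_false(anyNA(tr$area[20:22]))
  expect_true(all(is.na(tr$area[60:75])))
  expect_length(attr(tr, "dropped_gaps"), 1)
})
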