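plr <- plr_params("mouse")

test_that("flat protocol with zero noise gives a constant pupil", {
  p <- make_protocol("RAMP", freq_hz = 0, amplitude = 0, duration_s = 5,
                     conditions = "CONTRA", n_rep = 1)
  pu <- simulate_pupil(p, plr, noise_sd = 0, physio_noise_sd = 0)
  expect_equal(pu$contra$area, rep(plr$baseline_area, length(p$time)),
               tolerance = 1e-10)
})

test_that("step response reproduces the calibrated onset and peak", {
  p <- make_protocol("FLASH", level = 65, conditions = "CONTRA", n_rep = 1)
  pu <- simulate_pupil(p, plr, noise_sd = 0, physio_noise_sd = 0)
  kin <- plr_kinetics(pu$contra, p$onsets[1])
  expect_true(kin$valid)
  # with zero noise the threshold detector fires at the first movement,
  # i.e. at the transport delay; the calibrated 0.51 s onset applies at
  # realistic noise (covered by the parameter-recovery tests)
  expect_gte(kin$onset_latency_s, plr$transport_delay_s - 1e-9)
  expect_lte(kin$onset_latency_s, 0.51 + 0.07)
  expect_equal(kin$time_to_peak_s, 1.74, tolerance = 0.1)
  expect_equal(kin$constriction_amplitude_frac,
               plr$max_constriction_frac, tolerance = 0.03)
})

test_that("binocular low-contrast flash constricts deeper than monocular", {
  kin_of <- function(cond) {
    p <- make_protocol("FLASH", level = 20, conditions = cond, n_rep = 1)
    pu <- simulate_pupil(p, plr, noise_sd = 0, physio_noise_sd = 0)
    plr_kinetics(pu$contra, p$onsets[1])
  }
  pfi <- pupil_facilitation_index(kin_of("BOTH"), kin_of("CONTRA"))
  expect_gt(pfi, 0)
})

test_that("retinal illuminance is the bilinear area-luminance product", {
  lum <- c(9.5, 9.5, 65, 65)
  expect_equal(retinal_illuminance(lum, rep(2, 4), 2), lum)
  expect_equal(retinal_illuminance(rep(10, 4), c(2, 2, 1, 1), 2),
               c(10, 10, 5, 5))
  expect_error(retinal_illuminance(lum, rep(1, 3), 1), "length")
  # bilinearity
  a <- runif(5, 0.5, 2); l <- runif(5, 0, 60)
  expect_equal(retinal_illuminance(3 * l, a, 1),
               3 * retinal_illuminance(l, a, 1))
  expect_equal(retinal_illuminance(l, 2 * a, 1),
               2 * retinal_illuminance(l, a, 1))
})

test_that("PLR produces a negative illuminance transient during a flash", {
  p <- make_protocol("FLASH", level = 31, conditions = "CONTRA", n_rep = 1)
  pu <- simulate_pupil(p, plr, noise_sd = 0, physio_noise_sd = 0)
  E <- retinal_illuminance(p$lum_contra, pu$contra$area, plr$baseline_area)
  on <- p$onsets[1]
  rise <- E[p$time >= on & p$time < on + 0.2]
  during <- E[p$time >= on + 0.6 & p$time <= on + 1.74]
  expect_equal(max(rise) / 9.5, 31 / 9.5, tolerance = 0.05) # ~3.3x jump
  expect_lt(mean(diff(during)), 0) # falling while the pupil constricts
})

test_that("modeled-PLR stimulus reproduces dynamic-pupil illuminance on a clamped pupil", {
  p <- make_protocol("FLASH", level = 65, conditions = "CONTRA", n_rep = 2)
  pu <- simulate_pupil(p, plr, noise_sd = 0, physio_noise_sd = 0)
  a0 <- plr$baseline_area
  # constant pupil at baseline: protocol unchanged
  flat <- pupil_trace(p$time, rep(a0, length(p$time)))
  same <- model_plr_stimulus(p, list(contra = flat, ipsi = flat),
                             clamped_area = a0, baseline_area = a0)
  expect_equal(same$lum_contra, p$lum_contra, tolerance = 1e-12)
  # pupil at 50% of baseline throughout: all luminances halved
  half <- pupil_trace(p$time, rep(a0 / 2, length(p$time)))
  halved <- model_plr_stimulus(p, list(contra = half, ipsi = half),
                               clamped_area = a0, baseline_area = a0)
  expect_equal(halved$lum_contra, p$lum_contra / 2, tolerance = 1e-12)
  # round trip through an atropine-dilated clamped pupil
  atro <- a0 * plr$atropine_dilation
  modeled <- model_plr_stimulus(p, pu, clamped_area = atro,
                                baseline_area = a0)
  e_clamped <- retinal_illuminance(modeled$lum_contra,
                                   rep(atro, length(p$time)), a0)
  e_dynamic <- retinal_illuminance(p$lum_contra, pu$contra$area, a0)
  expect_lt(max(abs(e_clamped - e_dynamic)) / max(e_dynamic), 1e-6)
  expect_error(model_plr_stimulus(p, pu, clamped_area = 0), "zero")
})

test_that("pharmacology clamps the pupil and TTX silences the ipsi drive", {
  for (drug in c("ATROPINE", "CARBACHOL")) {
    p <- make_protocol("FLASH", level = 65, n_rep = 2, pharmacology = drug)
    pu <- simulate_pupil(p, plr, noise_sd = 0, physio_noise_sd = 0)
    expect_equal(stats::var(pu$contra$area), 0)
    expected <- if (drug == "ATROPINE") {
      plr$baseline_area * plr$atropine_dilation
    } else {
      plr$baseline_area * (1 - plr$max_constriction_frac)
    }
    expect_equal(pu$contra$area[1], expected)
  }
  p_ttx <- make_protocol("FLASH", level = 65, conditions = "IPSI",
                         n_rep = 1, pharmacology = "TTX_IPSI")
  pu_ttx <- simulate_pupil(p_ttx, plr, noise_sd = 0, physio_noise_sd = 0)
  expect_equal(stats::var(pu_ttx$contra$area), 0) # no consensual drive left
  # but direct (contra-eye) PLR is preserved under TTX_IPSI
  p_ttx_c <- make_protocol("FLASH", level = 65, conditions = "CONTRA",
                           n_rep = 1, pharmacology = "TTX_IPSI")
  pu_c <- simulate_pupil(p_ttx_c, plr, noise_sd = 0, physio_noise_sd = 0)
  expect_gt(1 - min(pu_c$contra$area) / plr$baseline_area, 0.2)
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- make_protocol("FLASH", n_rep = 2, seed = 5)
  a <- simulate_pupil(p, plr, seed = 9)
  b <- simulate_pupil(p, plr, seed = 9)
  expect_identical(a$contra$area, b$contra$area)
  t1 <- simulate_boutons(p, a, seed = 11)
  t2 <- simulate_boutons(p, a, seed = 11)
  expect_identical(t1$F_raw, t2$F_raw)
})
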