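#' PLR kinetic parameters
#'
#' Parameters of the generative pupillary-light-reflex model. The pupil is
#' modelled as a delayed, biphasic linear filter applied to a saturating
#' binocular log-luminance drive:
#'
#' 1. drive `d(t) = log(L_own/B) + consensual_gain * log(L_other/B)`, with
#'    negative (dilation) excursions down-weighted by `dilation_gain` and a
#'    small luminance floor to keep the log finite in darkness;
#' 2. static saturation `g(d) = d / (d + half_sat)` (rescaled so that the
#'    reference high-contrast step, 9.5 to 65 lux, has unit drive) -
#'    constriction amplitude is sublinear in log intensity, as PLR
#'    amplitude saturates with flash intensity;
#' 3. a binocular supralinearity `(1 + lowcontrast_boost)` applied while
#'    both eyes are driven and the instantaneous luminance is below
#'    `boost_knee_lux`, producing low-contrast-specific facilitation;
#' 4. a neural integration pre-filter (two cascaded first-order stages of
#'    `tau_drive_s`, the retina-to-pretectum temporal integration) that
#'    low-passes the drive before it reaches the iris plant;
#' 5. a delayed biphasic *target* (integrated drive minus a slow
#'    adaptation term) tracked by an asymmetric first-order stage: both
#'    directions follow with time constant `time_constant_s`, but
#'    re-dilation speed is capped at `dilation_vmax` (fraction of the
#'    full constriction range per second). The integration pre-filter and
#'    the velocity asymmetry are standard pupil physiology (constriction
#'    is parasympathetically fast, dilation slow) and together they make
#'    the pupil track a 0.55 Hz contrast ramp cycle-by-cycle while only
#'    constricting gradually under the same ramp at 2 Hz, where the
#'    attenuated drive swing falls below what the pupil could re-dilate
#'    between cycles.
#'
#' The adaptation stage and the transport delay are solved numerically in
#' the constructor so that the noise-free step response crosses a 2%%
#' detection criterion at `onset_latency_s`, reaches peak constriction at
#' `time_to_peak_s`, and relaxes by `rebound_amp_frac` of the peak during
#' sustained illumination (mouse defaults: onset 0.51 s, peak 1.74 s;
#' human: 0.55 s / 1.18 s).
#'
#' @param species "mouse" or "human"; sets the kinetic defaults.
#' @param onset_latency_s Delay before constriction starts (s).
#' @param time_to_peak_s Time from stimulus onset to peak constriction (s).
#' @param max_constriction_frac Fractional area loss at peak for the
#'   reference high-contrast step (0-1).
#' @param consensual_gain Weight of the opposite eye's drive (0-1).
#' @param lowcontrast_boost Supralinear binocular gain below the knee.
#' @param boost_knee_lux Luminance knee below which the boost applies.
#' @param rebound_amp_frac Fraction of peak constriction recovered during
#'   sustained illumination (0-1).
#' @param time_constant_s First-order tracking constant (s); default
#'   0.35 (mouse) / 0.20 (human).
#' @param dilation_vmax Maximum re-dilation speed, in units of the full
#'   constriction range per second; limits how fast the pupil can recover
#'   between cycles of a fast stimulus.
#' @param tau_drive_s Time constant of each of the two neural-integration
#'   stages applied to the drive (s); default 0.35 (mouse) / 0.15
#'   (human, whose constriction peaks markedly faster).
#' @param half_sat Half-saturation of the drive nonlinearity, in units of
#'   log-luminance ratio.
#' @param dilation_gain Relative weight of negative (dilation) drive.
#' @param baseline_area Pupil area at baseline (a.u.).
#' @param atropine_dilation Area multiple of baseline when clamped dilated.
#' @param lum_floor_lux Luminance floor inside the log (lux).
#' @return A `plr_params` object.
#' @export
plr_params <- function(species = c("mouse", "human"),
                       onset_latency_s = NULL, time_to_peak_s = NULL,
                       max_constriction_frac = 0.5,
                       consensual_gain = 0.7,
                       lowcontrast_boost = 4.0, boost_knee_lux = 20,
                       rebound_amp_frac = 0.30, time_constant_s = NULL,
                       dilation_vmax = 0.30, tau_drive_s = NULL,
                       half_sat = 1.2, dilation_gain = 0.25,
                       baseline_area = 1.0, atropine_dilation = 1.3,
                       lum_floor_lux = 0.1) {
  species <- match.arg(species)
  if (is.null(onset_latency_s)) {
    onset_latency_s <- switch(species, mouse = 0.51, human = 0.55)
  }
  if (is.null(time_to_peak_s)) {
    time_to_peak_s <- switch(species, mouse = 1.74, human = 1.18)
  }
  if (is.null(time_constant_s)) {
    time_constant_s <- switch(species, mouse = 0.35, human = 0.20)
  }
  if (is.null(tau_drive_s)) {
    tau_drive_s <- switch(species, mouse = 0.35, human = 0.15)
  }
  stopifnot(
    max_constriction_frac > 0, max_constriction_frac < 1,
    consensual_gain >= 0, consensual_gain <= 1,
    time_constant_s > 0, dilation_vmax > 0, tau_drive_s > 0, half_sat > 0,
    onset_latency_s > 0, time_to_peak_s > onset_latency_s,
    rebound_amp_frac >= 0, rebound_amp_frac < 1,
    baseline_area > 0
  )
  p <- list(
    species = species,
    onset_latency_s = onset_latency_s, time_to_peak_s = time_to_peak_s,
    max_constriction_frac = max_constriction_frac,
    consensual_gain = consensual_gain,
    lowcontrast_boost = lowcontrast_boost, boost_knee_lux = boost_knee_lux,
    rebound_amp_frac = rebound_amp_frac, time_constant_s = time_constant_s,
    dilation_vmax = dilation_vmax, tau_drive_s = tau_drive_s,
    half_sat = half_sat, dilation_gain = dilation_gain,
    baseline_area = baseline_area, atropine_dilation = atropine_dilation,
    lum_floor_lux = lum_floor_lux
  )
  p <- c(p, calibrate_plr_dynamics(onset_latency_s, time_to_peak_s,
                                   rebound_amp_frac, time_constant_s,
                                   dilation_vmax, tau_drive_s))
  if (p$transport_delay_s < 0) {
    stop("onset_latency_s too short for the neural-integration stages; ",
         "reduce tau_drive_s")
  }
  structure(p, class = "plr_params")
}

# Asymmetric first-order tracking: the state follows the target with
# time constant tau_con, but downward (re-dilation) speed is capped at
# v_dil units per second.
track_asym <- function(target, dt, tau_con, v_dil) {
  a_con <- 1 - exp(-dt / tau_con)
  step_dil <- v_dil * dt
  s <- numeric(length(target))
  prev <- 0
  for (i in seq_along(target)) {
    d <- (target[i] - prev) * a_con
    if (d < -step_dil) d <- -step_dil
    prev <- prev + d
    s[i] <- prev
  }
  s
}

# Noise-free constriction response to a unit drive step under the full
# dynamic chain (neural integration + adaptation + asymmetric tracking),
# on a fine grid. onset_t is where the response first reaches 2% of its
# peak (the noise-free analogue of the threshold detector).
plr_step_response <- function(tau_con, v_dil, tau_adapt, k_adapt,
                              tau_drive, t_max = 25, dt = 0.005) {
  nu <- rep(1, round(t_max / dt))
  nu <- lowpass1(lowpass1(nu, dt, tau_drive), dt, tau_drive)
  target <- nu - k_adapt * lowpass1(nu, dt, tau_adapt)
  s <- track_asym(target, dt, tau_con, v_dil)
  pk <- max(s)
  list(t = (seq_along(s) - 1) * dt, s = s,
       peak_t = (which.max(s) - 1) * dt, peak = pk,
       onset_t = (which(s >= 0.02 * pk)[1] - 1) * dt,
       rebound = 1 - s[length(s)] / pk)
}

# Solve the adaptation stage (tau_adapt, k_adapt) so that the noise-free
# unit-step constriction peaks (time_to_peak - onset) seconds after its
# own 2% detection crossing and relaxes by `rebound` of the peak at
# steady state; the transport delay is then whatever remains of the
# onset latency after the filter rise. Two-parameter Nelder-Mead on the
# simulated step response; also returns the peak value s_peak used to
# normalize drive to constriction depth.
calibrate_plr_dynamics <- function(onset, ttp, rebound, tau_con, v_dil,
                                   tau_drive) {
  u_peak <- ttp - onset
  stopifnot(u_peak > 0)
  obj <- function(par) {
    tau_adapt <- exp(par[1])
    k <- stats::plogis(par[2])
    sr <- plr_step_response(tau_con, v_dil, tau_adapt, k, tau_drive)
    (sr$peak_t - sr$onset_t - u_peak)^2 + (sr$rebound - rebound)^2
  }
  fit <- stats::optim(c(log(2), stats::qlogis(0.4)), obj,
                      control = list(reltol = 1e-10, maxit = 500))
  tau_adapt <- exp(fit$par[1])
  k <- stats::plogis(fit$par[2])
  sr <- plr_step_response(tau_con, v_dil, tau_adapt, k, tau_drive)
  if (abs(sr$peak_t - sr$onset_t - u_peak) > 0.05 ||
      abs(sr$rebound - rebound) > 0.05) {
    warning("PLR dynamic calibration did not fully converge")
  }
  list(tau_adapt = tau_adapt, k_adapt = k, s_peak = sr$peak,
       transport_delay_s = onset - sr$onset_t)
}

# Reference drive: the log-ratio of the high-contrast step (9.5 -> 65 lux),
# which by convention produces the full max_constriction_frac.
ref_drive <- function(plr) log(65 / 9.5)

# Saturating drive nonlinearity, rescaled so g(ref_drive) = 1. Negative
# drive passes through linearly with the dilation weight already applied.
saturate_drive <- function(d, plr) {
  dref <- ref_drive(plr)
  h <- plr$half_sat
  scale <- (dref + h) / dref
  ifelse(d >= 0, scale * d / (d + h), d / dref)
}

#' Simulate the pupillary light reflex for both eyes
#'
#' Forward-simulates the pupil area of each eye in response to a stimulus
#' protocol, per the generative model documented in [plr_params()].
#' Multiplicative Gaussian noise emulates measurement/hippus variability.
#' Pharmacology flags on the protocol clamp the pupil (ATROPINE dilated,
#' CARBACHOL constricted) or remove the ipsilateral eye's drive from both
#' pupils (TTX_IPSI).
#'
#' Two noise sources are distinguished: `physio_noise_sd` is slow
#' physiological fluctuation (hippus) that genuinely modulates retinal
#' illuminance, while `noise_sd` is frame-level measurement noise from the
#' eye camera that only contaminates the recorded trace. The returned
#' traces carry the physiological area (what the retina experiences) in
#' the `"area_true"` attribute.
#'
#' @param protocol A `stim_protocol`.
#' @param plr A `plr_params` object.
#' @param noise_sd Multiplicative measurement-noise SD (default 0.05).
#' @param physio_noise_sd SD of slow multiplicative physiological
#'   fluctuation (default 0.01).
#' @param seed Optional seed for the noise.
#' @return List with elements `contra` and `ipsi`, each a [pupil_trace()].
#' @export
simulate_pupil <- function(protocol, plr = plr_params(), noise_sd = 0.05,
                           physio_noise_sd = 0.01, seed = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(plr, "plr_params"))
  if (!all(is.finite(unlist(plr[!names(plr) %in% "species"])))) {
    stop("non-finite PLR parameters")
  }
  fr <- protocol$frame_rate
  dt <- 1 / fr
  fl <- plr$lum_floor_lux
  bg_c <- protocol$lum_contra[1]
  bg_i <- protocol$lum_ipsi[1]
  log_c <- log((protocol$lum_contra + fl) / (bg_c + fl))
  log_i <- log((protocol$lum_ipsi + fl) / (bg_i + fl))
  if (protocol$pharmacology == "TTX_IPSI") log_i <- log_i * 0

  asym <- function(x) ifelse(x >= 0, x, plr$dilation_gain * x)
  boost_gate <- (log_c > 0) & (log_i > 0) &
    (pmax(protocol$lum_contra, protocol$lum_ipsi) <= plr$boost_knee_lux)
  boost <- ifelse(boost_gate, 1 + plr$lowcontrast_boost, 1)

  drive_eye <- function(own, other) {
    d <- asym(own) + plr$consensual_gain * asym(other)
    saturate_drive(d * boost, plr)
  }
  d_contra <- drive_eye(log_c, log_i)
  d_ipsi <- drive_eye(log_i, log_c)

  filt <- function(d) {
    lag <- round(plr$transport_delay_s * fr)
    d_del <- c(rep(0, lag), d)[seq_along(d)]
    d_int <- lowpass1(lowpass1(d_del, dt, plr$tau_drive_s), dt,
                      plr$tau_drive_s)
    target <- d_int - plr$k_adapt * lowpass1(d_int, dt, plr$tau_adapt)
    s <- track_asym(target, dt, plr$time_constant_s, plr$dilation_vmax)
    s / plr$s_peak
  }

  make_area <- function(d, eye) {
    a0 <- plr$baseline_area
    area <- switch(protocol$pharmacology,
      ATROPINE = rep(a0 * plr$atropine_dilation, length(d)),
      CARBACHOL = rep(a0 * (1 - plr$max_constriction_frac), length(d)),
      {
        s <- pmin(pmax(filt(d), -0.5), 1)
        a0 * (1 - plr$max_constriction_frac * s)
      })
    if (physio_noise_sd > 0 && protocol$pharmacology == "NONE") {
      h <- stats::rnorm(length(area))
      h <- lowpass1(h, dt, 0.5) - lowpass1(h, dt, 2)
      h <- h / max(stats::sd(h), 1e-12) * physio_noise_sd
      area <- area * (1 + h)
    }
    area_true <- pmax(area, 0.01 * plr$baseline_area)
    meas <- area_true
    if (noise_sd > 0) {
      meas <- meas * (1 + stats::rnorm(length(meas), 0, noise_sd))
    }
    tr <- pupil_trace(protocol$time, pmax(meas, 0.01 * plr$baseline_area),
                      eye = eye, sampling_rate = fr)
    attr(tr, "area_true") <- area_true
    tr
  }
  with_seed(seed, list(
    contra = make_area(d_contra, "contra"),
    ipsi = make_area(d_ipsi, "ipsi")
  ))
}

#' Retinal illuminance from screen luminance and pupil area
#'
#' The photoisomerization rate is proportional to screen luminance times
#' pupil area, so effective retinal illuminance (in screen-luminance
#' units) is the elementwise product `luminance * area / baseline_area`.
#'
#' @param luminance Luminance series (lux).
#' @param pupil_area Pupil area series, same length.
#' @param baseline_area Reference (baseline) pupil area.
#' @return Effective illuminance series (a.u., lux-scaled).
#' @export
retinal_illuminance <- function(luminance, pupil_area, baseline_area) {
  if (length(luminance) != length(pupil_area)) stop("length mismatch")
  stopifnot(baseline_area > 0, all(pupil_area > 0))
  luminance * pupil_area / baseline_area
}

#' Re-scale a protocol to mimic PLR-driven illuminance on a clamped pupil
#'
#' Scales the screen luminance frame-by-frame by the relative pupil area
#' of a (dynamic) pupil trace, plus a global correction for the clamped
#' (e.g. atropine-dilated) baseline area. Presenting the returned protocol
#' to an eye whose pupil is fixed at `clamped_area` reproduces the retinal
#' illuminance that the original protocol produced through the functioning
#' pupil.
#'
#' @param protocol A `stim_protocol`.
#' @param pupil List as returned by [simulate_pupil()] (or a single
#'   `pupil_trace` applied to both eyes), aligned to the protocol.
#' @param clamped_area Pupil area during the clamped presentation.
#' @param baseline_area Reference pupil area of the functioning pupil;
#'   when NULL it is estimated as the mean area over the first second.
#' @return A new `stim_protocol` with modified luminance series.
#' @export
model_plr_stimulus <- function(protocol, pupil, clamped_area,
                               baseline_area = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (inherits(pupil, "pupil_trace")) pupil <- list(contra = pupil, ipsi = pupil)
  if (clamped_area <= 0) stop("zero or negative clamped baseline area")
  scale_eye <- function(lum, tr) {
    if (length(tr$area) != length(lum)) stop("pupil trace not aligned")
    a0 <- baseline_area
    if (is.null(a0)) a0 <- mean(tr$area[seq_len(max(1, round(tr$sampling_rate)))])
    lum * (tr$area / a0) * (a0 / clamped_area)
  }
  out <- protocol
  out$lum_contra <- scale_eye(protocol$lum_contra, pupil$contra)
  out$lum_ipsi <- scale_eye(protocol$lum_ipsi, pupil$ipsi)
  out
}
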