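#' Human observer parameters for the dimming-detection task
#'
#' The simulated observer perceives brightness on a Weber-Fechner (log)
#' scale. During a constant-luminance step the PLR reduces retinal
#' illuminance, so the perceived brightness *elevation* above the adapted
#' baseline decays; the observer reports a dimming when the fractional
#' loss of that elevation exceeds `dimming_threshold`. Because PLR
#' amplitude saturates with intensity, a low-contrast step loses a much
#' larger fraction of its (small) elevation than a high-contrast step
#' does, which is what makes low-contrast dimming easier to detect.
#'
#' @param dimming_threshold Fractional loss of log-elevation required for
#'   detection (default 0.45).
#' @param threshold_jitter_sd Relative SD of the per-trial threshold
#'   jitter (default 0.35).
#' @param motor_delay_s Key-press motor delay (default 0.35 s).
#' @param lapse_rate Probability of missing a supra-threshold event
#'   (default 0.15).
#' @param integration_s Perceptual integration window: the brightness
#'   signal is averaged over this window before threshold comparison, so
#'   the observer does not respond to frame-level noise (default 0.3 s).
#' @param persist_s Time the signal must stay beyond threshold to be
#'   reported (default 0.15 s).
#' @return An `observer_params` object.
#' @export
observer_params <- function(dimming_threshold = 0.45,
                            threshold_jitter_sd = 0.35,
                            motor_delay_s = 0.35, lapse_rate = 0.15,
                            integration_s = 0.3, persist_s = 0.15) {
  stopifnot(dimming_threshold > 0, lapse_rate >= 0, lapse_rate <= 1,
            motor_delay_s >= 0, threshold_jitter_sd >= 0,
            integration_s >= 0, persist_s >= 0)
  structure(list(dimming_threshold = dimming_threshold,
                 threshold_jitter_sd = threshold_jitter_sd,
                 motor_delay_s = motor_delay_s, lapse_rate = lapse_rate,
                 integration_s = integration_s, persist_s = persist_s),
            class = "observer_params")
}

#' Simulate detection key-presses for a flash protocol
#'
#' Runs the observer model over every trial of a (constant-after-onset)
#' flash protocol, given the pupil dynamics, and returns the trial log in
#' the human-psychophysics session format. Trials whose flash level is at
#' or below 20 lux are labelled LOW contrast, the rest HIGH.
#'
#' @param protocol A FLASH `stim_protocol` (typically with both LOW and
#'   HIGH level trials; see [make_detection_protocol()]).
#' @param pupil Output of [simulate_pupil()] for the same protocol.
#' @param obs An [observer_params()].
#' @param subject Subject identifier.
#' @param seed Optional seed for lapses and threshold jitter.
#' @return A [psycho_session()].
#' @export
simulate_observer <- function(protocol, pupil, obs = observer_params(),
                              subject = "sim", seed = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(obs, "observer_params"))
  fr <- protocol$frame_rate
  tr <- pupil$contra
  area <- attr(tr, "area_true") # perception follows the physiological pupil
  if (is.null(area)) area <- tr$area
  a0 <- mean(area[seq_len(max(1, round(fr)))])
  E <- retinal_illuminance(protocol$lum_contra, area, a0)
  fl <- 0.1
  e_base <- mean(E[seq_len(max(1, round(fr)))]) + fl
  elev <- log((E + fl) / e_base)
  dur <- protocol$stim_duration_s
  levels <- level_per_trial(protocol)

  with_seed(seed, {
    n <- length(protocol$onsets)
    keypress <- rep(NA_real_, n)
    detected <- logical(n)
    persist_n <- max(1L, round(obs$persist_s * fr))
    for (i in seq_len(n)) {
      i0 <- round(protocol$onsets[i] * fr) + 1L
      idx <- i0:(i0 + round(dur * fr) - 1L)
      el <- elev[idx]
      if (obs$integration_s > 0) {
        el <- smooth_trace(el, max(1L, round(obs$integration_s * fr)))
      }
      el0 <- max(el[seq_len(max(2, round(0.3 * fr)))])
      if (el0 <= 0) next
      frac_drop <- 1 - el / el0
      theta <- obs$dimming_threshold *
        (1 + stats::rnorm(1, 0, obs$threshold_jitter_sd))
      above <- frac_drop >= theta
      runs <- rle(above)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ok <- which(runs$values & runs$lengths >= persist_n)
      if (length(ok) > 0 && stats::runif(1) >= obs$lapse_rate) {
        detected[i] <- TRUE
        keypress[i] <- (starts[ok[1]] - 1) / fr + obs$motor_delay_s
      }
    }
    trials <- data.frame(
      contrast = ifelse(levels <= 20, "LOW", "HIGH"),
      onset_s = protocol$onsets,
      flash_duration_s = dur,
      keypress_s = keypress, # relative to flash onset
      stringsAsFactors = FALSE
    )
    psycho_session(trials, subject = subject, pupil = tr)
  })
}

# Flash level actually shown on the stimulated screen in each trial.
level_per_trial <- function(protocol) {
  fr <- protocol$frame_rate
  vapply(seq_along(protocol$onsets), function(i) {
    i0 <- round(protocol$onsets[i] * fr) + 1L
    idx <- i0:(i0 + round(protocol$stim_duration_s * fr) - 1L)
    lum <- if (protocol$conditions[i] == "IPSI") {
      protocol$lum_ipsi
    } else {
      protocol$lum_contra
    }
    max(lum[idx])
  }, numeric(1))
}

#' Build the human detection-task protocol
#'
#' A randomized sequence of 8 low-amplitude (9.5 to 12 lux) and 8
#' high-amplitude (9.5 to 65 lux) 3 s luminance steps, viewed binocularly,
#' with 6 s of baseline before each step.
#'
#' @param n_low,n_high Trials per contrast (default 8 each).
#' @param duration_s Flash duration (default 3 s).
#' @param frame_rate Sampling rate (Hz).
#' @param seed Seed for the trial-order randomization.
#' @return A `stim_protocol` whose trials mix the two levels.
#' @export
make_detection_protocol <- function(n_low = 8, n_high = 8, duration_s = 3,
                                    frame_rate = 30, seed = NULL) {
  levels <- with_seed(seed, sample(c(rep(12, n_low), rep(65, n_high))))
  proto <- make_protocol("FLASH", level = 65, duration_s = duration_s,
                         conditions = "BOTH", n_rep = length(levels),
                         iti_s = 6, pre_s = 10, frame_rate = frame_rate)
  # overwrite the per-trial step height to the randomized level sequence
  fr <- frame_rate
  for (i in seq_along(levels)) {
    i0 <- round(proto$onsets[i] * fr) + 1L
    idx <- i0:(i0 + round(duration_s * fr) - 1L)
    proto$lum_contra[idx] <- levels[i]
    proto$lum_ipsi[idx] <- levels[i]
  }
  proto$level <- NA_real_
  proto
}
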