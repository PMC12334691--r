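#' RGC functional type specification
#'
#' Describes one simulated retinal ganglion cell type: response polarity
#' (ON cells fire to illuminance increases, OFF cells to decreases),
#' kinetics (TRANSIENT types respond only to the change, SUSTAINED types
#' add a tonic term proportional to the illuminance offset from baseline),
#' gain, calcium-indicator kernel time constants and noise level.
#'
#' @param polarity "ON" or "OFF".
#' @param kinetics "TRANSIENT" or "SUSTAINED".
#' @param gain Response gain (dF/F per unit normalized drive).
#' @param indicator_tau_rise_s,indicator_tau_decay_s Double-exponential
#'   indicator kernel time constants (defaults 0.1 / 1.0 s).
#' @param noise_sd Per-bouton additive fluorescence noise SD.
#' @param sustained_weight Weight of the tonic term for SUSTAINED types.
#' @param rate_half_sat Half-saturation of the output nonlinearity
#'   (units of instantaneous rate, 1/s): RGC responses saturate with
#'   contrast, so large luminance transients are compressed while small
#'   (e.g. pupil-driven) ones remain in the linear range. `Inf` disables.
#' @param label Optional type label.
#' @return An `rgc_type` object.
#' @export
rgc_type <- function(polarity = c("ON", "OFF"),
                     kinetics = c("TRANSIENT", "SUSTAINED"),
                     gain = 1, indicator_tau_rise_s = 0.1,
                     indicator_tau_decay_s = 1.0, noise_sd = 0.05,
                     sustained_weight = 0.5, rate_half_sat = Inf,
                     label = NULL) {
  polarity <- match.arg(polarity)
  kinetics <- match.arg(kinetics)
  stopifnot(indicator_tau_rise_s > 0, indicator_tau_decay_s > 0,
            indicator_tau_decay_s > indicator_tau_rise_s, gain > 0,
            rate_half_sat > 0)
  if (is.null(label)) label <- paste(polarity, kinetics, sep = "_")
  structure(list(polarity = polarity, kinetics = kinetics, gain = gain,
                 indicator_tau_rise_s = indicator_tau_rise_s,
                 indicator_tau_decay_s = indicator_tau_decay_s,
                 noise_sd = noise_sd, sustained_weight = sustained_weight,
                 rate_half_sat = rate_half_sat, label = label),
            class = "rgc_type")
}

#' Default five-type RGC panel
#'
#' One transient OFF, two sustained OFF, one transient ON and one
#' sustained ON type — the five functional classes separable by the chirp
#' stimulus. The two sustained OFF types differ in gain and tonic weight.
#'
#' @param noise_sd Noise SD applied to every type.
#' @return List of five [rgc_type()] objects.
#' @export
rgc_type_panel <- function(noise_sd = 0.05) {
  list(
    rgc_type("OFF", "TRANSIENT", gain = 1.2, noise_sd = noise_sd,
             label = "OFF_TRANSIENT"),
    rgc_type("OFF", "SUSTAINED", gain = 1.0, sustained_weight = 0.6,
             noise_sd = noise_sd, label = "OFF_SUSTAINED_1"),
    rgc_type("OFF", "SUSTAINED", gain = 0.7, sustained_weight = 0.3,
             indicator_tau_decay_s = 1.6, noise_sd = noise_sd,
             label = "OFF_SUSTAINED_2"),
    rgc_type("ON", "TRANSIENT", gain = 1.2, noise_sd = noise_sd,
             label = "ON_TRANSIENT"),
    rgc_type("ON", "SUSTAINED", gain = 0.9, sustained_weight = 0.6,
             noise_sd = noise_sd, label = "ON_SUSTAINED")
  )
}

# Double-exponential indicator kernel, peak-normalized.
indicator_kernel <- function(tau_rise, tau_decay, frame_rate,
                             length_s = 6 * tau_decay) {
  u <- seq(0, length_s, by = 1 / frame_rate)
  k <- exp(-u / tau_decay) - exp(-u / tau_rise)
  k / max(k)
}

#' Simulate bouton calcium traces from a protocol and pupil dynamics
#'
#' Forward model of the evoked two-photon recording. All boutons belong to
#' axons of the GCaMP-expressing (contralateral) eye, so their drive is
#' that eye's retinal illuminance `E(t) = L_contra(t) * area_contra(t) /
#' baseline_area`. Each bouton's underlying rate is the type's gain times
#' the rectified relative change of `E` (OFF: decreases; ON: increases),
#' plus a tonic term for SUSTAINED kinetics; the rate is convolved with a
#' double-exponential indicator kernel. Boutons sharing an axon share the
#' convolved signal and receive independent Gaussian noise. A matched
#' neuropil trace (a scaled common background with slow drift) is emitted
#' per bouton, and the raw traces are contaminated by `npil_contamination`
#' times that background — so the neuropil-subtraction step downstream has
#' something real to remove.
#'
#' @param protocol A `stim_protocol`.
#' @param pupil Output of [simulate_pupil()] for the same protocol.
#' @param types List of [rgc_type()] (default [rgc_type_panel()]).
#' @param axons_per_type Number of simulated axons per type.
#' @param boutons_per_axon Boutons sharing each axon's signal.
#' @param f0 Baseline fluorescence (a.u.).
#' @param npil_level Neuropil background level (a.u.).
#' @param npil_contamination Fraction of neuropil added to the raw trace
#'   (default 0.9, matching the downstream correction).
#' @param bleach_tau_s Photobleaching time constant (s); `Inf` disables.
#' @param seed Optional seed.
#' @return A `bouton_traces` object: matrices `F_raw`, `F_neuropil`
#'   (boutons x frames), `frame_rate`, trial sync (`onsets`, `conditions`,
#'   `stim_duration_s`) and a `meta` data.frame with ground-truth type,
#'   polarity, kinetics and axon id per bouton.
#' @export
simulate_boutons <- function(protocol, pupil, types = rgc_type_panel(),
                             axons_per_type = 4, boutons_per_axon = 1,
                             f0 = 100, npil_level = 20,
                             npil_contamination = 0.9,
                             bleach_tau_s = Inf, seed = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"), length(types) > 0)
  fr <- protocol$frame_rate
  n_frames <- length(protocol$time)
  # boutons respond to the physiological pupil, not the camera's noisy
  # measurement of it
  area <- attr(pupil$contra, "area_true")
  if (is.null(area)) area <- pupil$contra$area
  a0 <- mean(area[seq_len(max(1, round(fr)))])
  E <- retinal_illuminance(protocol$lum_contra, area, a0)
  fl <- 0.1
  e_base <- mean(E[seq_len(max(1, round(fr)))]) + fl
  le <- log((E + fl) / e_base) # Weber-scaled illuminance
  de <- c(0, diff(le)) * fr    # per-second relative change

  with_seed(seed, {
    n_axons <- length(types) * axons_per_type
    n_boutons <- n_axons * boutons_per_axon
    F_raw <- matrix(0, n_boutons, n_frames)
    F_neu <- matrix(0, n_boutons, n_frames)
    meta <- data.frame(bouton_id = seq_len(n_boutons),
                       type = character(n_boutons),
                       polarity = character(n_boutons),
                       kinetics = character(n_boutons),
                       axon_id = integer(n_boutons),
                       stringsAsFactors = FALSE)
    # common slow neuropil fluctuation shared by the field of view
    slow <- lowpass1(stats::rnorm(n_frames), 1 / fr, 5)
    slow <- slow / max(stats::sd(slow), 1e-12) * 0.05
    bleach <- if (is.finite(bleach_tau_s)) {
      exp(-protocol$time / bleach_tau_s)
    } else rep(1, n_frames)

    b <- 0L
    ax <- 0L
    for (ty in types) {
      kern <- indicator_kernel(ty$indicator_tau_rise_s,
                               ty$indicator_tau_decay_s, fr)
      rate <- if (ty$polarity == "OFF") relu(-de) else relu(de)
      if (ty$kinetics == "SUSTAINED") {
        tonic <- if (ty$polarity == "OFF") relu(-le) else relu(le)
        rate <- rate + ty$sustained_weight * tonic
      }
      if (is.finite(ty$rate_half_sat)) {
        rate <- rate / (1 + rate / ty$rate_half_sat)
      }
      sig <- ty$gain * stats::convolve(rate, rev(kern), type = "open")
      sig <- sig[seq_len(n_frames)] / fr
      for (a in seq_len(axons_per_type)) {
        ax <- ax + 1L
        axon_gain <- exp(stats::rnorm(1, 0, 0.2)) # axon-to-axon variability
        for (k in seq_len(boutons_per_axon)) {
          b <- b + 1L
          npil <- npil_level * (1 + slow) *
            exp(stats::rnorm(1, 0, 0.05))
          noise <- stats::rnorm(n_frames, 0, ty$noise_sd * f0)
          F_neu[b, ] <- npil
          F_raw[b, ] <- f0 * bleach * (1 + axon_gain * sig) + noise +
            npil_contamination * npil
          meta$type[b] <- ty$label
          meta$polarity[b] <- ty$polarity
          meta$kinetics[b] <- ty$kinetics
          meta$axon_id[b] <- ax
        }
      }
    }
    structure(list(F_raw = F_raw, F_neuropil = F_neu, frame_rate = fr,
                   onsets = protocol$onsets,
                   conditions = protocol$conditions,
                   stim_duration_s = protocol$stim_duration_s,
                   bouton_ids = meta$bouton_id, meta = meta),
              class = "bouton_traces")
  })
}

#' @export
print.bouton_traces <- function(x, ...) {
  cat(sprintf("<bouton_traces> %d boutons x %d frames @ %.1f Hz | %d trials\n",
              nrow(x$F_raw), ncol(x$F_raw), x$frame_rate, length(x$onsets)))
  invisible(x)
}

#' Simulate spontaneous bouton activity with shared-axon structure
#'
#' Generates the designated "spontaneous" segment used for axon grouping:
#' each axon emits a sparse Poisson train of calcium events; all of its
#' boutons share the convolved event trace and receive independent noise.
#'
#' @param n_axons Number of axons.
#' @param boutons_per_axon Boutons per axon; either a scalar or a vector
#'   of length `n_axons`.
#' @param duration_s Recording duration (s).
#' @param frame_rate Sampling rate (Hz).
#' @param event_rate_hz Mean calcium-event rate per axon.
#' @param amp Event amplitude (dF/F-scale, relative to noise_sd).
#' @param noise_sd Independent per-bouton noise SD.
#' @param seed Optional seed.
#' @return List with matrix `F` (boutons x frames), `frame_rate` and the
#'   ground-truth `axon_id` per bouton.
#' @export
simulate_spontaneous <- function(n_axons, boutons_per_axon = 3,
                                 duration_s = 300, frame_rate = 15,
                                 event_rate_hz = 0.05, amp = 1,
                                 noise_sd = 0.1, seed = NULL) {
  stopifnot(n_axons >= 1, duration_s > 0)
  if (length(boutons_per_axon) == 1L) {
    boutons_per_axon <- rep(boutons_per_axon, n_axons)
  }
  stopifnot(length(boutons_per_axon) == n_axons)
  n_frames <- round(duration_s * frame_rate)
  kern <- indicator_kernel(0.1, 1.0, frame_rate)
  with_seed(seed, {
    n_boutons <- sum(boutons_per_axon)
    Fm <- matrix(0, n_boutons, n_frames)
    axon_id <- integer(n_boutons)
    b <- 0L
    for (a in seq_len(n_axons)) {
      spikes <- stats::rbinom(n_frames, 1, event_rate_hz / frame_rate) *
        stats::rexp(n_frames, 1 / amp)
      sig <- stats::convolve(spikes, rev(kern), type = "open")[seq_len(n_frames)]
      for (k in seq_len(boutons_per_axon[a])) {
        b <- b + 1L
        Fm[b, ] <- sig + stats::rnorm(n_frames, 0, noise_sd)
        axon_id[b] <- a
      }
    }
    list(F = Fm, frame_rate = frame_rate, axon_id = axon_id)
  })
}
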