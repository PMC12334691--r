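#' Construct a full-field dichoptic stimulation protocol
#'
#' Builds the per-eye luminance time series for one of the three full-field
#' protocols used to probe PLR-driven retinal activity:
#'
#' * `FLASH`: positive luminance steps from the 9.5 lux baseline to one of
#'   12, 20, 31, 44 or 65 lux, lasting 3 or 5 s.
#' * `RAMP`: 12 cycles of a sinusoid oscillating around the baseline whose
#'   cycle-by-cycle amplitude grows linearly until it spans the full
#'   0.15-34 lux range, presented at 0.55 or 2 Hz.
#' * `CHIRP`: a compound stimulus (flash, 0.5-8 Hz frequency sweep, 2 Hz
#'   amplitude ramp) used for functional typing of RGC responses.
#'
#' Each trial is presented to the contralateral eye, the ipsilateral eye,
#' or both, `n_rep` times per condition. The non-stimulated eye is held at
#' the baseline luminance (`background_mode = "GRAY"`), which is what
#' permits consensual-PLR-driven responses, or at 0 lux (`"DARK"`), which
#' abolishes them.
#'
#' @param kind One of "FLASH", "RAMP", "CHIRP".
#' @param level Flash luminance in lux (FLASH/CHIRP; default 65).
#' @param duration_s Flash duration in s (3 or 5; default 3).
#' @param freq_hz Sinusoid frequency for RAMP (0.55 or 2 Hz). 0 gives the
#'   degenerate flat ramp.
#' @param n_cycles Number of ramp cycles (default 12).
#' @param amplitude Relative amplitude of the final ramp cycle in (0, 1];
#'   1 spans the full `lum_range`. 0 gives a flat trace.
#' @param conditions Character vector of trial conditions drawn from
#'   CONTRA, IPSI, BOTH.
#' @param n_rep Trials per condition (default 6).
#' @param iti_s Inter-trial pause in s (default 10).
#' @param pre_s Adaptation time before the first trial in s (default 6).
#' @param baseline_lux Background luminance (default 9.5 lux).
#' @param lum_range Minimal/maximal ramp luminance (default c(0.15, 34)).
#' @param frame_rate Sampling rate of the generated series in Hz.
#' @param pharmacology One of "NONE", "ATROPINE", "CARBACHOL", "TTX_IPSI";
#'   carried as a flag interpreted by the simulator.
#' @param background_mode "GRAY" or "DARK".
#' @param seed Optional seed for randomizing the condition order; when
#'   NULL the conditions are interleaved deterministically.
#' @return A `stim_protocol` object: per-eye luminance series, trial
#'   onsets/durations/conditions/levels and protocol metadata.
#' @export
make_protocol <- function(kind = c("FLASH", "RAMP", "CHIRP"),
                          level = 65, duration_s = 3,
                          freq_hz = 0.55, n_cycles = 12, amplitude = 1,
                          conditions = c("CONTRA", "IPSI", "BOTH"),
                          n_rep = 6, iti_s = 10, pre_s = 6,
                          baseline_lux = 9.5, lum_range = c(0.15, 34),
                          frame_rate = 30,
                          pharmacology = c("NONE", "ATROPINE", "CARBACHOL", "TTX_IPSI"),
                          background_mode = c("GRAY", "DARK"),
                          seed = NULL) {
  kind <- match.arg(kind)
  pharmacology <- match.arg(pharmacology)
  background_mode <- match.arg(background_mode)
  conditions <- match.arg(conditions, several.ok = TRUE)
  stop_if_not_scalar(baseline_lux, "baseline_lux")
  if (baseline_lux < 0 || any(lum_range < 0) || level < 0) {
    stop("luminance must be non-negative")
  }
  if (kind == "FLASH" && !level %in% c(12, 20, 31, 44, 65)) {
    warning("flash level outside the standard set {12, 20, 31, 44, 65} lux")
  }

  wave <- switch(kind,
    FLASH = flash_wave(level, duration_s, baseline_lux, frame_rate),
    RAMP = ramp_wave(freq_hz, n_cycles, amplitude, duration_s,
                     baseline_lux, lum_range, frame_rate),
    CHIRP = chirp_wave(baseline_lux, lum_range, frame_rate)
  )
  stim_dur <- length(wave) / frame_rate

  trial_cond <- rep(conditions, each = n_rep)
  if (!is.null(seed)) {
    trial_cond <- with_seed(seed, sample(trial_cond))
  } else {
    trial_cond <- rep(conditions, times = n_rep) # deterministic interleave
  }
  n_trials <- length(trial_cond)
  onsets <- pre_s + (seq_len(n_trials) - 1) * (stim_dur + iti_s)
  total_s <- pre_s + n_trials * (stim_dur + iti_s)
  n_frames <- round(total_s * frame_rate)
  time <- (seq_len(n_frames) - 1) / frame_rate

  bg <- if (background_mode == "GRAY") baseline_lux else 0
  lum_contra <- rep(bg, n_frames)
  lum_ipsi <- rep(bg, n_frames)
  # In DARK mode the stimulated eye also starts from darkness; the stimulus
  # waveform is shifted so its baseline matches the background.
  shift <- bg - baseline_lux
  for (i in seq_len(n_trials)) {
    i0 <- round(onsets[i] * frame_rate) + 1L
    idx <- i0:(i0 + length(wave) - 1L)
    w <- pmax(wave + shift, 0)
    if (trial_cond[i] %in% c("CONTRA", "BOTH")) lum_contra[idx] <- w
    if (trial_cond[i] %in% c("IPSI", "BOTH")) lum_ipsi[idx] <- w
  }
  if (any(lum_contra < 0) || any(lum_ipsi < 0)) stop("negative luminance")
  if (any(diff(onsets) < stim_dur)) stop("overlapping trials")

  structure(list(
    kind = kind, frame_rate = frame_rate, time = time,
    lum_contra = lum_contra, lum_ipsi = lum_ipsi,
    onsets = onsets, stim_duration_s = stim_dur,
    conditions = trial_cond, level = level,
    freq_hz = if (kind != "FLASH") freq_hz else NA_real_,
    n_cycles = if (kind == "RAMP") n_cycles else NA_integer_,
    baseline_lux = baseline_lux, lum_range = lum_range,
    pharmacology = pharmacology, background_mode = background_mode
  ), class = "stim_protocol")
}

flash_wave <- function(level, duration_s, baseline_lux, frame_rate) {
  rep(level, round(duration_s * frame_rate))
}

# Sinusoid around baseline; positive and negative half-cycles are scaled
# separately so that the final cycle touches both ends of lum_range even
# though the baseline does not sit at its midpoint. The per-cycle envelope
# grows linearly with the cycle number.
ramp_wave <- function(freq_hz, n_cycles, amplitude, duration_s,
                      baseline_lux, lum_range, frame_rate) {
  if (freq_hz < 0 || amplitude < 0 || amplitude > 1) {
    stop("invalid ramp parameters")
  }
  if (freq_hz == 0 || amplitude == 0) {
    dur <- if (freq_hz > 0) n_cycles / freq_hz else duration_s
    return(rep(baseline_lux, round(dur * frame_rate)))
  }
  dur <- n_cycles / freq_hz
  t <- seq(0, dur, by = 1 / frame_rate)
  t <- t[-length(t)]
  s <- sin(2 * pi * freq_hz * t)
  cyc <- pmin(floor(t * freq_hz) + 1, n_cycles)
  env <- amplitude * cyc / n_cycles
  up <- lum_range[2] - baseline_lux
  down <- baseline_lux - lum_range[1]
  baseline_lux + env * ifelse(s >= 0, s * up, s * down)
}

# Compound functional-typing stimulus: flash, frequency sweep, 2 Hz
# amplitude ramp, separated by baseline segments.
chirp_wave <- function(baseline_lux, lum_range, frame_rate) {
  gap <- rep(baseline_lux, round(2 * frame_rate))
  flash <- rep(lum_range[2], round(3 * frame_rate))
  sweep_dur <- 8
  t <- seq(0, sweep_dur, by = 1 / frame_rate)
  t <- t[-length(t)]
  f0 <- 0.5; f1 <- 8
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * sweep_dur))
  s <- sin(phase)
  up <- lum_range[2] - baseline_lux
  down <- baseline_lux - lum_range[1]
  sweep <- baseline_lux + ifelse(s >= 0, s * up, s * down)
  ramp <- ramp_wave(2, 12, 1, NA, baseline_lux, lum_range, frame_rate)
  c(gap, flash, gap, sweep, gap, ramp, gap)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %s | %d trials (%s) | stim %.1f s | %.0f Hz | baseline %.1f lux | %s/%s\n",
    x$kind, length(x$onsets), paste(unique(x$conditions), collapse = "/"),
    x$stim_duration_s, x$frame_rate, x$baseline_lux,
    x$pharmacology, x$background_mode))
  invisible(x)
}

#' Time window (s) covered by the k-th ramp cycles
#'
#' Helper for windowed RMI/SNR analyses of the contrast ramp: returns the
#' `[start, end)` interval, relative to trial onset, spanned by the given
#' cycle numbers (e.g. `c(2, 4)` for the low-contrast phase).
#'
#' @param freq_hz Ramp frequency in Hz.
#' @param cycles Integer vector of cycle numbers (1-based).
#' @return Numeric `c(start_s, end_s)`.
#' @export
ramp_cycle_window <- function(freq_hz, cycles) {
  stopifnot(freq_hz > 0, all(cycles >= 1))
  c(min(cycles) - 1, max(cycles)) / freq_hz
}
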