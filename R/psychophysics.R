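#' Human detection-task session log
#'
#' @param trials data.frame with columns `contrast` ("LOW"/"HIGH"),
#'   `onset_s`, `flash_duration_s` and `keypress_s` (time of the detection
#'   key-press relative to flash onset; `NA` when the trial was not
#'   detected).
#' @param subject Subject identifier.
#' @param pupil Optional [pupil_trace()] recorded during the session.
#' @return A `psycho_session` object.
#' @export
psycho_session <- function(trials, subject, pupil = NULL) {
  req <- c("contrast", "onset_s", "flash_duration_s", "keypress_s")
  if (!all(req %in% names(trials))) {
    stop("trials must have columns: ", paste(req, collapse = ", "))
  }
  bad <- !is.na(trials$keypress_s) &
    (trials$keypress_s < 0 | trials$keypress_s > trials$flash_duration_s + 1)
  if (any(bad)) stop("keypress outside the flash window")
  structure(list(trials = trials, subject = subject, pupil = pupil),
            class = "psycho_session")
}

#' Detection statistics across sessions
#'
#' Pools trials across sessions per contrast level and reports detection
#' counts, the percentage through the standard proportion formatter, and
#' the mean detection time (from flash onset) with its SEM. Across
#' subjects, per-subject LOW vs HIGH detection rates are compared with a
#' paired two-sided t-test (primary test; pooled proportions are reported
#' alongside).
#'
#' @param sessions A `psycho_session` or list of them.
#' @return List with a `by_contrast` data.frame (contrast, n_trials,
#'   n_detected, pct_detected, mean_time_s, sem_time_s) and `paired_test`
#'   (htest or NULL when fewer than 2 subjects).
#' @export
detection_stats <- function(sessions) {
  if (inherits(sessions, "psycho_session")) sessions <- list(sessions)
  if (length(sessions) == 0) stop("no sessions")
  all_trials <- do.call(rbind, lapply(sessions, function(s) {
    cbind(s$trials, subject = s$subject, stringsAsFactors = FALSE)
  }))
  if (nrow(all_trials) == 0) stop("no trials")
  by_contrast <- do.call(rbind, lapply(c("LOW", "HIGH"), function(cc) {
    tr <- all_trials[all_trials$contrast == cc, , drop = FALSE]
    if (nrow(tr) == 0) return(NULL)
    det <- !is.na(tr$keypress_s)
    times <- tr$keypress_s[det]
    data.frame(
      contrast = cc, n_trials = nrow(tr), n_detected = sum(det),
      pct_detected = format_proportion(sum(det), nrow(tr)),
      mean_time_s = if (any(det)) mean(times) else NA_real_,
      sem_time_s = if (sum(det) > 1) {
        stats::sd(times) / sqrt(length(times))
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  paired_test <- NULL
  subjects <- unique(all_trials$subject)
  if (length(subjects) >= 2) {
    rate <- function(cc, s) {
      tr <- all_trials[all_trials$contrast == cc & all_trials$subject == s, ]
      if (nrow(tr) == 0) return(NA_real_)
      mean(!is.na(tr$keypress_s))
    }
    lo <- vapply(subjects, rate, numeric(1), cc = "LOW")
    hi <- vapply(subjects, rate, numeric(1), cc = "HIGH")
    ok <- is.finite(lo) & is.finite(hi)
    if (sum(ok) >= 2 && stats::sd(lo[ok] - hi[ok]) > 0) {
      paired_test <- stats::t.test(lo[ok], hi[ok], paired = TRUE)
    }
  }
  list(by_contrast = by_contrast, paired_test = paired_test)
}

#' Align detection times to the PLR peak
#'
#' For every detected trial, the difference between the key-press time and
#' the pupil's peak-constriction time, `keypress - time_to_peak` (both
#' relative to flash onset). Values near zero mean the perceived dimming
#' coincides with peak constriction.
#'
#' @param session A [psycho_session()] (must carry a pupil trace unless
#'   `kinetics` is supplied).
#' @param kinetics Either one [plr_kinetics()] applied to all trials or a
#'   list with one per trial; when NULL, kinetics are computed per trial
#'   from the session's pupil trace.
#' @return Numeric vector of time differences (s), one per detected trial.
#' @export
align_to_plr <- function(session, kinetics = NULL) {
  stopifnot(inherits(session, "psycho_session"))
  tr <- session$trials
  if (is.null(kinetics)) {
    if (is.null(session$pupil)) stop("session has no pupil trace")
    kinetics <- lapply(tr$onset_s, function(on) {
      plr_kinetics(session$pupil, on, window_s = tr$flash_duration_s[1])
    })
  }
  if (inherits(kinetics, "plr_kinetics")) {
    kinetics <- rep(list(kinetics), nrow(tr))
  }
  stopifnot(length(kinetics) == nrow(tr))
  out <- mapply(function(kp, kin) {
    if (is.na(kp) || !kin$valid) return(NA_real_)
    kp - kin$time_to_peak_s
  }, tr$keypress_s, kinetics)
  out[!is.na(out)]
}

#' Compare PLR kinetics between species (or any two groups)
#'
#' Two-sided Welch t-tests on constriction-onset latency and time-to-peak
#' between two groups of [plr_kinetics()] measurements.
#'
#' @param group1,group2 Lists of valid `plr_kinetics` (>= 2 each).
#' @param labels Group labels for the report.
#' @return data.frame with one row per measure: group means, t statistic,
#'   p value.
#' @export
species_kinetics_compare <- function(group1, group2,
                                     labels = c("mouse", "human")) {
  pull <- function(g, field) {
    v <- vapply(g, function(k) k[[field]], numeric(1))
    v[is.finite(v)]
  }
  out <- lapply(c(onset = "onset_latency_s", peak = "time_to_peak_s"),
                function(field) {
    x <- pull(group1, field); y <- pull(group2, field)
    if (length(x) < 2 || length(y) < 2) stop("degenerate group")
    tt <- stats::t.test(x, y)
    data.frame(measure = field, mean1 = mean(x), mean2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[2:3] <- paste0("mean_", labels)
  rownames(out) <- NULL
  out
}

#' Match step photon fluxes across species by relative intensity
#'
#' Given the background photoisomerization rate used for the human
#' experiment, scales each mouse step by its luminance ratio to the mouse
#' baseline: `flux_i = background_flux * step_lux_i / baseline_lux`,
#' optionally rounded to the nearest `round_to`. E.g. a 1500 R* rod^-1
#' s^-1 background with 9.5 lux baseline maps the 12 and 20 lux steps to
#' 1895 and 3160 R* rod^-1 s^-1.
#'
#' @param background_flux Background rate (R* rod^-1 s^-1), positive.
#' @param baseline_lux Mouse baseline luminance (lux), positive.
#' @param step_lux Vector of mouse step luminances (lux).
#' @param round_to Rounding grain (default 5); NULL disables rounding.
#' @return Numeric vector of matched fluxes.
#' @export
match_photon_flux <- function(background_flux, baseline_lux, step_lux,
                              round_to = 5) {
  if (baseline_lux <= 0) stop("zero or negative baseline luminance")
  stopifnot(background_flux > 0, all(step_lux >= 0))
  flux <- background_flux * step_lux / baseline_lux
  if (!is.null(round_to)) flux <- round(flux / round_to) * round_to
  flux
}
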