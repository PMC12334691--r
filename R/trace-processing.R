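#' Neuropil correction
#'
#' Subtracts the scaled neuropil signal from the raw fluorescence,
#' `F_corr = F_raw - scale * F_neuropil` (default scale 0.9).
#'
#' @param F_raw,F_neuropil Equal-shape numeric vectors or matrices
#'   (boutons x frames).
#' @param scale Neuropil scaling factor (default 0.9).
#' @return Corrected fluorescence, same shape.
#' @export
neuropil_correct <- function(F_raw, F_neuropil, scale = 0.9) {
  if (!identical(dim(F_raw), dim(F_neuropil)) ||
      length(F_raw) != length(F_neuropil)) {
    stop("F_raw and F_neuropil must have the same shape")
  }
  F_raw - scale * F_neuropil
}

#' Per-trial dF/F tensors
#'
#' Cuts corrected fluorescence into trial windows and normalizes each
#' trial independently as `(F - F0) / F0`, with `F0` the mean over the
#' `baseline_s` seconds before the trial onset. Per-trial baselining
#' removes slow baseline shifts (photobleaching) at each trial start.
#' Trials whose baseline is non-positive are excluded and recorded.
#'
#' @param F_corr Corrected fluorescence: vector (one bouton) or matrix
#'   (boutons x frames).
#' @param frame_rate Sampling rate (Hz).
#' @param onsets_s Trial onset times (s).
#' @param conditions Condition label per trial (e.g. CONTRA/IPSI/BOTH).
#' @param baseline_s Baseline duration before onset (default 2 s).
#' @param window_s `c(start, end)` of the extracted window relative to
#'   onset (default `c(-baseline_s, stim_duration_s + 4)`).
#' @param stim_duration_s Stimulus duration, used for the default window.
#' @return A `trial_tensor_set`: per condition a `time x trials x boutons`
#'   array of dF/F, plus the relative time axis, frame rate and a record
#'   of excluded trials.
#' @export
dff_per_trial <- function(F_corr, frame_rate, onsets_s, conditions,
                          baseline_s = 2, window_s = NULL,
                          stim_duration_s = 3) {
  if (is.vector(F_corr)) F_corr <- matrix(F_corr, nrow = 1)
  stopifnot(length(onsets_s) == length(conditions))
  if (is.null(window_s)) window_s <- c(-baseline_s, stim_duration_s + 4)
  stopifnot(window_s[1] <= -baseline_s + 1e-9, window_s[2] > 0)
  n_frames <- ncol(F_corr)
  n_b <- nrow(F_corr)
  rel_idx <- seq(round(window_s[1] * frame_rate),
                 round(window_s[2] * frame_rate) - 1L)
  rel_time <- rel_idx / frame_rate
  base_sel <- rel_time >= -baseline_s & rel_time < 0
  if (sum(base_sel) < 1) stop("no baseline samples before trial onset")

  conds <- unique(conditions)
  excluded <- data.frame(trial = integer(0), bouton = integer(0))
  tensors <- list()
  for (cc in conds) {
    tr_idx <- which(conditions == cc)
    arr <- array(NA_real_, dim = c(length(rel_time), length(tr_idx), n_b))
    keep <- rep(TRUE, length(tr_idx))
    for (j in seq_along(tr_idx)) {
      i0 <- round(onsets_s[tr_idx[j]] * frame_rate) + 1L
      idx <- i0 + rel_idx
      if (idx[1] < 1 || idx[length(idx)] > n_frames) {
        stop("trial window outside the recording (need >= baseline_s of ",
             "pre-trial data)")
      }
      seg <- F_corr[, idx, drop = FALSE]
      f0 <- rowMeans(seg[, base_sel, drop = FALSE])
      bad <- f0 <= 0
      if (any(bad)) {
        excluded <- rbind(excluded, data.frame(trial = tr_idx[j],
                                               bouton = which(bad)))
        f0[bad] <- NA_real_
      }
      arr[, j, ] <- t((seg - f0) / f0)
    }
    tensors[[cc]] <- arr[, keep, , drop = FALSE]
  }
  structure(list(tensors = tensors, time = rel_time,
                 frame_rate = frame_rate, n_boutons = n_b,
                 stim_duration_s = stim_duration_s, excluded = excluded),
            class = "trial_tensor_set")
}

#' Per-trial dF/F from simulated bouton traces
#'
#' Convenience wrapper chaining [neuropil_correct()], [smooth_trace()] and
#' [dff_per_trial()] on a `bouton_traces` object, in that order (the
#' corrected trace is smoothed with a 4-frame moving mean before
#' baselining).
#'
#' @param traces A `bouton_traces` object.
#' @param scale Neuropil scale (default 0.9).
#' @param smooth_window Moving-mean window in frames (default 4).
#' @param ... Passed to [dff_per_trial()].
#' @return A `trial_tensor_set`.
#' @export
process_traces <- function(traces, scale = 0.9, smooth_window = 4L, ...) {
  stopifnot(inherits(traces, "bouton_traces"))
  fc <- neuropil_correct(traces$F_raw, traces$F_neuropil, scale)
  fc <- smooth_trace(fc, smooth_window)
  dff_per_trial(fc, traces$frame_rate, traces$onsets, traces$conditions,
                stim_duration_s = traces$stim_duration_s, ...)
}

#' Extract one bouton/condition trial matrix
#'
#' @param set A `trial_tensor_set`.
#' @param condition Condition label.
#' @param bouton Bouton index.
#' @return `time x trials` matrix with attributes `time` and `frame_rate`.
#' @export
get_tensor <- function(set, condition, bouton = 1L) {
  stopifnot(inherits(set, "trial_tensor_set"))
  arr <- set$tensors[[condition]]
  if (is.null(arr)) stop("no such condition: ", condition)
  m <- arr[, , bouton, drop = FALSE]
  dim(m) <- dim(arr)[1:2]
  attr(m, "time") <- set$time
  attr(m, "frame_rate") <- set$frame_rate
  m
}

#' Response quality index
#'
#' `RQI = Var_t[ mean_r(C) ] / mean_r[ Var_t(C) ]` for a `time x trials`
#' response matrix `C`: the temporal variance of the trial-averaged trace
#' over the mean single-trial temporal variance (sample, n-1, variances).
#' Identical non-constant trials give exactly 1; uncorrelated noise tends
#' to `1/R`. Returns `NA` when every trial is constant in time (the bouton
#' should then be excluded).
#'
#' @param C Numeric `time x trials` matrix, `T >= 2`, `R >= 2`.
#' @return RQI scalar (NA when undefined).
#' @export
rqi <- function(C) {
  stopifnot(is.matrix(C))
  if (nrow(C) < 2 || ncol(C) < 2) stop("need T >= 2 and R >= 2")
  if (anyNA(C)) return(NA_real_)
  num <- stats::var(rowMeans(C))
  den <- mean(apply(C, 2, stats::var))
  if (den == 0) return(NA_real_)
  num / den
}

#' RQI table for every bouton and condition
#'
#' @param set A `trial_tensor_set`.
#' @return data.frame `bouton x condition` of RQI values, boutons in rows.
#' @export
rqi_table <- function(set) {
  stopifnot(inherits(set, "trial_tensor_set"))
  out <- sapply(names(set$tensors), function(cc) {
    arr <- set$tensors[[cc]]
    vapply(seq_len(dim(arr)[3]), function(b) {
      m <- arr[, , b, drop = FALSE]
      dim(m) <- dim(arr)[1:2]
      rqi(m)
    }, numeric(1))
  })
  out <- as.data.frame(out)
  out$bouton <- seq_len(nrow(out))
  out[, c("bouton", setdiff(names(out), "bouton"))]
}

#' Filter boutons by response quality
#'
#' Keeps the boutons whose RQI reaches the threshold under *any*
#' condition, so purely binocular responders are retained. The threshold
#' is conventionally set between 0.3 and 0.45 depending on indicator
#' expression; values outside that range trigger a warning.
#'
#' @param rqi_values Either the data.frame from [rqi_table()] or a numeric
#'   matrix/vector of RQI values per bouton.
#' @param threshold RQI threshold (inclusive; default 0.3).
#' @return Integer vector of kept bouton ids.
#' @export
threshold_boutons <- function(rqi_values, threshold = 0.3) {
  if (threshold < 0.3 || threshold > 0.45) {
    warning("RQI threshold outside the conventional 0.3-0.45 range")
  }
  if (is.data.frame(rqi_values)) {
    ids <- rqi_values$bouton
    vals <- as.matrix(rqi_values[, setdiff(names(rqi_values), "bouton"),
                                 drop = FALSE])
  } else {
    vals <- as.matrix(rqi_values)
    ids <- seq_len(nrow(vals))
  }
  best <- apply(vals, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0) -Inf else max(r)
  })
  ids[best >= threshold]
}
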