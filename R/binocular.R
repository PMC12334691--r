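#' Response modulation index (binocular facilitation)
#'
#' `RMI = (AUC(R_BOTH) - AUC(R_CONTRA)) / (AUC(R_BOTH) + AUC(R_CONTRA))`,
#' where each AUC is the time integral of the trial-averaged dF/F over the
#' analysis window, rectified at zero before integration (dF/F can be
#' negative and the index is unbounded otherwise; rectification keeps RMI
#' in \[-1, 1\] and is flagged in the result). Positive RMI = binocular
#' facilitation. For flashes the window is the stimulus "On" period; for
#' the contrast ramp, cycles 2-4 (low-contrast phase) or 7-11
#' (high-contrast phase) via [ramp_cycle_window()].
#'
#' @param tensor_both,tensor_contra `time x trials` matrices on the same
#'   time base (from [get_tensor()]).
#' @param window `c(start, end)` in s relative to trial onset.
#' @return An `rmi_result`: `rmi`, `auc_both`, `auc_contra`, `window`,
#'   `rectified = TRUE`. `rmi` is `NA` when both AUCs are 0.
#' @export
rmi <- function(tensor_both, tensor_contra, window) {
  tt <- attr(tensor_both, "time")
  tc <- attr(tensor_contra, "time")
  if (is.null(tt) || is.null(tc) || !isTRUE(all.equal(tt, tc))) {
    stop("tensors must share a time base (attribute 'time')")
  }
  auc_b <- window_auc(rowMeans(tensor_both, na.rm = TRUE), tt, window)
  auc_c <- window_auc(rowMeans(tensor_contra, na.rm = TRUE), tt, window)
  val <- if (auc_b + auc_c == 0) NA_real_ else (auc_b - auc_c) / (auc_b + auc_c)
  structure(list(rmi = val, auc_both = auc_b, auc_contra = auc_c,
                 window = window, rectified = TRUE),
            class = "rmi_result")
}

# Rectified area under the mean trace within [window[1], window[2]).
window_auc <- function(mean_trace, time, window) {
  sel <- time >= window[1] & time < window[2]
  if (!any(sel)) stop("empty analysis window")
  dt <- mean(diff(time))
  sum(relu(mean_trace[sel])) * dt
}

#' @export
print.rmi_result <- function(x, ...) {
  cat(sprintf("<rmi_result> RMI = %.3f (AUC both %.3f, contra %.3f)\n",
              x$rmi, x$auc_both, x$auc_contra))
  invisible(x)
}

#' Classify binocular summation as sub-, supra- or linear
#'
#' Compares the onset-window response to simultaneous stimulation of both
#' eyes against the sum of the two monocular responses. The response is
#' the rectified AUC over the window; uncertainty comes from resampling
#' trials with replacement within each condition. SUPRALINEAR when the
#' whole (1 - conf) bootstrap band of `both - (contra + ipsi)` lies above
#' zero, SUBLINEAR when below, LINEAR otherwise.
#'
#' @param tensor_both,tensor_contra,tensor_ipsi `time x trials` matrices
#'   on the same time base.
#' @param window `c(start, end)` s; for flashes use `c(0, duration)`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Band coverage (default 0.95).
#' @param seed Optional seed.
#' @return List: `class` ("SUBLINEAR"/"LINEAR"/"SUPRALINEAR"),
#'   `auc_both`, `auc_sum`, `band` (the bootstrap interval of the
#'   difference).
#' @export
summation_class <- function(tensor_both, tensor_contra, tensor_ipsi,
                            window, n_boot = 1000, conf = 0.95,
                            seed = NULL) {
  tt <- attr(tensor_both, "time")
  auc_of <- function(m, cols) {
    window_auc(rowMeans(m[, cols, drop = FALSE], na.rm = TRUE), tt, window)
  }
  nb <- ncol(tensor_both); nc <- ncol(tensor_contra); ni <- ncol(tensor_ipsi)
  obs_b <- auc_of(tensor_both, seq_len(nb))
  obs_s <- auc_of(tensor_contra, seq_len(nc)) +
    auc_of(tensor_ipsi, seq_len(ni))
  diffs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    auc_of(tensor_both, sample.int(nb, replace = TRUE)) -
      (auc_of(tensor_contra, sample.int(nc, replace = TRUE)) +
         auc_of(tensor_ipsi, sample.int(ni, replace = TRUE)))
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  band <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
  cls <- if (band[1] > 0) {
    "SUPRALINEAR"
  } else if (band[2] < 0) {
    "SUBLINEAR"
  } else "LINEAR"
  list(class = cls, auc_both = obs_b, auc_sum = obs_s, band = band)
}

#' Shuffle-null significance of binocular facilitation
#'
#' For each bouton, builds a null RMI distribution by shuffling the
#' BOTH/CONTRA labels across trials, fits a normal distribution to the
#' shuffled RMIs, and flags the bouton as facilitated when its observed
#' RMI exceeds the fitted 95th percentile. One-sided normal p-values are
#' also returned, Bonferroni-corrected by the axon-group correction
#' factor.
#'
#' @param tensors_both,tensors_contra `time x trials x boutons` arrays on
#'   the same time base (e.g. `set$tensors[["BOTH"]]`).
#' @param time Relative time axis of the arrays.
#' @param window Analysis window `c(start, end)` s.
#' @param n_shuffles Label shuffles per bouton (default 1000).
#' @param correction_factor Bonferroni factor from [cluster_axons()]
#'   (default 1).
#' @param percentile Null percentile for the facilitation flag
#'   (default 0.95).
#' @param alpha Significance level for the corrected p-value (default
#'   0.05).
#' @param seed Optional seed.
#' @return data.frame per bouton: `rmi`, `null_q` (fitted percentile),
#'   `facilitated` (RMI above the null percentile), `p`, `p_adj`,
#'   `significant`.
#' @export
rmi_significance <- function(tensors_both, tensors_contra, time, window,
                             n_shuffles = 1000, correction_factor = 1,
                             percentile = 0.95, alpha = 0.05, seed = NULL) {
  stopifnot(length(dim(tensors_both)) == 3,
            length(dim(tensors_contra)) == 3,
            dim(tensors_both)[3] == dim(tensors_contra)[3])
  nb <- dim(tensors_both)[2]
  nc <- dim(tensors_contra)[2]
  if (nb < 2 || nc < 2) stop("need >= 2 trials per condition")
  n_boutons <- dim(tensors_both)[3]
  sel <- time >= window[1] & time < window[2]
  if (!any(sel)) stop("empty analysis window")
  dt <- mean(diff(time))

  # Precompute windowed trial AUCs (rectify the mean trace, so keep the
  # windowed samples per trial and rectify after averaging).
  win_b <- tensors_both[sel, , , drop = FALSE]
  win_c <- tensors_contra[sel, , , drop = FALSE]
  rmi_from <- function(wb, wc) {
    ab <- sum(relu(rowMeans(wb, na.rm = TRUE))) * dt
    ac <- sum(relu(rowMeans(wc, na.rm = TRUE))) * dt
    if (ab + ac == 0) return(NA_real_)
    (ab - ac) / (ab + ac)
  }
  with_seed(seed, {
    out <- data.frame(bouton = seq_len(n_boutons), rmi = NA_real_,
                      null_q = NA_real_, facilitated = FALSE,
                      p = NA_real_, p_adj = NA_real_, significant = FALSE)
    for (b in seq_len(n_boutons)) {
      wb <- win_b[, , b, drop = FALSE]; dim(wb) <- dim(win_b)[1:2]
      wc <- win_c[, , b, drop = FALSE]; dim(wc) <- dim(win_c)[1:2]
      obs <- rmi_from(wb, wc)
      pool <- cbind(wb, wc)
      null <- vapply(seq_len(n_shuffles), function(s) {
        idx <- sample.int(nb + nc)
        rmi_from(pool[, idx[seq_len(nb)], drop = FALSE],
                 pool[, idx[-seq_len(nb)], drop = FALSE])
      }, numeric(1))
      null <- null[is.finite(null)]
      if (!is.finite(obs) || length(null) < 10) next
      mu <- mean(null); sdev <- stats::sd(null)
      if (sdev == 0) {
        q <- mu; p <- as.numeric(obs <= mu)
      } else {
        q <- stats::qnorm(percentile, mu, sdev)
        p <- stats::pnorm(obs, mu, sdev, lower.tail = FALSE)
      }
      out$rmi[b] <- obs
      out$null_q[b] <- q
      out$facilitated[b] <- obs > q
      out$p[b] <- p
      out$p_adj[b] <- min(1, p * correction_factor)
      out$significant[b] <- out$p_adj[b] < alpha
    }
    out
  })
}

#' Trial-covariance SNR decomposition
#'
#' Estimates the stimulus-locked signal variance as the average covariance
#' over all trial pairs, `V_signal = mean_{i<j} Cov(R_i, R_j)` (sample
#' covariance over time), and the noise variance as the mean per-trial
#' variance minus the signal variance. `SNR = V_signal / V_noise`, clamped
#' to 0 when `V_signal < 0` and to `cap` when `V_noise <= 0` (identical
#' trials).
#'
#' @param tensor `time x trials` matrix, >= 2 trials.
#' @param cap SNR value reported when the noise variance is non-positive
#'   (default `Inf`).
#' @return An `snr_result`: `v_signal`, `v_noise`, `snr`, `n_trials`,
#'   `variant = "COVARIANCE"`, `clamped`.
#' @export
snr_covariance <- function(tensor, cap = Inf) {
  stopifnot(is.matrix(tensor))
  n <- ncol(tensor)
  if (n < 2) stop("need >= 2 trials")
  cv <- stats::cov(tensor) # trials x trials, covariance over time
  v_signal <- mean(cv[upper.tri(cv)])
  v_noise <- mean(diag(cv)) - v_signal
  clamped <- FALSE
  if (v_signal < 0) {
    snr <- 0; clamped <- TRUE
  } else if (v_noise <= 0) {
    snr <- cap; clamped <- TRUE
  } else {
    snr <- v_signal / v_noise
  }
  structure(list(v_signal = v_signal, v_noise = v_noise, snr = snr,
                 n_trials = n, variant = "COVARIANCE", clamped = clamped),
            class = "snr_result")
}

#' Binocular SNR improvement ratio
#'
#' `SNR_both / SNR_contra`, with flags at the classical binocular-summation
#' landmarks sqrt(2) (passive summation) and 2 (active summation).
#'
#' @param result_both,result_contra `snr_result` objects.
#' @return List: `ratio`, `above_sqrt2`, `above_2`.
#' @export
snr_improvement <- function(result_both, result_contra) {
  stopifnot(inherits(result_both, "snr_result"),
            inherits(result_contra, "snr_result"))
  if (!is.finite(result_contra$snr) || result_contra$snr == 0) {
    stop("zero or non-finite denominator SNR")
  }
  ratio <- result_both$snr / result_contra$snr
  list(ratio = ratio, above_sqrt2 = ratio >= sqrt(2), above_2 = ratio >= 2)
}

#' Peak-wise SNR for contrast-ramp steps
#'
#' For sparse subsets (e.g. the top 20% responders per ramp peak) the
#' covariance estimator is noisy; here `SNR = mu_signal / sigma_noise`
#' with `mu_signal` the mean of the trial-averaged response inside each
#' peak window and `sigma_noise` the SD of the trial-averaged trace in the
#' pre-stimulus noise window.
#'
#' @param tensor `time x trials` matrix with a `time` attribute.
#' @param peak_windows List of `c(start, end)` windows (s), one per peak.
#' @param noise_window `c(start, end)` pre-stimulus window (s).
#' @return data.frame per peak: `peak`, `mu_signal`, `sigma_noise`, `snr`
#'   (`variant = "PEAKWISE"` attribute).
#' @export
snr_peakwise <- function(tensor, peak_windows, noise_window) {
  tt <- attr(tensor, "time")
  if (is.null(tt)) stop("tensor lacks a time attribute")
  if (!is.list(peak_windows)) peak_windows <- list(peak_windows)
  for (w in peak_windows) {
    if (w[1] < noise_window[2] && noise_window[1] < w[2]) {
      stop("peak windows must not overlap the noise window")
    }
  }
  m <- rowMeans(tensor, na.rm = TRUE)
  nsel <- tt >= noise_window[1] & tt < noise_window[2]
  if (!any(nsel)) stop("empty noise window")
  sigma <- stats::sd(m[nsel])
  out <- do.call(rbind, lapply(seq_along(peak_windows), function(i) {
    w <- peak_windows[[i]]
    sel <- tt >= w[1] & tt < w[2]
    if (!any(sel)) stop("empty peak window")
    mu <- mean(m[sel])
    data.frame(peak = i, mu_signal = mu, sigma_noise = sigma,
               snr = if (sigma == 0) {
                 if (mu == 0) 0 else Inf
               } else mu / sigma)
  }))
  attr(out, "variant") <- "PEAKWISE"
  out
}

#' Select the top-responding boutons
#'
#' Explicit filter for the peak-wise SNR path: keeps the given fraction of
#' boutons with the largest response values.
#'
#' @param values Numeric response measure per bouton (e.g. peak dF/F).
#' @param frac Fraction to keep (default 0.2).
#' @return Integer indices of the kept boutons.
#' @export
top_responders <- function(values, frac = 0.2) {
  stopifnot(frac > 0, frac <= 1)
  n_keep <- max(1L, floor(length(values) * frac))
  order(values, decreasing = TRUE)[seq_len(n_keep)]
}
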