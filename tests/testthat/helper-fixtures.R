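# Shared fixtures built in code.

# A time x trials matrix with a `time` attribute, as get_tensor() returns.
as_tensor <- function(m, frame_rate = 10, t0 = 0) {
  m <- as.matrix(m)
  attr(m, "time") <- t0 + (seq_len(nrow(m)) - 1) / frame_rate
  attr(m, "frame_rate") <- frame_rate
  m
}

# Tensor whose trial-mean rectified AUC over [0, nrow/fr) equals `auc`.
tensor_with_auc <- function(auc, n_time = 10, n_trials = 4, frame_rate = 10) {
  val <- auc * frame_rate / n_time
  as_tensor(matrix(val, n_time, n_trials), frame_rate)
}

# Small evoked simulation used by several end-to-end tests.
quick_flash_run <- function(level = 20, pharmacology = "NONE",
                            background_mode = "GRAY", n_rep = 6,
                            conditions = c("CONTRA", "IPSI", "BOTH"),
                            axons_per_type = 2, seed = 42,
                            plr = plr_params("mouse")) {
  proto <- make_protocol("FLASH", level = level, n_rep = n_rep,
                         conditions = conditions,
                         pharmacology = pharmacology,
                         background_mode = background_mode, seed = seed)
  pupil <- simulate_pupil(proto, plr, seed = seed + 1)
  traces <- simulate_boutons(proto, pupil, axons_per_type = axons_per_type,
                             seed = seed + 2)
  set <- process_traces(traces)
  list(proto = proto, pupil = pupil, traces = traces, set = set)
}

# Mean dF/F of a bouton within a time window (relative to onset).
window_mean <- function(set, condition, bouton, window) {
  m <- get_tensor(set, condition, bouton)
  tt <- attr(m, "time")
  mean(rowMeans(m, na.rm = TRUE)[tt >= window[1] & tt < window[2]])
}
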