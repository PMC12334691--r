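#' Build per-bouton response signatures
#'
#' Concatenates the trial-averaged responses of each bouton across one or
#' more stimuli (in a fixed canonical order: alphabetical by stimulus
#' name, so the result does not depend on list order), smoothed with a
#' 4-frame moving mean. For monocular-typing the CONTRA tensors are used;
#' for PLR-type clustering the IPSI tensors.
#'
#' @param tensor_sets Named list of `trial_tensor_set` objects, one per
#'   stimulus.
#' @param mode Condition to average, "CONTRA" or "IPSI".
#' @param smooth_window Moving-mean window (frames, default 4).
#' @return Numeric boutons x time matrix (the signature matrix).
#' @export
build_signature <- function(tensor_sets, mode = c("CONTRA", "IPSI"),
                            smooth_window = 4L) {
  mode <- match.arg(mode)
  if (inherits(tensor_sets, "trial_tensor_set")) {
    tensor_sets <- list(stim = tensor_sets)
  }
  if (is.null(names(tensor_sets)) || any(names(tensor_sets) == "")) {
    names(tensor_sets) <- paste0("stim", seq_along(tensor_sets))
  }
  ord <- order(names(tensor_sets))
  parts <- lapply(tensor_sets[ord], function(set) {
    arr <- set$tensors[[mode]]
    if (is.null(arr)) stop("condition ", mode, " missing from a tensor set")
    t(apply(arr, 3, function(m) rowMeans(m, na.rm = TRUE))) # boutons x time
  })
  nb <- vapply(parts, nrow, integer(1))
  if (length(unique(nb)) != 1) stop("bouton counts differ across stimuli")
  sig <- do.call(cbind, parts)
  smooth_trace(sig, smooth_window)
}

#' Row-wise z-score normalization of a signature matrix
#'
#' Normalizes each bouton's signature to zero mean and unit (sample) SD
#' along time. Constant rows cannot be normalized; they are dropped with a
#' warning and recorded in the `"excluded"` attribute.
#'
#' @param signature Boutons x time matrix.
#' @return Normalized matrix (possibly fewer rows), with attribute
#'   `excluded` holding the dropped row indices.
#' @export
znorm <- function(signature) {
  stopifnot(is.matrix(signature))
  sds <- apply(signature, 1, stats::sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    warning(sum(bad), " constant signature row(s) excluded")
  }
  out <- (signature[!bad, , drop = FALSE] -
            rowMeans(signature[!bad, , drop = FALSE])) / sds[!bad]
  attr(out, "excluded") <- which(bad)
  out
}

#' Embed response signatures in 2-D and cluster them
#'
#' Reduces the (normalized) signature matrix to two dimensions with PCA
#' (first two principal components) or UMAP, then clusters the embedded
#' points with k-means or a Gaussian mixture model. All stochastic steps
#' run under the supplied seed.
#'
#' @param signatures Boutons x time matrix (typically [znorm()] output).
#' @param k Number of clusters (>= 1; 1 returns a single label).
#' @param method Embedding, "PCA" or "UMAP" (UMAP requires the `uwot`
#'   package).
#' @param algo Clustering algorithm, "KMEANS" or "GMM".
#' @param seed Seed for the embedding/clustering.
#' @return List with `labels` (integer per bouton), `embedding`
#'   (boutons x 2), `method`, `algo`.
#' @export
embed_and_cluster <- function(signatures, k, method = c("PCA", "UMAP"),
                              algo = c("KMEANS", "GMM"), seed = 1) {
  method <- match.arg(method)
  algo <- match.arg(algo)
  stopifnot(is.matrix(signatures), k >= 1)
  if (nrow(signatures) < k) stop("fewer signatures than clusters")
  with_seed(seed, {
    emb <- if (method == "PCA") {
      stats::prcomp(signatures, center = TRUE, scale. = FALSE)$x[, 1:2,
                                                                 drop = FALSE]
    } else {
      if (!requireNamespace("uwot", quietly = TRUE)) {
        stop("UMAP embedding requires the 'uwot' package")
      }
      uwot::umap(signatures,
                 n_neighbors = min(15, nrow(signatures) - 1),
                 n_components = 2, min_dist = 0.1,
                 n_threads = 1, n_sgd_threads = 1)
    }
    labels <- if (k == 1) {
      rep(1L, nrow(signatures))
    } else if (algo == "KMEANS") {
      as.integer(stats::kmeans(emb, centers = k, nstart = 25,
                               iter.max = 100)$cluster)
    } else {
      # Gaussian mixture (full covariances), EM initialized from k-means
      init <- stats::kmeans(emb, centers = k, nstart = 25, iter.max = 100)
      z0 <- mclust::unmap(init$cluster)
      ms <- mclust::mstepVVV(data = emb, z = z0)
      fit <- mclust::emVVV(data = emb, parameters = ms$parameters)
      as.integer(apply(fit$z, 1, which.max))
    }
    list(labels = labels, embedding = emb, method = method, algo = algo)
  })
}

#' Time a bouton's peak and suppression relative to the PLR phases
#'
#' Locates the maximum (peak) and minimum (suppressed) of the trial-mean
#' response within the stimulus window and labels the peak CONSTRICTION if
#' it falls between the constriction onset and the peak-constriction time,
#' REBOUND if it occurs after peak constriction, and EARLY before onset.
#' A flat tensor gets no phase label (`NA`).
#'
#' @param tensor `time x trials` matrix from [get_tensor()] (its `time`
#'   attribute is relative to trial onset).
#' @param kinetics A valid [plr_kinetics()].
#' @param stim_duration_s Stimulus window length (s).
#' @return List with `peak_time_s`, `suppressed_time_s`, `phase`.
#' @export
plr_phase_timing <- function(tensor, kinetics, stim_duration_s = 3) {
  stopifnot(is.matrix(tensor), inherits(kinetics, "plr_kinetics"))
  if (!kinetics$valid) stop("kinetics must be valid")
  tt <- attr(tensor, "time")
  if (is.null(tt)) stop("tensor lacks a time attribute")
  m <- rowMeans(tensor, na.rm = TRUE)
  sel <- tt >= 0 & tt <= stim_duration_s
  ms <- m[sel]; ts <- tt[sel]
  if (max(ms) - min(ms) < .Machine$double.eps^0.5) {
    return(list(peak_time_s = NA_real_, suppressed_time_s = NA_real_,
                phase = NA_character_))
  }
  pk <- ts[which.max(ms)]
  sup <- ts[which.min(ms)]
  phase <- if (pk < kinetics$onset_latency_s) {
    "EARLY"
  } else if (pk <= kinetics$time_to_peak_s) {
    "CONSTRICTION"
  } else {
    "REBOUND"
  }
  list(peak_time_s = pk, suppressed_time_s = sup, phase = phase)
}
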