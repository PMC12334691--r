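#' Detect activity-event windows in a z-scored trace
#'
#' Finds the samples exceeding `z_thresh` standard deviations above the
#' mean and returns the merged set of windows extending `half_window_s` on
#' either side of each supra-threshold sample.
#'
#' @param z Z-scored trace (use [zscore()] first if needed).
#' @param frame_rate Sampling rate (Hz).
#' @param z_thresh Threshold in SDs (default 3.5).
#' @param half_window_s Half window around each event (default 0.7 s).
#' @return Integer matrix with columns `start`, `end` (sample indices,
#'   inclusive); zero rows when the trace never crosses the threshold.
#' @export
detect_events <- function(z, frame_rate, z_thresh = 3.5,
                          half_window_s = 0.7) {
  hw <- round(half_window_s * frame_rate)
  hits <- which(z > z_thresh)
  if (length(hits) == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  starts <- pmax(hits - hw, 1L)
  ends <- pmin(hits + hw, length(z))
  # merge overlapping / touching intervals
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  m_start <- starts[1]; m_end <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= m_end + 1L) {
      m_end <- max(m_end, ends[i])
    } else {
      out[[length(out) + 1L]] <- c(m_start, m_end)
      m_start <- starts[i]; m_end <- ends[i]
    }
  }
  out[[length(out) + 1L]] <- c(m_start, m_end)
  mat <- do.call(rbind, out)
  colnames(mat) <- c("start", "end")
  mat
}

#' Z-score rows of a trace matrix
#'
#' @param x Numeric vector or boutons-x-frames matrix.
#' @return Same shape, each row centered and scaled by its sample SD.
#' @export
zscore <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, zscore)))
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Event-window noise-correlation matrix
#'
#' For every bouton pair, concatenates the samples falling inside the
#' union of the two boutons' activity windows (keeping the pair aligned in
#' time) and computes the Pearson correlation there. Boutons without any
#' event get zero off-diagonal correlation.
#'
#' @param traces Boutons x frames matrix (raw or dF/F; z-scored
#'   internally).
#' @param frame_rate Sampling rate (Hz).
#' @param z_thresh,half_window_s Passed to [detect_events()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
event_correlation_matrix <- function(traces, frame_rate, z_thresh = 3.5,
                                     half_window_s = 0.7) {
  stopifnot(is.matrix(traces), nrow(traces) >= 2)
  z <- zscore(traces)
  n <- nrow(z)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- detect_events(z[i, ], frame_rate, z_thresh, half_window_s)
    m <- logical(ncol(z))
    if (nrow(ev) > 0) {
      for (r in seq_len(nrow(ev))) m[ev[r, 1]:ev[r, 2]] <- TRUE
    }
    masks[[i]] <- m
  }
  cm <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sel <- masks[[i]] | masks[[j]]
      if (sum(sel) < 3 || !any(masks[[i]]) || !any(masks[[j]])) {
        val <- 0
      } else {
        val <- stats::cor(z[i, sel], z[j, sel])
        if (!is.finite(val)) val <- 0
      }
      cm[i, j] <- cm[j, i] <- val
    }
  }
  cm
}

#' Group boutons into putative axons by correlation clustering
#'
#' Thresholds the noise-correlation matrix (entries below `corr_thresh`
#' set to 0), computes pairwise cosine distances between the thresholded
#' correlation vectors, runs average-linkage hierarchical clustering, and
#' cuts the dendrogram at height `cut`. The maximum group size, rounded
#' up, is the Bonferroni correction factor applied to downstream tests.
#'
#' @param corr_matrix Square symmetric correlation matrix.
#' @param corr_thresh Correlation threshold (default 0.7).
#' @param cut Dendrogram cut height in cosine distance (default 0.85).
#' @param linkage Hierarchical-clustering linkage (default "average").
#' @return An `axon_groups` object: `groups` (integer assignment per
#'   bouton), `max_group_size`, `correction_factor`.
#' @export
cluster_axons <- function(corr_matrix, corr_thresh = 0.7, cut = 0.85,
                          linkage = "average") {
  stopifnot(is.matrix(corr_matrix),
            nrow(corr_matrix) == ncol(corr_matrix))
  n <- nrow(corr_matrix)
  if (n == 1) {
    return(structure(list(groups = 1L, max_group_size = 1L,
                          correction_factor = 1L), class = "axon_groups"))
  }
  cm <- corr_matrix
  cm[cm < corr_thresh] <- 0
  norms <- sqrt(rowSums(cm^2))
  sim <- matrix(0, n, n)
  nz <- norms > 0
  if (any(nz)) {
    sim[nz, nz] <- (cm[nz, , drop = FALSE] %*% t(cm[nz, , drop = FALSE])) /
      (norms[nz] %o% norms[nz])
  }
  d <- 1 - sim
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  groups <- stats::cutree(hc, h = cut)
  sizes <- table(groups)
  mx <- max(sizes)
  structure(list(groups = as.integer(groups),
                 max_group_size = as.integer(mx),
                 correction_factor = as.integer(ceiling(mx))),
            class = "axon_groups")
}

#' @export
print.axon_groups <- function(x, ...) {
  cat(sprintf(
    "<axon_groups> %d boutons in %d groups | max size %d | Bonferroni x%d\n",
    length(x$groups), length(unique(x$groups)), x$max_group_size,
    x$correction_factor))
  invisible(x)
}
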