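#' Render binary pupil masks from an area trace
#'
#' Produces one filled-ellipse binary frame per sample of a pupil trace,
#' for exercising the ellipse-fit extraction path. The ellipse axes are
#' chosen so the analytic area `pi * a * b` matches the trace value; pixel
#' quantization limits the match to about one pixel ring. Frames whose
#' area is `NA` or zero are emitted empty.
#'
#' @param trace A [pupil_trace()] with areas in pixel^2.
#' @param image_size `c(height, width)` in pixels (default 128 x 128).
#' @param aspect Ratio a/b of the ellipse axes (default 1 = circle).
#' @param jitter_px SD of the center jitter in pixels (default 0).
#' @param seed Optional seed for the jitter.
#' @return Integer array `height x width x frames` of 0/1 masks.
#' @export
render_pupil_masks <- function(trace, image_size = c(128, 128), aspect = 1,
                               jitter_px = 0, seed = NULL) {
  stopifnot(inherits(trace, "pupil_trace"), aspect > 0)
  h <- image_size[1]; w <- image_size[2]
  n <- length(trace$area)
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
  out <- array(0L, dim = c(h, w, n))
  with_seed(seed, {
    for (i in seq_len(n)) {
      area <- trace$area[i]
      if (is.na(area) || area <= 0) next
      a <- sqrt(area * aspect / pi) # semi-axis along x
      b <- area / (pi * a)
      if (2 * a > w || 2 * b > h) stop("ellipse larger than frame")
      cy <- cy0 + if (jitter_px > 0) stats::rnorm(1, 0, jitter_px) else 0
      cx <- cx0 + if (jitter_px > 0) stats::rnorm(1, 0, jitter_px) else 0
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      out[, , i] <- ((xx - cx)^2 / a^2 + (yy - cy)^2 / b^2 <= 1) * 1L
    }
  })
  out
}

#' Moment-based ellipse fit of a binary pupil mask
#'
#' Fits an ellipse to the foreground pixels by second moments: for a
#' filled ellipse the pixel-coordinate covariance eigenvalues equal
#' `a^2/4` and `b^2/4`, so the semi-axes are `2 * sqrt(eigenvalue)` and
#' the area `pi * a * b`. An empty mask returns an invalid-frame marker
#' (not an error), so the caller can interpolate over blinks.
#'
#' @param mask Binary (0/1 or logical) matrix with at most one pupil blob.
#' @return List with `area`, `center` (x, y), `axes` (a, b),
#'   `orientation` (radians) and `valid`.
#' @export
fit_ellipse_area <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(area = NA_real_, center = c(NA, NA), axes = c(NA, NA),
                orientation = NA_real_, valid = FALSE))
  }
  xy <- cbind(x = idx[, 2], y = idx[, 1])
  center <- colMeans(xy)
  if (nrow(xy) < 4) {
    return(list(area = nrow(xy), center = center, axes = c(NA, NA),
                orientation = NA_real_, valid = TRUE))
  }
  # population covariance plus 1/12 for the pixel's own extent
  cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy) + diag(2) / 12
  eig <- eigen(cv, symmetric = TRUE)
  axes <- 2 * sqrt(pmax(eig$values, 0))
  area <- pi * axes[1] * axes[2]
  orientation <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
  list(area = area, center = center, axes = axes,
       orientation = orientation, valid = TRUE)
}

#' Extract a pupil-area trace from a mask stack
#'
#' Applies [fit_ellipse_area()] frame-by-frame; invalid frames become `NA`
#' in the returned trace (interpolate with [interpolate_invalid()]).
#'
#' @param masks `height x width x frames` binary array.
#' @param sampling_rate Frames per second.
#' @param eye Eye label.
#' @return A [pupil_trace()].
#' @export
masks_to_trace <- function(masks, sampling_rate, eye = "contra") {
  stopifnot(length(dim(masks)) == 3)
  n <- dim(masks)[3]
  areas <- vapply(seq_len(n), function(i) fit_ellipse_area(masks[, , i])$area,
                  numeric(1))
  pupil_trace((seq_len(n) - 1) / sampling_rate, areas, eye = eye,
              sampling_rate = sampling_rate)
}
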