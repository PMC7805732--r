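# Region-based active-contour segmentation of the joint space.
#
# Two-phase piecewise-constant (Chan-Vese type) region evolution in its
# morphological form: each iteration reassigns pixels to the phase whose
# current mean intensity is closer, then regularises the region with a 3x3
# majority (binary median) smoothing mask. The joint space is radiolucent,
# so the segmentation returns the darker phase.

majority_3x3 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  acc <- matrix(0L, nr, nc)
  for (dc in -1:1) {
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    for (dr in -1:1) {
      ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      acc <- acc + mask[ri, ci]
    }
  }
  acc >= 5L
}

#' Segment the joint space with a region-based active contour
#'
#' Evolves a two-phase piecewise-constant region model initialised from a
#' rectangle inset 10% from the ROI border. Each iteration (a) recomputes
#' the two phase means, (b) reassigns every pixel to the nearer phase mean,
#' and (c) applies a 3x3 majority smoothing mask to the region. Evolution
#' stops when the fraction of pixels changing falls below `tolerance` or
#' after `max_iterations`. The returned foreground is the darker
#' (joint-space) phase.
#'
#' @param roi_image Numeric intensity matrix (the cropped ROI).
#' @param max_iterations Iteration cap (default 200).
#' @param tolerance Convergence threshold as a fraction of pixels changed
#'   per iteration (default 1e-3).
#' @return Logical matrix marking the segmented joint-space pixels, with
#'   attributes `iterations` (number performed) and `change_history`
#'   (fraction of pixels changed at each iteration).
#' @export
active_contour_segment <- function(roi_image, max_iterations = 200L,
                                   tolerance = 1e-3) {
  check_gray_image(roi_image)
  if (max_iterations < 1) {
    stop_invalid("`max_iterations` must be >= 1")
  }
  nr <- nrow(roi_image)
  nc <- ncol(roi_image)
  if (nr < 3 || nc < 3) {
    stop_invalid("ROI crop too small to segment (need >= 3x3)")
  }
  if (max(roi_image) - min(roi_image) <= .Machine$double.eps * 255) {
    stop_segment("cannot segment a constant region: no two intensity phases")
  }

  inset_r <- max(1L, round(0.1 * nr))
  inset_c <- max(1L, round(0.1 * nc))
  u <- matrix(FALSE, nr, nc)
  u[(inset_r + 1):(nr - inset_r), (inset_c + 1):(nc - inset_c)] <- TRUE

  npix <- nr * nc
  history <- numeric(0)
  for (it in seq_len(max_iterations)) {
    n_in <- sum(u)
    if (n_in == 0L || n_in == npix) {
      stop_segment("active contour collapsed to a single phase")
    }
    c_in <- sum(roi_image[u]) / n_in
    c_out <- (sum(roi_image) - c_in * n_in) / (npix - n_in)
    if (!is.finite(c_in) || !is.finite(c_out) || c_in == c_out) {
      stop_segment("cannot segment: phase means coincide")
    }
    u_new <- majority_3x3((roi_image - c_in)^2 < (roi_image - c_out)^2)
    change <- sum(xor(u_new, u)) / npix
    history <- c(history, change)
    u <- u_new
    if (change < tolerance) {
      break
    }
  }
  if (!any(u) || all(u)) {
    stop_segment("segmentation converged to an empty phase")
  }
  # Keep the darker phase: the joint space is radiolucent.
  if (mean(roi_image[u]) > mean(roi_image[!u])) {
    u <- !u
  }
  if (!any(u)) {
    stop_segment("segmentation produced an empty joint-space mask")
  }
  attr(u, "iterations") <- length(history)
  attr(u, "change_history") <- history
  u
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return Dice coefficient `2|A&B| / (|A| + |B|)`; 1 if both masks are
#'   empty.
#' @export
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop_invalid("masks must have identical dimensions")
  }
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    return(1)
  }
  2 * sum(a & b) / denom
}
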