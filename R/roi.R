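# Joint-space (cartilage) ROI localisation by pixel density.
#
# Bone attenuates X-rays far more than cartilage, so bone rows carry much
# higher summed intensity. The row-wise intensity-sum profile of a knee
# radiograph therefore shows two high plateaus (femur, tibia) separated by
# a valley at the joint space; the ROI is a horizontal band centred on that
# valley.

gaussian_smooth_vec <- function(v, sd = 3) {
  if (sd <= 0) {
    return(v)
  }
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  k <- k / sum(k)
  n <- length(v)
  padded <- c(rep(v[1], r), v, rep(v[n], r))
  as.numeric(stats::filter(padded, k, sides = 2))[(r + 1):(r + n)]
}

# Deepest valley between two density-profile peaks. Returns NULL when the
# profile is flat, has fewer than two peaks, or the best valley is shallower
# than min_prominence of the dynamic range.
profile_valley <- function(profile, min_prominence) {
  n <- length(profile)
  lo <- min(profile)
  hi <- max(profile)
  rng <- hi - lo
  if (n < 3L || rng <= .Machine$double.eps * max(1, abs(hi))) {
    return(NULL)
  }
  # Candidate peaks: local maxima above 30% of the dynamic range.
  inner <- 2:(n - 1)
  is_peak <- profile[inner] >= profile[inner - 1] &
    profile[inner] >= profile[inner + 1] &
    profile[inner] > lo + 0.3 * rng
  peaks <- inner[is_peak]
  # Collapse plateau runs of equal-height maxima to their midpoints.
  if (length(peaks) > 1L) {
    grp <- cumsum(c(TRUE, diff(peaks) > 1))
    peaks <- round(tapply(peaks, grp, function(i) mean(range(i))))
  }
  if (length(peaks) > 15L) {
    peaks <- sort(peaks[order(profile[peaks], decreasing = TRUE)][1:15])
  }
  if (length(peaks) < 2L) {
    return(NULL)
  }
  # The femur and tibia bands are the peak pair with the deepest valley
  # between them (the radiolucent joint space).
  best <- NULL
  for (i in seq_len(length(peaks) - 1L)) {
    for (j in (i + 1L):length(peaks)) {
      between <- (peaks[i] + 1L):(peaks[j] - 1L)
      if (length(between) < 2L) next
      valley <- min(profile[between])
      depth <- min(profile[peaks[i]], profile[peaks[j]]) - valley
      if (is.null(best) || depth > best$depth) {
        best <- list(depth = depth, between = between, valley = valley)
      }
    }
  }
  if (is.null(best) || best$depth < min_prominence * rng) {
    return(NULL)
  }
  mins <- best$between[which(profile[best$between] == best$valley)]
  best$position <- mins[ceiling(length(mins) / 2)]
  best
}

#' Locate the joint-space ROI from the pixel-density profile
#'
#' Computes the directional intensity-sum profiles (row-wise and
#' column-wise), smooths each with a Gaussian (sd = 3), and finds the pair
#' of profile peaks (the femoral and tibial bone bands) whose intervening
#' valley is deepest; the orientation with the more prominent valley wins,
#' so knees imaged sideways (joint space running vertically) are located
#' too. The joint line is the profile minimum between the two peaks; the
#' returned ROI is a band of `band_height` rows (or columns, for a vertical
#' joint) centred there, spanning the full perpendicular extent. An image
#' without two bone bands — a flat profile, a single band, or no valley
#' deeper than `min_prominence` of the profile's dynamic range — raises an
#' ROI-not-found error.
#'
#' @param image Numeric intensity matrix (ideally already denoised).
#' @param band_height ROI thickness (rows for a horizontal joint, columns
#'   for a vertical one); default one quarter of that dimension.
#' @param min_prominence Minimum valley depth (peak height minus valley
#'   minimum) accepted as a joint space, as a fraction of the smoothed
#'   profile's dynamic range (default 0.05).
#' @return An [roi_box()].
#' @export
locate_joint_roi <- function(image, band_height = NULL,
                             min_prominence = 0.05) {
  check_gray_image(image)
  v_row <- profile_valley(gaussian_smooth_vec(rowSums(image), sd = 3),
                          min_prominence)
  v_col <- profile_valley(gaussian_smooth_vec(colSums(image), sd = 3),
                          min_prominence)
  if (is.null(v_row) && is.null(v_col)) {
    stop_roi("no joint space found: no valley between two bone-density peaks")
  }
  horizontal <- !is.null(v_row) &&
    (is.null(v_col) || v_row$depth >= v_col$depth)
  extent <- if (horizontal) nrow(image) else ncol(image)
  if (is.null(band_height)) {
    band_height <- round(extent / 4)
  }
  band_height <- as.integer(band_height)
  if (band_height < 2 || band_height >= extent) {
    stop_invalid("`band_height` must be in [2, image extent)")
  }
  center <- if (horizontal) v_row$position else v_col$position
  s0 <- center - band_height %/% 2
  s0 <- min(max(s0, 1L), extent - band_height + 1L)
  if (horizontal) {
    roi_box(s0 - 1L, s0 - 1L + band_height, 0L, ncol(image))
  } else {
    roi_box(0L, nrow(image), s0 - 1L, s0 - 1L + band_height)
  }
}

#' Centre row (1-based) of an ROI box
#'
#' @param roi An [roi_box()].
#' @return The central row index, 1-based.
#' @export
roi_center_row <- function(roi) {
  if (!inherits(roi, "roi_box")) {
    stop_invalid("`roi` must be an roi_box")
  }
  (roi$row_start + roi$row_end + 1) / 2
}
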