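# Geometric test transforms. Rotations by multiples of 90 degrees are pure
# index permutations (mathematically lossless), so invariance of the Hu
# moments under them holds to floating-point precision; all other angles
# and all rescaling use inverse-mapped bilinear interpolation with
# zero-valued padding, where invariance holds only up to discretisation
# error.

# Bilinear sample of `image` at fractional (row, col) positions, 1-based;
# points outside the grid read as 0.
bilinear_sample <- function(image, r, c) {
  nr <- nrow(image)
  nc <- ncol(image)
  r0 <- floor(r)
  c0 <- floor(c)
  fr <- r - r0
  fc <- c - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- image[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * at(r0, c0) +
    (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) +
    fr * fc * at(r0 + 1, c0 + 1)
}

rotate90_once <- function(image) {
  # 90 degrees counter-clockwise in matrix terms: new[i, j] = old[j, nr2-i+1]
  t(image)[rev(seq_len(ncol(image))), , drop = FALSE]
}

#' Rotate a grayscale image about its centre
#'
#' Multiples of 90 degrees are performed as exact index permutations.
#' Any other angle uses bilinear interpolation on an enlarged canvas (the
#' rotated bounding box of the input), padded with zeros, so no foreground
#' is cropped.
#'
#' @param image Numeric intensity matrix.
#' @param angle_degrees Rotation angle in degrees (counter-clockwise).
#' @return The rotated image matrix.
#' @export
rotate_image <- function(image, angle_degrees) {
  check_gray_image(image)
  if (!is.finite(angle_degrees)) {
    stop_invalid("`angle_degrees` must be finite")
  }
  a <- angle_degrees %% 360
  if (isTRUE(all.equal(a %% 90, 0)) || isTRUE(all.equal(a %% 90, 90))) {
    k <- round(a / 90) %% 4
    out <- image
    for (i in seq_len(k)) out <- rotate90_once(out)
    return(out)
  }
  theta <- a * pi / 180
  nr <- nrow(image)
  nc <- ncol(image)
  # Enlarged canvas: rotated bounding box of the source.
  nr2 <- ceiling(abs(nr * cos(theta)) + abs(nc * sin(theta)))
  nc2 <- ceiling(abs(nc * cos(theta)) + abs(nr * sin(theta)))
  cr_in <- (nr + 1) / 2
  cc_in <- (nc + 1) / 2
  cr_out <- (nr2 + 1) / 2
  cc_out <- (nc2 + 1) / 2
  grid_r <- rep(seq_len(nr2), times = nc2) - cr_out
  grid_c <- rep(seq_len(nc2), each = nr2) - cc_out
  # Inverse map (rotate output coordinates by -theta). With y = row pointing
  # down, counter-clockwise on screen corresponds to this sign convention.
  src_c <- cos(theta) * grid_c - sin(theta) * grid_r + cc_in
  src_r <- sin(theta) * grid_c + cos(theta) * grid_r + cr_in
  matrix(bilinear_sample(image, src_r, src_c), nr2, nc2)
}

#' Rescale a grayscale image by a positive factor
#'
#' Bilinear resampling to `round(dim * factor)` (at least 1x1).
#'
#' @param image Numeric intensity matrix.
#' @param factor Positive scale factor (< 1 shrinks).
#' @return The resampled image matrix.
#' @export
scale_image <- function(image, factor) {
  check_gray_image(image)
  if (!is.finite(factor) || factor <= 0) {
    stop_invalid("`factor` must be a positive number")
  }
  if (factor == 1) {
    return(image)
  }
  nr2 <- max(1L, as.integer(round(nrow(image) * factor)))
  nc2 <- max(1L, as.integer(round(ncol(image) * factor)))
  # Pixel-centre alignment: output centre u+0.5 maps to input (u+0.5)/f.
  src_r <- (rep(seq_len(nr2), times = nc2) - 0.5) / factor + 0.5
  src_c <- (rep(seq_len(nc2), each = nr2) - 0.5) / factor + 0.5
  matrix(bilinear_sample(image, src_r, src_c), nr2, nc2)
}

#' Translate an image by whole pixels on a fixed canvas
#'
#' Integer shift with zero fill; used to exercise translation invariance of
#' the moment features. Foreground shifted off the canvas is cropped, so
#' invariance checks should keep shifts inside the padding.
#'
#' @param image Numeric intensity matrix.
#' @param dr,dc Integer row/column shifts (positive = down/right).
#' @return Shifted image, same dimensions.
#' @export
shift_image <- function(image, dr, dc) {
  check_gray_image(image)
  if (dr != round(dr) || dc != round(dc)) {
    stop_invalid("`dr` and `dc` must be integers")
  }
  nr <- nrow(image)
  nc <- ncol(image)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c]]
  out
}
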