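# Pre-processing: 3x3 median noise filtering and bone-contour detection.

# The nine 3x3-neighbourhood planes of `image`, with replicated edges,
# as columns of an n-pixel x 9 matrix.
neighbor_stack <- function(image) {
  nr <- nrow(image)
  nc <- ncol(image)
  out <- matrix(0, nr * nc, 9L)
  k <- 0L
  for (dc in -1:1) {
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    for (dr in -1:1) {
      ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      k <- k + 1L
      out[, k] <- image[ri, ci]
    }
  }
  out
}

# Vectorised median of nine values per row, via the classic 19-exchange
# partial sorting network (only element 5 is fully selected).
median_of_nine <- function(m) {
  s <- function(i, j) {
    lo <- pmin(m[, i], m[, j])
    m[, j] <<- pmax(m[, i], m[, j])
    m[, i] <<- lo
  }
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6)
  s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  m[, 5]
}

#' Median-filter denoising
#'
#' A 3x3 median filter with edge replication: the standard pre-processing
#' step that suppresses impulsive film/digitisation noise without blurring
#' the bone edges needed downstream.
#'
#' @param image Numeric intensity matrix.
#' @return Filtered image, same dimensions and intensity range.
#' @export
denoise <- function(image) {
  check_gray_image(image)
  if (nrow(image) == 1L && ncol(image) == 1L) {
    return(image)
  }
  matrix(median_of_nine(neighbor_stack(image)), nrow(image), ncol(image))
}

#' Detect bone contours by thresholding and boundary tracing
#'
#' Binarises the image at `threshold` (Otsu's method by default, since
#' radiographs and phantoms both have bimodal bone/soft-tissue histograms),
#' labels the connected foreground components, discards specks smaller than
#' `min_area`, and marks each component's boundary pixels (foreground pixels
#' with at least one 4-neighbour of background or image border).
#'
#' @param image Numeric intensity matrix.
#' @param threshold Intensity cut; foreground is `image > threshold`.
#'   `NULL` (default) selects the Otsu threshold.
#' @param min_area Minimum component area in pixels; smaller components are
#'   ignored.
#' @return An object of class `contour_map`: list with `edges` (logical
#'   matrix of boundary pixels), `labels` (integer component labels, 0 =
#'   background) and `contour_count` (number of closed boundaries, i.e.
#'   retained components).
#' @export
detect_bone_contours <- function(image, threshold = NULL, min_area = 16L) {
  check_gray_image(image)
  if (is.null(threshold)) {
    rng <- range(image)
    if (rng[1] == rng[2]) {
      # Constant image: no foreground/background separation.
      threshold <- rng[2]
    } else {
      threshold <- EBImage::otsu(image, range = c(0, 255), levels = 256L)
    }
  }
  fg <- image > threshold
  if (!any(fg)) {
    return(structure(
      list(edges = matrix(FALSE, nrow(image), ncol(image)),
           labels = matrix(0L, nrow(image), ncol(image)),
           contour_count = 0L, threshold = threshold),
      class = "contour_map"
    ))
  }
  labels <- EBImage::bwlabel(fg * 1)
  labels <- matrix(as.integer(round(labels)), nrow(image), ncol(image))
  keep <- which(tabulate(labels[labels > 0]) >= min_area)
  labels[!(labels %in% keep)] <- 0L
  labels <- matrix(match(labels, c(0L, keep)) - 1L, nrow(image), ncol(image))
  fg <- labels > 0L

  nr <- nrow(fg)
  nc <- ncol(fg)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr
    cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr
    ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- fg[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- fg & pad(-1, 0) & pad(1, 0) & pad(0, -1) & pad(0, 1)
  edges <- fg & !interior
  structure(
    list(edges = edges, labels = labels,
         contour_count = length(keep), threshold = threshold),
    class = "contour_map"
  )
}

#' @export
print.contour_map <- function(x, ...) {
  cat(sprintf("<contour_map> %d contour(s), %d edge pixel(s), threshold %.2f\n",
              x$contour_count, sum(x$edges), x$threshold))
  invisible(x)
}
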