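# Geometric moments of a grayscale image region.
#
# The image intensity plays the role of the density f(x, y); the continuous
# moment integral is discretised as a plain pixel sum with x = column index
# and y = row index, both 0-based. Raw 8-bit intensities are used as-is
# (no binarisation, no [0,1] rescaling); pixels outside a region mask
# contribute zero.

#' Raw geometric moment of a grayscale image
#'
#' Computes \eqn{m_{pq} = \sum_x \sum_y x^p y^q f(x,y)} over all pixels,
#' with `x` the 0-based column index and `y` the 0-based row index.
#'
#' @param image Numeric matrix of intensities (rows x columns), values
#'   \eqn{\ge 0}.
#' @param p,q Non-negative integer orders; the moment order is `p + q`.
#' @return The raw moment, a single number.
#' @export
#' @examples
#' img <- matrix(0, 8, 8)
#' img[6, 4] <- 1 # x = 3, y = 5
#' raw_moment(img, 1, 0) # m10 = 3
raw_moment <- function(image, p, q) {
  check_gray_image(image)
  if (p < 0 || q < 0 || p != round(p) || q != round(q)) {
    stop_invalid("moment orders `p` and `q` must be non-negative integers")
  }
  x <- seq_len(ncol(image)) - 1
  y <- seq_len(nrow(image)) - 1
  # Sum over rows first: t(y^q) %*% image %*% x^p as vector products.
  as.numeric(crossprod(y^q, image %*% x^p))
}

#' Intensity centroid of a grayscale image
#'
#' @inheritParams raw_moment
#' @return Numeric vector `c(x, y)` with the 0-based centroid
#'   `(m10/m00, m01/m00)`.
#' @export
centroid <- function(image) {
  check_gray_image(image)
  m00 <- sum(image)
  if (m00 <= 0) {
    stop_degenerate("centroid undefined: total image mass m00 is zero")
  }
  c(
    x = raw_moment(image, 1, 0) / m00,
    y = raw_moment(image, 0, 1) / m00
  )
}

#' Central geometric moment of a grayscale image
#'
#' Computes \eqn{\mu_{pq} = \sum_x \sum_y (x-\bar x)^p (y-\bar y)^q f(x,y)}
#' about the intensity centroid, which makes the result invariant to
#' translations of the foreground.
#'
#' @inheritParams raw_moment
#' @return The central moment, a single number.
#' @export
central_moment <- function(image, p, q) {
  check_gray_image(image)
  if (p < 0 || q < 0 || p != round(p) || q != round(q)) {
    stop_invalid("moment orders `p` and `q` must be non-negative integers")
  }
  ctr <- centroid(image)
  x <- (seq_len(ncol(image)) - 1) - ctr[["x"]]
  y <- (seq_len(nrow(image)) - 1) - ctr[["y"]]
  as.numeric(crossprod(y^q, image %*% x^p))
}

#' All moments of order up to three for one image region
#'
#' Computes the raw moments \eqn{m_{pq}} (\eqn{p+q \le 3}), the centroid,
#' the central moments \eqn{\mu_{pq}}, and the scale-normalised central
#' moments \eqn{\eta_{pq} = \mu_{pq} / \mu_{00}^{\gamma}} with
#' \eqn{\gamma = (p+q)/2 + 1} for \eqn{p+q \in \{2, 3\}}.
#'
#' @inheritParams raw_moment
#' @return An object of class `moment_set`: a list with elements `raw`,
#'   `centroid`, `central`, `normalized` and `gamma`. The moment tables are
#'   4x4 matrices indexed `[p + 1, q + 1]` (entries with `p + q > 3` are
#'   `NA`; `normalized` is `NA` outside orders 2--3).
#' @export
moment_set <- function(image) {
  check_gray_image(image)
  if (sum(image) <= 0) {
    stop_degenerate("moment set undefined: total image mass m00 is zero")
  }
  orders <- which(outer(0:3, 0:3, `+`) <= 3, arr.ind = TRUE) - 1L
  raw <- central <- normalized <- gamma <-
    matrix(NA_real_, 4, 4, dimnames = list(p = 0:3, q = 0:3))
  ctr <- centroid(image)
  xc <- seq_len(ncol(image)) - 1
  yc <- seq_len(nrow(image)) - 1
  for (i in seq_len(nrow(orders))) {
    p <- orders[i, 1]
    q <- orders[i, 2]
    raw[p + 1, q + 1] <- as.numeric(crossprod(yc^q, image %*% xc^p))
    central[p + 1, q + 1] <-
      as.numeric(crossprod((yc - ctr[["y"]])^q, image %*% (xc - ctr[["x"]])^p))
    if (p + q >= 2) {
      g <- (p + q) / 2 + 1
      gamma[p + 1, q + 1] <- g
      normalized[p + 1, q + 1] <- central[p + 1, q + 1] / central[1, 1]^g
    }
  }
  structure(
    list(raw = raw, centroid = ctr, central = central,
         normalized = normalized, gamma = gamma),
    class = "moment_set"
  )
}

#' @export
print.moment_set <- function(x, ...) {
  cat("<moment_set>\n")
  cat(sprintf("  m00 = %g, centroid = (%.4f, %.4f)\n",
              x$raw[1, 1], x$centroid[["x"]], x$centroid[["y"]]))
  eta <- x$normalized
  cat(sprintf("  eta20 = %.6g, eta02 = %.6g, eta11 = %.6g\n",
              eta[3, 1], eta[1, 3], eta[2, 2]))
  invisible(x)
}

#' Fill the normalised central moments of a moment set
#'
#' Applies the scale normalisation \eqn{\eta_{pq} = \mu_{pq} /
#' \mu_{00}^{(p+q)/2 + 1}} to an existing moment set. [moment_set()]
#' already performs this; the function exists so the normalisation step is
#' separately testable.
#'
#' @param momset A `moment_set`.
#' @return The moment set with `normalized` (and `gamma`) filled.
#' @export
normalized_moments <- function(momset) {
  if (!inherits(momset, "moment_set")) {
    stop_invalid("`momset` must be a moment_set")
  }
  mu00 <- momset$central[1, 1]
  if (!is.finite(mu00) || mu00 <= 0) {
    stop_degenerate("normalised moments undefined: mu00 is zero")
  }
  for (p in 0:3) {
    for (q in 0:3) {
      if (p + q >= 2 && p + q <= 3) {
        g <- (p + q) / 2 + 1
        momset$gamma[p + 1, q + 1] <- g
        momset$normalized[p + 1, q + 1] <-
          momset$central[p + 1, q + 1] / mu00^g
      }
    }
  }
  momset
}

#' Hu's seven invariant moments
#'
#' Combines the normalised central moments \eqn{\eta_{pq}} into Hu's seven
#' polynomial invariants \eqn{\phi_1 \ldots \phi_7}, which are unchanged by
#' translation, uniform scaling and in-plane rotation of the image
#' foreground; \eqn{\phi_7} changes sign under reflection (the skew
#' invariant). Values are returned on the raw scale (no log transform).
#'
#' @param momset A `moment_set` with normalised moments filled, or a
#'   grayscale image matrix (in which case the moment chain is computed
#'   first).
#' @return Named numeric vector `phi1 ... phi7`.
#' @export
#' @examples
#' img <- matrix(0, 64, 64)
#' img[20:44, 25:39] <- 200
#' hu_vector(img)
hu_vector <- function(momset) {
  if (is.matrix(momset) && is.numeric(momset)) {
    momset <- moment_set(momset)
  }
  if (!inherits(momset, "moment_set")) {
    stop_invalid("`momset` must be a moment_set or a grayscale image matrix")
  }
  eta <- momset$normalized
  if (any(!is.finite(eta[outer(0:3, 0:3, `+`) %in% c(2, 3)]))) {
    stop_state("normalised moments are missing; call normalized_moments()")
  }
  e <- function(p, q) eta[p + 1, q + 1]
  n20 <- e(2, 0); n02 <- e(0, 2); n11 <- e(1, 1)
  n30 <- e(3, 0); n03 <- e(0, 3); n21 <- e(2, 1); n12 <- e(1, 2)
  phi1 <- n20 + n02
  phi2 <- (n20 - n02)^2 + 4 * n11^2
  phi3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  phi4 <- (n30 + n12)^2 + (n21 + n03)^2
  phi5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  phi6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  phi7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n12 - n30) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(phi1 = phi1, phi2 = phi2, phi3 = phi3, phi4 = phi4,
    phi5 = phi5, phi6 = phi6, phi7 = phi7)
}

#' Hu moments of a masked image region
#'
#' Zeroes every pixel outside `mask`, then runs the full moment chain
#' (raw, central, normalised) and returns Hu's seven invariants for the
#' remaining region. This is the feature extractor applied to the segmented
#' joint-space region in the grading pipeline.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix of the same shape; `TRUE` marks the region.
#' @return Named numeric vector `phi1 ... phi7`. A single-pixel region is
#'   degenerate but defined: all invariants are zero.
#' @export
features_from_region <- function(image, mask) {
  check_gray_image(image)
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_invalid("`mask` must be a logical matrix")
  }
  if (!identical(dim(mask), dim(image))) {
    stop_invalid("`mask` and `image` must have identical dimensions")
  }
  if (!any(mask)) {
    stop_degenerate("empty mask: no foreground pixels in region")
  }
  masked <- image
  masked[!mask] <- 0
  if (sum(masked) <= 0) {
    stop_degenerate("masked region has zero total intensity")
  }
  hu_vector(moment_set(masked))
}
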