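test_that("raw moments of delta and uniform images match hand sums", {
  img <- matrix(0, 8, 8)
  img[6, 4] <- 1 # x = 3, y = 5 in 0-based coordinates
  expect_equal(raw_moment(img, 0, 0), 1)
  expect_equal(raw_moment(img, 1, 0), 3)
  expect_equal(raw_moment(img, 0, 1), 5)

  ones <- matrix(1, 2, 2)
  expect_equal(raw_moment(ones, 0, 0), 4)
  expect_equal(raw_moment(ones, 1, 0), 2)
  expect_equal(raw_moment(ones, 0, 1), 2)

  expect_error(raw_moment(img, -1, 0), class = "km_invalid_argument")
})

test_that("centroid matches the delta position and uniform-image centre", {
  img <- matrix(0, 8, 8)
  img[6, 4] <- 7
  expect_equal(unname(centroid(img)), c(3, 5))

  uni <- matrix(3, 5, 9)
  expect_equal(unname(centroid(uni)), c((9 - 1) / 2, (5 - 1) / 2))

  expect_error(centroid(matrix(0, 4, 4)), class = "km_degenerate_input")
})

test_that("moments of orders <= 3 match the nested-loop oracle on 50 random images", {
  for (i in 1:50) {
    dims <- withr::with_seed(1000 + i, sample(2:16, 2, replace = TRUE))
    img <- random_test_image(dims[1], dims[2], seed = 2000 + i)
    if (sum(img) == 0) img[1, 1] <- 1
    ms <- moment_set(img)
    mu00 <- sum(img)
    for (p in 0:3) {
      for (q in 0:(3 - p)) {
        expect_moment_equal(ms$raw[p + 1, q + 1],
                            oracle_raw_moment(img, p, q), img, p, q)
        expect_moment_equal(ms$central[p + 1, q + 1],
                            oracle_central_moment(img, p, q), img, p, q)
        if (p + q >= 2) {
          expect_moment_equal(ms$normalized[p + 1, q + 1],
                              oracle_eta(img, p, q), img, p, q,
                              denom = mu00^((p + q) / 2 + 1))
        }
      }
    }
  }
})

test_that("first-order central moments vanish and mu is translation invariant", {
  img <- random_test_image(12, 10, seed = 7)
  m00 <- sum(img)
  expect_lt(abs(central_moment(img, 1, 0)), 1e-9 * m00)
  expect_lt(abs(central_moment(img, 0, 1)), 1e-9 * m00)

  # Lossless integer shift on a padded canvas leaves central moments alone.
  pad <- matrix(0, 30, 30)
  pad[10:21, 10:19] <- img
  shifted <- shift_image(pad, 4, -3)
  for (pq in list(c(2, 0), c(1, 1), c(0, 2), c(3, 0), c(2, 1))) {
    expect_equal(central_moment(shifted, pq[1], pq[2]),
                 central_moment(pad, pq[1], pq[2]), tolerance = 1e-9)
  }
})

test_that("normalised moments carry gamma = (p+q)/2 + 1 and are scale invariant", {
  sq <- function(side, n = 64) {
    img <- matrix(0, n, n)
    at <- (n - side) %/% 2
    img[at:(at + side - 1), at:(at + side - 1)] <- 1
    img
  }
  ms8 <- moment_set(sq(8))
  ms32 <- moment_set(sq(32))
  expect_equal(ms8$gamma[3, 1], 2) # p+q = 2
  expect_equal(ms8$gamma[4, 1], 2.5) # p+q = 3
  expect_equal(ms8$normalized[3, 1], ms32$normalized[3, 1], tolerance = 0.02)
  # Axis symmetry: eta11 = 0.
  expect_lt(abs(ms32$normalized[2, 2]), 1e-9)

  expect_error(
    normalized_moments(structure(list(central = matrix(0, 4, 4)),
                                 class = "moment_set")),
    class = "km_degenerate_input"
  )
})

test_that("Hu invariants of a centred disc match the closed form", {
  # Continuous unit-density disc: eta20 = eta02 = 1/(4*pi), so
  # phi1 = 1/(2*pi) and all other invariants vanish by rotational symmetry.
  n <- 256
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), times = n), n)
  disc <- ((xs - 128.5)^2 + (ys - 128.5)^2 <= 40^2) * 1
  phi <- hu_vector(disc)
  expect_equal(unname(phi[1]), 1 / (2 * pi), tolerance = 1e-3)
  expect_true(all(abs(phi[2:7]) <= 1e-4))
})

test_that("mirroring negates phi7 and preserves phi1..phi6", {
  sh <- smooth_test_shape(128)
  phi <- hu_vector(sh)
  phim <- hu_vector(sh[, rev(seq_len(ncol(sh)))])
  expect_equal(phim[1:6], phi[1:6], tolerance = 1e-9)
  expect_equal(unname(phim[7]), -unname(phi[7]), tolerance = 1e-9)
})

test_that("hu_vector handles degenerate and invalid inputs", {
  ms <- moment_set(matrix(1, 4, 4))
  ms$normalized[] <- 0
  expect_equal(unname(hu_vector(ms)), rep(0, 7))

  ms$normalized[] <- NA_real_
  expect_error(hu_vector(ms), class = "km_invalid_state")
  expect_error(hu_vector(list()), class = "km_invalid_argument")
})

test_that("features_from_region masks correctly", {
  img <- random_test_image(16, 16, seed = 3) + 1
  all_fg <- matrix(TRUE, 16, 16)
  expect_equal(features_from_region(img, all_fg), hu_vector(img))

  one <- matrix(FALSE, 16, 16)
  one[5, 9] <- TRUE
  expect_equal(unname(features_from_region(img, one)), rep(0, 7))

  expect_error(features_from_region(img, matrix(FALSE, 16, 16)),
               class = "km_degenerate_input")
  expect_error(features_from_region(img, matrix(TRUE, 8, 8)),
               class = "km_invalid_argument")

  # Lossless 90-degree rotation of a masked region leaves the invariants.
  ph <- generate_phantom(phantom_spec("Moderate", seed = 5, noise_sd = 0))
  crop <- crop_roi(ph$image, ph$true_roi)
  mask <- ph$true_mask[(ph$true_roi$row_start + 1):ph$true_roi$row_end, ]
  phi <- features_from_region(crop, mask)
  rot_img <- rotate_image(crop, 90)
  rot_mask <- rotate_image(mask * 1, 90) > 0.5
  phi_rot <- features_from_region(rot_img, rot_mask)
  big <- abs(phi) > 1e-12
  expect_equal(phi_rot[big], phi[big], tolerance = 1e-9)
})
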