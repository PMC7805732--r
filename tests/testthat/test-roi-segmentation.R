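test_that("joint ROI is found at the phantom's true joint line", {
  sp <- phantom_spec("Mild", seed = 3, noise_sd = 0)
  ph <- generate_phantom(sp)
  roi <- locate_joint_roi(ph$image)
  expect_lte(abs(roi_center_row(roi) - ph$gap_center_row), 5)

  # 180-degree rotation mirrors the joint line position.
  roi180 <- locate_joint_roi(rotate_image(ph$image, 180))
  expect_lte(abs(roi_center_row(roi180) -
                   (nrow(ph$image) + 1 - ph$gap_center_row)), 5)

  expect_error(locate_joint_roi(matrix(100, 64, 64)),
               class = "km_roi_not_found")
  expect_error(locate_joint_roi(ph$image, band_height = 1),
               class = "km_invalid_argument")
})

test_that("ROI localisation tolerates noise within two rows", {
  for (seed in 1:8) {
    clean <- generate_phantom(phantom_spec("Moderate", seed = seed,
                                           noise_sd = 0))
    noisy <- generate_phantom(phantom_spec("Moderate", seed = seed,
                                           noise_sd = 5))
    r0 <- locate_joint_roi(denoise(clean$image))
    r1 <- locate_joint_roi(denoise(noisy$image))
    expect_lte(abs(roi_center_row(r1) - roi_center_row(r0)), 2)
  }
})

test_that("active contour recovers a dark rectangle on bright background", {
  crop <- matrix(200, 60, 100)
  crop[20:40, 30:70] <- 60
  mask <- active_contour_segment(crop)
  truth <- matrix(FALSE, 60, 100)
  truth[20:40, 30:70] <- TRUE
  expect_gte(dice_overlap(mask, truth), 0.95)

  expect_error(active_contour_segment(matrix(128, 40, 40)),
               class = "km_segmentation_failed")
  expect_error(active_contour_segment(crop, max_iterations = 0),
               class = "km_invalid_argument")
})

test_that("segmentation of the phantom joint space overlaps the ground truth", {
  ph <- generate_phantom(phantom_spec("Doubtful", seed = 8, noise_sd = 0))
  roi <- locate_joint_roi(ph$image)
  crop <- crop_roi(ph$image, roi)
  mask <- active_contour_segment(crop)
  truth <- ph$true_mask[(roi$row_start + 1):roi$row_end,
                        (roi$col_start + 1):roi$col_end]
  expect_gte(dice_overlap(mask, truth), 0.90)
})

test_that("active-contour evolution settles monotonically", {
  ok <- 0
  runs <- 10
  for (seed in seq_len(runs)) {
    ph <- generate_phantom(phantom_spec("Mild", seed = 100 + seed,
                                        noise_sd = 5))
    roi <- locate_joint_roi(denoise(ph$image))
    mask <- active_contour_segment(crop_roi(denoise(ph$image), roi))
    h <- attr(mask, "change_history")
    tail_h <- utils::tail(h, 10)
    if (all(diff(tail_h) <= 0)) ok <- ok + 1
  }
  expect_gte(ok / runs, 0.9)
})

test_that("the pipeline's Hu features are stable under 90-degree rotation", {
  pipe <- function(img) {
    d <- denoise(img)
    roi <- locate_joint_roi(d)
    crop <- crop_roi(d, roi)
    features_from_region(crop, active_contour_segment(crop))
  }
  ph <- generate_phantom(phantom_spec("Mild", seed = 3, noise_sd = 5))
  p0 <- pipe(ph$image)
  p90 <- pipe(rotate_image(ph$image, 90))
  big <- abs(p0) > 1e-12
  expect_equal(p90[big], p0[big], tolerance = 0.05)
})
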