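# Synthetic knee-phantom generator.
#
# A phantom emulates a fixed-flexion knee radiograph just closely enough to
# exercise every pipeline stage: two bright horizontal "bone" bands (femur
# above, tibia below) with gently rounded condyle profiles, separated by a
# darker joint-space gap whose width encodes the KL grade, optional bright
# osteophyte bumps protruding into the gap, and additive clipped Gaussian
# noise. Every output is a pure function of its spec (including the seed).

# Run `expr` under a private RNG state so generators never disturb the
# caller's random stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default joint-space gap width for a KL grade
#'
#' Package default mapping from KL grade to joint-space width in pixels at
#' the default 256-row phantom scale. The widths decrease strictly with
#' severity (joint-space narrowing is the key radiographic severity cue);
#' Severe may reach 0 (bone-on-bone) after per-sample jitter.
#'
#' @param grade Anything accepted by [kl_grade()].
#' @return Numeric gap width(s) in pixels: 30, 22, 14, 7, 2 for
#'   Normal ... Severe.
#' @export
#' @examples
#' default_gap_width(kl_grades())
default_gap_width <- function(grade) {
  widths <- c(Normal = 30, Doubtful = 22, Mild = 14, Moderate = 7, Severe = 2)
  unname(widths[as.character(kl_grade(grade))])
}

#' Specification of one synthetic knee phantom
#'
#' @param grade KL grade of the phantom (label or 0--4 ordinal).
#' @param image_size Integer `c(rows, cols)`; the default 256 x 465 keeps
#'   the aspect ratio of a full-size digital knee radiograph at roughly
#'   one-fifth scale.
#' @param gap_width Joint-space width in pixels at the image midline;
#'   defaults to [default_gap_width()] for the grade.
#' @param gap_center_row Row (1-based) of the joint-space centre line.
#' @param osteophyte_count Number of marginal bone bumps protruding into
#'   the gap; defaults to the grade ordinal (0 for Normal ... 4 for Severe).
#' @param condyle_amplitude Amplitude (pixels) of the rounded condyle
#'   profile of the band edges.
#' @param bone_intensity,gap_intensity,background_intensity Mean 8-bit
#'   intensities of bone, joint space and surrounding soft tissue.
#' @param noise_sd Standard deviation of the additive clipped Gaussian
#'   noise, in intensity units.
#' @param seed Integer seed; phantoms are bit-identical given the same spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grade,
                         image_size = c(256L, 465L),
                         gap_width = default_gap_width(grade),
                         gap_center_row = round(image_size[1] / 2),
                         osteophyte_count = kl_ordinal(grade),
                         condyle_amplitude = 4,
                         bone_intensity = 200,
                         gap_intensity = 60,
                         background_intensity = 30,
                         noise_sd = 8,
                         seed = 1L) {
  grade <- kl_grade(grade)
  if (length(image_size) != 2L || any(image_size < 32)) {
    stop_invalid("`image_size` must be c(rows, cols) with both >= 32")
  }
  if (gap_width < 0) {
    stop_invalid("`gap_width` must be non-negative")
  }
  if (gap_width >= image_size[1]) {
    stop_invalid("`gap_width` exceeds the image height")
  }
  if (osteophyte_count < 0 || osteophyte_count != round(osteophyte_count)) {
    stop_invalid("`osteophyte_count` must be a non-negative integer")
  }
  if (noise_sd < 0) {
    stop_invalid("`noise_sd` must be non-negative")
  }
  structure(
    list(grade = grade, image_size = as.integer(image_size),
         gap_width = gap_width, gap_center_row = gap_center_row,
         osteophyte_count = as.integer(osteophyte_count),
         condyle_amplitude = condyle_amplitude,
         bone_intensity = bone_intensity, gap_intensity = gap_intensity,
         background_intensity = background_intensity,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic knee phantom with ground truth
#'
#' Renders the phantom described by a [phantom_spec()] and returns the image
#' together with the ground-truth joint-space mask, the true ROI box, and
#' the grade, so segmentation and grading accuracy can be scored exactly.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `knee_phantom`: a list with `image` (numeric
#'   matrix), `true_roi` ([roi_box()] around the joint space), `true_mask`
#'   (logical matrix marking joint-space pixels), `grade`,
#'   `gap_center_row`, and the originating `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec("Mild", seed = 7))
#' dim(ph$image)
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_invalid("`spec` must be a phantom_spec")
  }
  nr <- spec$image_size[1]
  nc <- spec$image_size[2]
  ctr <- spec$gap_center_row
  half <- spec$gap_width / 2

  x <- seq_len(nc)
  # Rounded condyle profile: a single smooth arch widening the gap slightly
  # toward mid-image, applied to both band edges.
  arch <- spec$condyle_amplitude * sin(pi * (x - 0.5) / nc)
  femur_edge <- ctr - half - arch       # last bone row of the femur (real)
  tibia_edge <- ctr + half + arch       # first bone row of the tibia (real)

  # Marginal osteophytes: bright semicircular bumps protruding into the
  # joint space, alternating femur/tibia, at deterministic positions.
  if (spec$osteophyte_count > 0) {
    pos <- round(seq(0.15, 0.85, length.out = spec$osteophyte_count) * nc)
    for (i in seq_along(pos)) {
      w <- 8
      dx <- x - pos[i]
      bump <- ifelse(abs(dx) < w, 5 * sqrt(pmax(0, 1 - (dx / w)^2)), 0)
      if (i %% 2 == 1) {
        femur_edge <- femur_edge + bump
      } else {
        tibia_edge <- tibia_edge - bump
      }
    }
    # Bumps may not cross the opposite edge.
    cross <- tibia_edge - femur_edge < 0
    mid <- (tibia_edge + femur_edge) / 2
    femur_edge[cross] <- mid[cross]
    tibia_edge[cross] <- mid[cross]
  }

  femur_top <- round(0.12 * nr)
  tibia_bottom <- round(0.88 * nr)

  rows <- matrix(seq_len(nr), nr, nc)
  fe <- matrix(femur_edge, nr, nc, byrow = TRUE)
  te <- matrix(tibia_edge, nr, nc, byrow = TRUE)
  bone <- (rows >= femur_top & rows <= fe) |
    (rows >= te & rows <= tibia_bottom)
  gap <- rows > fe & rows < te

  img <- matrix(spec$background_intensity, nr, nc)
  img[gap] <- spec$gap_intensity
  img[bone] <- spec$bone_intensity

  if (spec$noise_sd > 0) {
    noise <- with_local_seed(spec$seed,
                             matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc))
    img <- clip_intensity(img + noise)
  }

  band <- max(16L, round(nr / 4))
  r0 <- max(0L, ctr - band %/% 2)
  r1 <- min(nr, r0 + band)
  structure(
    list(image = img,
         true_roi = roi_box(r0, r1, 0L, nc),
         true_mask = gap,
         grade = spec$grade,
         gap_center_row = ctr,
         spec = spec),
    class = "knee_phantom"
  )
}

#' @export
print.knee_phantom <- function(x, ...) {
  cat(sprintf("<knee_phantom> %dx%d, grade %s, gap %.1f px (centre row %d)\n",
              nrow(x$image), ncol(x$image), as.character(x$grade),
              x$spec$gap_width, x$gap_center_row))
  invisible(x)
}

#' Draw randomised phantom specs for a labelled cohort
#'
#' Produces one spec per requested sample with per-sample jitter around the
#' grade defaults: gap width x U(0.85, 1.15) (relative joint-space-width
#' variation within a grade), joint-centre row +/- 8 rows, condyle
#' amplitude 2--5 px, and +/- 10 / +/- 5 intensity units on bone / joint
#' space. The multiplicative jitter keeps the five grades' gap-width ranges
#' disjoint, so the ordinal gap ordering is preserved.
#'
#' @param n_per_grade Either a single count applied to every grade or a
#'   named/ordered vector of five counts (Normal ... Severe). The default
#'   mirrors a realistically imbalanced clinical cohort at one-tenth scale:
#'   65, 53, 28, 26, 28.
#' @param seed Integer master seed; all jitter and per-phantom noise seeds
#'   derive from it.
#' @param noise_sd Noise level passed to every spec.
#' @param image_size Image size passed to every spec.
#' @return A list of [phantom_spec()] objects with names `<grade>_<i>`.
#' @export
sample_phantom_specs <- function(n_per_grade = c(65L, 53L, 28L, 26L, 28L),
                                 seed = 1L, noise_sd = 8,
                                 image_size = c(256L, 465L)) {
  if (length(n_per_grade) == 1L) {
    n_per_grade <- rep(n_per_grade, 5L)
  }
  if (length(n_per_grade) != 5L || any(n_per_grade < 1)) {
    stop_invalid("`n_per_grade` must give a count >= 1 for each of 5 grades")
  }
  grades <- kl_grades()
  with_local_seed(seed, {
    specs <- list()
    for (g in seq_along(grades)) {
      base <- default_gap_width(grades[g])
      for (i in seq_len(n_per_grade[g])) {
        specs[[paste0(grades[g], "_", i)]] <- phantom_spec(
          grade = grades[g],
          image_size = image_size,
          gap_width = base * runif(1, 0.85, 1.15),
          gap_center_row = round(image_size[1] / 2 + runif(1, -8, 8)),
          condyle_amplitude = runif(1, 2, 5),
          bone_intensity = 200 + runif(1, -10, 10),
          gap_intensity = 60 + runif(1, -5, 5),
          noise_sd = noise_sd,
          seed = sample.int(.Machine$integer.max, 1)
        )
      }
    }
    specs
  })
}

#' Generate a labelled Hu-feature dataset from phantoms
#'
#' Runs the full measurement pipeline on each sampled phantom — denoising,
#' joint-ROI localisation from the pixel-density profile, active-contour
#' segmentation of the joint space, and Hu-moment extraction from the
#' segmented region — and returns a tidy labelled feature table.
#'
#' @inheritParams sample_phantom_specs
#' @param band_height ROI band height in rows passed to
#'   [locate_joint_roi()]; default one quarter of the image rows.
#' @return A tibble with columns `image_id`, `grade` (ordered factor) and
#'   `phi1` ... `phi7`. Deterministic given `seed`.
#' @export
#' @examples
#' feats <- generate_feature_dataset(n_per_grade = 2, seed = 42)
#' feats
generate_feature_dataset <- function(n_per_grade = c(65L, 53L, 28L, 26L, 28L),
                                     seed = 1L, noise_sd = 8,
                                     image_size = c(256L, 465L),
                                     band_height = NULL) {
  specs <- sample_phantom_specs(n_per_grade, seed = seed,
                                noise_sd = noise_sd, image_size = image_size)
  rows <- purrr::imap(specs, function(sp, id) {
    phi <- tryCatch(
      phantom_features(sp, band_height = band_height),
      kneemoments_error = function(e) {
        km_stop(paste0("feature pipeline failed for phantom '", id,
                       "' (seed ", sp$seed, "): ", conditionMessage(e)),
                class(e)[1])
      }
    )
    tibble::tibble(image_id = id, grade = as.character(sp$grade),
                   !!!as.list(phi))
  })
  out <- dplyr::bind_rows(rows)
  out$grade <- kl_grade(out$grade)
  out
}

# Full per-phantom measurement chain: phantom -> denoise -> ROI -> active
# contour -> Hu features of the segmented joint space.
phantom_features <- function(spec, band_height = NULL) {
  ph <- generate_phantom(spec)
  img <- denoise(ph$image)
  roi <- locate_joint_roi(img, band_height = band_height)
  crop <- crop_roi(img, roi)
  mask <- active_contour_segment(crop)
  features_from_region(crop, mask)
}

#' Write / read a labelled feature table as CSV
#'
#' Plain CSV with mandatory header `image_id, phi1 ... phi7, grade`.
#'
#' @param features Tibble as returned by [generate_feature_dataset()].
#' @param path CSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_csv <- function(features, path) {
  need <- c("image_id", paste0("phi", 1:7), "grade")
  if (!all(need %in% names(features))) {
    stop_invalid("feature table must have columns image_id, phi1..phi7, grade")
  }
  df <- as.data.frame(features)[, need]
  df$grade <- as.character(df$grade)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) {
    stop_io(paste0("feature CSV not found: ", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", paste0("phi", 1:7), "grade")
  if (!all(need %in% names(df))) {
    stop_invalid("feature CSV must have columns image_id, phi1..phi7, grade")
  }
  out <- tibble::as_tibble(df[, need])
  out$grade <- kl_grade(out$grade)
  out
}
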