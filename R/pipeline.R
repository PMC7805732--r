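# End-to-end orchestration: image -> denoise -> contours -> ROI ->
# active-contour segmentation -> Hu features -> K-NN grade, plus the
# experiment driver (phantom cohort -> features -> stratified 2-fold CV).

# Small FNV-1a hash for config fingerprints in run reports. 32-bit state is
# kept as a double; the multiply works in 16-bit limbs so no intermediate
# exceeds 2^53.
fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' One declarative object holding every tunable default of the grading
#' pipeline, so a run is fully auditable from its report.
#'
#' @param band_height ROI band height in rows; `NULL` means one quarter of
#'   the image rows.
#' @param min_prominence Minimum joint-valley prominence for
#'   [locate_joint_roi()].
#' @param ac_max_iterations,ac_tolerance Active-contour stopping rule, see
#'   [active_contour_segment()].
#' @param k,metric,standardize k-NN configuration, see [knn_fit()].
#' @param log_features Apply the signed-log transform [hu_log_transform()]
#'   to features before classification (off by default; the pipeline
#'   works on raw-scale invariants).
#' @return A list of class `kl_config` with a `fingerprint` attribute.
#' @export
kl_config <- function(band_height = NULL, min_prominence = 0.05,
                      ac_max_iterations = 200L, ac_tolerance = 1e-3,
                      k = 3L, metric = "euclidean", standardize = TRUE,
                      log_features = FALSE) {
  cfg <- list(band_height = band_height,
              min_prominence = min_prominence,
              ac_max_iterations = ac_max_iterations,
              ac_tolerance = ac_tolerance,
              k = k, metric = metric, standardize = standardize,
              log_features = log_features)
  attr(cfg, "fingerprint") <- fnv1a(paste(
    names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                       character(1)),
    sep = "=", collapse = ";"
  ))
  class(cfg) <- "kl_config"
  cfg
}

#' Signed logarithmic transform of Hu invariants
#'
#' `-sign(phi) * log10(|phi|)`, the transform often used to compress the
#' dynamic range of the seven invariants; exact zeros map to zero. Offered
#' as an opt-in classifier input transform — the package stores and reports
#' raw-scale invariants.
#'
#' @param x Numeric vector, matrix, or data frame with `phi` columns.
#' @return Same shape as `x`, transformed.
#' @export
hu_log_transform <- function(x) {
  f <- function(v) ifelse(v == 0, 0, -sign(v) * log10(abs(v)))
  if (is.data.frame(x)) {
    for (col in intersect(feature_cols(), names(x))) {
      x[[col]] <- f(x[[col]])
    }
    x
  } else {
    f(x)
  }
}

#' Grade one radiograph (or phantom image) end to end
#'
#' Runs the full measurement chain on a single image: median denoising,
#' bone-contour detection, joint-ROI localisation from the row-density
#' profile, active-contour segmentation of the joint space, Hu-moment
#' extraction, and k-NN grading. Each stage is timed and recorded; a stage
#' failure is captured in the report rather than thrown (the `status` and
#' `failed_stage` fields, and the corresponding CLI exit code, identify it).
#'
#' @param image Path to a PNG/TIFF file, or a numeric intensity matrix.
#' @param model A fitted [knn_fit()] model (or a path to one saved with
#'   [save_knn_model()]).
#' @param config A [kl_config()].
#' @param truth_mask Optional logical matrix (full image size) with the true
#'   joint-space mask; when supplied the report carries the Dice overlap.
#' @param image_id Identifier recorded in the report; defaults to the file
#'   name or `"image"`.
#' @return An object of class `run_report` (see [validate_run_report()]).
#' @export
grade_image <- function(image, model, config = kl_config(),
                        truth_mask = NULL, image_id = NULL) {
  if (is.character(model)) {
    model <- load_knn_model(model)
  }
  if (!inherits(model, "knn_model")) {
    stop_invalid("`model` must be a knn_model or a path to a saved one")
  }
  if (!inherits(config, "kl_config")) {
    stop_invalid("`config` must be a kl_config")
  }
  if (is.character(image)) {
    if (is.null(image_id)) {
      image_id <- basename(image)
    }
    image <- read_gray_image(image)
  } else if (is.null(image_id)) {
    image_id <- "image"
  }

  report <- list(image_id = image_id,
                 config_fingerprint = attr(config, "fingerprint"),
                 status = "ok", failed_stage = NULL, stages = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), kneemoments_error = function(e) e)
    report$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 4),
      ok = !inherits(res, "condition")
    )
    if (inherits(res, "condition")) {
      report$status <<- "failed"
      report$failed_stage <<- name
      report$error <<- conditionMessage(res)
    }
    res
  }

  den <- run_stage("denoise", function() denoise(image))
  if (report$status == "failed") {
    return(structure(report, class = "run_report"))
  }
  contours <- run_stage("contours", function() detect_bone_contours(den))
  if (report$status == "failed") {
    return(structure(report, class = "run_report"))
  }
  report$contour_count <- contours$contour_count

  bh <- if (is.null(config$band_height)) round(nrow(den) / 4)
        else config$band_height
  roi <- run_stage("roi", function() {
    locate_joint_roi(den, band_height = bh,
                     min_prominence = config$min_prominence)
  })
  if (report$status == "failed") {
    return(structure(report, class = "run_report"))
  }
  report$roi <- list(row_start = roi$row_start, row_end = roi$row_end,
                     col_start = roi$col_start, col_end = roi$col_end)

  crop <- crop_roi(den, roi)
  mask <- run_stage("segment", function() {
    active_contour_segment(crop, max_iterations = config$ac_max_iterations,
                           tolerance = config$ac_tolerance)
  })
  if (report$status == "failed") {
    return(structure(report, class = "run_report"))
  }
  report$mask_summary <- list(foreground_pixels = sum(mask))
  if (!is.null(truth_mask)) {
    report$mask_summary$dice <- dice_overlap(mask, crop_roi_mask(truth_mask,
                                                                 roi))
  }

  phi <- run_stage("features", function() features_from_region(crop, mask))
  if (report$status == "failed") {
    return(structure(report, class = "run_report"))
  }
  report$features <- as.list(phi)

  pred <- run_stage("grade", function() {
    feats <- if (config$log_features) hu_log_transform(phi) else phi
    knn_predict(model, feats)
  })
  if (report$status == "failed") {
    return(structure(report, class = "run_report"))
  }
  report$predicted <- as.character(pred)
  structure(report, class = "run_report")
}

# Crop a logical mask with an roi_box (crop_roi requires numeric).
crop_roi_mask <- function(mask, roi) {
  mask[(roi$row_start + 1):roi$row_end,
       (roi$col_start + 1):roi$col_end, drop = FALSE]
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s: %s\n", x$image_id, x$status))
  if (x$status == "ok") {
    cat(sprintf("  predicted grade: %s; ROI rows [%d, %d); %d mask px\n",
                x$predicted, x$roi$row_start, x$roi$row_end,
                x$mask_summary$foreground_pixels))
  } else {
    cat(sprintf("  failed at stage '%s': %s\n", x$failed_stage, x$error))
  }
  invisible(x)
}

#' Write / read a run report as JSON
#'
#' Stage timings are excluded from determinism guarantees; everything else
#' in the report is a pure function of (image, model, config).
#'
#' @param report A `run_report`.
#' @param path JSON path.
#' @return `path` (write) or the report list (read).
#' @export
write_run_report <- function(report, path) {
  if (!inherits(report, "run_report")) {
    stop_invalid("`report` must be a run_report")
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a run report against the shipped schema
#'
#' Structural validation against the JSON schema in
#' `inst/schema/run_report.json`: required top-level fields, stage entries
#' with `seconds`/`ok`, and — for successful runs — a 7-element feature
#' block, a well-formed 0-based half-open ROI and a valid grade label.
#'
#' @param report A `run_report` or a list parsed from a report JSON.
#' @return `TRUE` invisibly; otherwise an invalid-argument error describing
#'   the first violation.
#' @export
validate_run_report <- function(report) {
  r <- unclass(report)
  need <- c("image_id", "config_fingerprint", "status", "stages")
  for (f in need) {
    if (is.null(r[[f]])) {
      stop_invalid(paste0("run report missing required field `", f, "`"))
    }
  }
  if (!r$status %in% c("ok", "failed")) {
    stop_invalid("run report `status` must be 'ok' or 'failed'")
  }
  for (nm in names(r$stages)) {
    st <- r$stages[[nm]]
    if (is.null(st$seconds) || is.null(st$ok)) {
      stop_invalid(paste0("stage `", nm, "` missing seconds/ok"))
    }
  }
  if (r$status == "failed") {
    if (is.null(r$failed_stage)) {
      stop_invalid("failed run report must name the failed stage")
    }
    return(invisible(TRUE))
  }
  if (length(r$features) != 7L) {
    stop_invalid("run report must carry 7 features phi1..phi7")
  }
  roi <- r$roi
  if (is.null(roi) || roi$row_start < 0 || roi$row_start >= roi$row_end ||
      roi$col_start < 0 || roi$col_start >= roi$col_end) {
    stop_invalid("run report ROI must be 0-based half-open with start < end")
  }
  if (!r$predicted %in% kl_grades()) {
    stop_invalid("run report `predicted` must be a KL grade label")
  }
  invisible(TRUE)
}

#' Save / load a k-NN model as JSON
#'
#' The model is persisted as transparent JSON (training matrix, labels and
#' configuration), not an opaque binary.
#'
#' @param model A [knn_fit()] model.
#' @param path JSON path.
#' @return `path` (save) or the reconstructed `knn_model` (load).
#' @export
save_knn_model <- function(model, path) {
  if (!inherits(model, "knn_model")) {
    stop_invalid("`model` must be a knn_model")
  }
  payload <- list(
    type = "knn_model",
    k = model$k, metric = model$metric, standardize = model$standardize,
    center = model$center, scale = model$scale,
    labels = as.character(model$y),
    x = model$x
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_knn_model
#' @export
load_knn_model <- function(path) {
  if (!file.exists(path)) {
    stop_io(paste0("model file not found: ", path))
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$type) || p$type != "knn_model") {
    stop_invalid("file is not a saved knn_model")
  }
  x <- as.matrix(p$x)
  colnames(x) <- feature_cols()
  structure(
    list(x = x, y = kl_grade(p$labels), k = as.integer(p$k),
         metric = p$metric, standardize = isTRUE(p$standardize),
         center = as.numeric(p$center), scale = as.numeric(p$scale)),
    class = "knn_model"
  )
}

#' Run a full phantom grading experiment
#'
#' Generates (or accepts) a labelled Hu-feature dataset, runs stratified
#' two-fold cross-validation with both the k-NN grader and the CART
#' comparison tree on the same split, and assembles the pooled confusion
#' matrix, overall accuracy, and per-grade precision/recall under both
#' denominator conventions.
#'
#' @param data Optional feature tibble (columns `phi1..phi7`, `grade`); when
#'   `NULL`, a phantom cohort is generated.
#' @param n_per_grade,noise_sd,image_size Phantom cohort parameters, see
#'   [generate_feature_dataset()].
#' @param config A [kl_config()].
#' @param max_depth Tree depth cap for the comparison classifier.
#' @param seed Seed for phantom generation and the CV split.
#' @param out_dir Optional directory; when given, the features
#'   (`features.csv`), confusion matrix (`confusion_knn.csv`), metrics
#'   (`metrics.csv`) and a JSON summary (`experiment.json`) are written.
#' @return A list of class `kl_experiment` with `features`, `knn` and
#'   `tree` ([two_fold_cv()] results), and `metrics` (long tibble of
#'   precision/recall per grade and convention).
#' @export
run_experiment <- function(data = NULL,
                           n_per_grade = c(65L, 53L, 28L, 26L, 28L),
                           noise_sd = 8, image_size = c(256L, 465L),
                           config = kl_config(), max_depth = 8L,
                           seed = 1L, out_dir = NULL) {
  if (is.null(data)) {
    data <- generate_feature_dataset(n_per_grade = n_per_grade, seed = seed,
                                     noise_sd = noise_sd,
                                     image_size = image_size,
                                     band_height = config$band_height)
  } else {
    if (!is.data.frame(data) || !"grade" %in% names(data) ||
        !all(feature_cols() %in% names(data))) {
      stop_invalid("`data` must have columns phi1..phi7 and grade")
    }
  }
  feats <- if (config$log_features) hu_log_transform(data) else data
  cv_knn <- two_fold_cv(feats, classifier = "knn", k = config$k,
                        metric = config$metric,
                        standardize = config$standardize, seed = seed)
  cv_tree <- two_fold_cv(feats, classifier = "tree", max_depth = max_depth,
                         seed = seed)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(precision_recall(cv_knn$confusion, "paper"),
                  convention = "paper"),
    dplyr::mutate(precision_recall(cv_knn$confusion, "standard"),
                  convention = "standard")
  )
  out <- structure(
    list(features = data, knn = cv_knn, tree = cv_tree, metrics = metrics,
         config = config, seed = as.integer(seed)),
    class = "kl_experiment"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!"image_id" %in% names(data)) {
      data$image_id <- sprintf("sample_%04d", seq_len(nrow(data)))
    }
    write_feature_csv(data, file.path(out_dir, "features.csv"))
    write.csv(as.data.frame(unclass(cv_knn$confusion)),
              file.path(out_dir, "confusion_knn.csv"))
    write.csv(as.data.frame(metrics), file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(knn_accuracy = cv_knn$accuracy, tree_accuracy = cv_tree$accuracy,
           n = nrow(data), seed = seed,
           config_fingerprint = attr(config, "fingerprint")),
      file.path(out_dir, "experiment.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}

#' @export
print.kl_experiment <- function(x, ...) {
  cat(sprintf(
    "<kl_experiment> n = %d | 2-fold CV accuracy: knn %.4f, tree %.4f\n",
    nrow(x$features), x$knn$accuracy, x$tree$accuracy
  ))
  invisible(x)
}
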